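#' Specific binding ratio
#'
#' `(striatal - cerebellar) / cerebellar` VOI mean counts: the
#' cerebellum-referenced dopamine-transporter uptake measure.
#' Vectorized; invariant to rescaling all of a subject's counts.
#'
#' @param striatal_count,cerebellar_count VOI mean counts; cerebellar
#'   counts must be positive.
#' @return dimensionless ratio(s) > -1.
#' @export
compute_sbr <- function(striatal_count, cerebellar_count) {
  if (any(!is.finite(cerebellar_count)) || any(cerebellar_count <= 0))
    stop("cerebellar count must be positive", call. = FALSE)
  (striatal_count - cerebellar_count) / cerebellar_count
}

#' Left-right asymmetry index
#'
#' `|R - L| / (R + L)` of a bilateral uptake measure, in `[0, 1]`.
#' Negative inputs (possible for noisy SBR values) are clipped to zero
#' with a warning before the index is formed; when both sides are zero
#' the index is undefined and `NA` is returned.
#'
#' @param right,left uptake values (e.g. SBR) for the right and left VOI.
#' @return asymmetry index in `[0, 1]`, `NA` where `R + L = 0`.
#' @export
compute_asymmetry_index <- function(right, left) {
  if (any(right < 0, na.rm = TRUE) || any(left < 0, na.rm = TRUE)) {
    warning("negative uptake values clipped to 0 before asymmetry index",
            call. = FALSE)
    right <- pmax(right, 0)
    left <- pmax(left, 0)
  }
  s <- right + left
  out <- abs(right - left) / s
  out[s == 0] <- NA_real_
  out
}

#' Quantify uptake from a VOI count table
#'
#' Computes the specific binding ratio for each striatal VOI (caudate,
#' anterior putamen, posterior putamen x side) against the subject's
#' cerebellar reference, and the per-region asymmetry indices.
#'
#' @param voi_counts long data.frame with columns `subject_id`, `region`,
#'   `side`, `mean_count`; one `cerebellum` row per subject (side `NA`).
#' @return list of class `uptake_record` with `sbr` (subject_id, region,
#'   side, sbr) and `ai` (subject_id, region, ai).
#' @export
uptake_from_counts <- function(voi_counts) {
  cereb <- voi_counts[voi_counts$region == "cerebellum", ]
  if (any(duplicated(cereb$subject_id)))
    stop("multiple cerebellum rows for a subject", call. = FALSE)
  stri <- voi_counts[voi_counts$region != "cerebellum", ]
  ref <- setNames(cereb$mean_count, cereb$subject_id)
  if (anyNA(ref[stri$subject_id]))
    stop("missing cerebellum reference row for at least one subject",
         call. = FALSE)
  sbr <- data.frame(subject_id = stri$subject_id, region = stri$region,
                    side = stri$side,
                    sbr = compute_sbr(stri$mean_count,
                                      unname(ref[stri$subject_id])),
                    stringsAsFactors = FALSE)
  key <- paste(sbr$subject_id, sbr$region)
  r_side <- sbr[sbr$side == "R", ]
  l_side <- sbr[sbr$side == "L", ]
  m <- match(paste(r_side$subject_id, r_side$region),
             paste(l_side$subject_id, l_side$region))
  ai <- data.frame(subject_id = r_side$subject_id,
                   region = r_side$region,
                   ai = compute_asymmetry_index(r_side$sbr,
                                                l_side$sbr[m]),
                   stringsAsFactors = FALSE)
  structure(list(sbr = sbr, ai = ai), class = "uptake_record")
}

#' Group summaries of striatal uptake
#'
#' Per (region, side): group means and standard errors, percent
#' difference of each patient group versus HC
#' (`100 * (HC_mean - group_mean) / HC_mean`), and one-way ANOVA with
#' Tukey post-hoc comparisons; the same ANOVA machinery is applied to the
#' per-region asymmetry indices.
#'
#' @param uptake an `uptake_record` from [uptake_from_counts()].
#' @param groups named vector or data.frame mapping `subject_id` to
#'   group.
#' @param reference reference group for percent differences (default
#'   `"HC"`).
#' @return list with `group_means`, `percent_diff`, `anova_sbr`,
#'   `tukey_sbr`, `anova_ai`, `tukey_ai`.
#' @export
summarize_uptake <- function(uptake, groups, reference = "HC") {
  if (is.data.frame(groups))
    groups <- setNames(groups$group, groups$subject_id)
  sbr <- uptake$sbr
  sbr$group <- unname(groups[sbr$subject_id])
  ai <- uptake$ai
  ai$group <- unname(groups[ai$subject_id])
  if (anyNA(sbr$group))
    stop("every subject in the uptake table needs a group label",
         call. = FALSE)

  cell <- function(df, value) {
    agg_m <- aggregate(df[[value]],
                       by = df[c("region", "side", "group")[
                         c("region", "side", "group") %in% names(df)]],
                       FUN = mean, na.rm = TRUE)
    names(agg_m)[ncol(agg_m)] <- "mean"
    agg_n <- aggregate(df[[value]],
                       by = df[c("region", "side", "group")[
                         c("region", "side", "group") %in% names(df)]],
                       FUN = function(z) sum(is.finite(z)))
    agg_s <- aggregate(df[[value]],
                       by = df[c("region", "side", "group")[
                         c("region", "side", "group") %in% names(df)]],
                       FUN = function(z) sd(z, na.rm = TRUE))
    agg_m$n <- agg_n[[ncol(agg_n)]]
    agg_m$sem <- agg_s[[ncol(agg_s)]] / sqrt(agg_m$n)
    agg_m
  }
  gm <- cell(sbr, "sbr")

  ref <- gm[gm$group == reference, ]
  others <- setdiff(unique(gm$group), reference)
  pd <- do.call(rbind, lapply(others, function(g) {
    gg <- gm[gm$group == g, ]
    m <- match(paste(gg$region, gg$side), paste(ref$region, ref$side))
    data.frame(region = gg$region, side = gg$side, group = g,
               percent_diff = 100 * (ref$mean[m] - gg$mean) / ref$mean[m],
               stringsAsFactors = FALSE)
  }))

  run_tests <- function(df, value, by_side) {
    keys <- unique(df[, intersect(c("region", "side"), names(df)),
                      drop = FALSE])
    an_rows <- list(); tk_rows <- list()
    for (i in seq_len(nrow(keys))) {
      sel <- df$region == keys$region[i]
      if (by_side) sel <- sel & df$side == keys$side[i]
      dd <- df[sel & is.finite(df[[value]]), ]
      sizes <- table(dd$group)
      lab <- if (by_side) sprintf("%s_%s", keys$region[i], keys$side[i])
             else keys$region[i]
      if (length(sizes) < 2 || any(sizes < 2)) {
        an_rows[[i]] <- data.frame(variable = lab, F = NA_real_,
                                   df1 = NA_real_, df2 = NA_real_,
                                   p = NA_real_)
        next
      }
      res <- anova_tukey(dd[[value]], dd$group)
      an_rows[[i]] <- cbind(variable = lab, res$anova)
      tk_rows[[i]] <- cbind(variable = lab, res$tukey)
    }
    list(anova = do.call(rbind, an_rows), tukey = do.call(rbind, tk_rows))
  }
  ts <- run_tests(sbr, "sbr", by_side = TRUE)
  ta <- run_tests(ai, "ai", by_side = FALSE)

  list(group_means = gm, percent_diff = pd,
       anova_sbr = ts$anova, tukey_sbr = ts$tukey,
       anova_ai = ta$anova, tukey_ai = ta$tukey)
}
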
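# parameter x side grid used throughout the classifier
classifier_grid <- function() {
  expand.grid(parameter = tapmark_parameters(), side = tapmark_sides(),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

summary_column <- function(parameter) {
  c(amplitude = "mean_amplitude", open_speed = "mean_peak_open_speed",
    close_speed = "mean_peak_close_speed")[[parameter]]
}

slope_column <- function(parameter) {
  c(amplitude = "slope_amplitude", open_speed = "slope_open_speed",
    close_speed = "slope_close_speed")[[parameter]]
}

#' Construct a normative model from explicit statistics
#'
#' Lower-level constructor used when the per-parameter means and SDs are
#' known (e.g. population values in simulation studies).  Cutoffs are the
#' 2-SD rule: `mean - 2 * sd` for values and, when slope statistics are
#' supplied, for slopes.
#'
#' @param stats data.frame with columns `parameter` (`amplitude`,
#'   `open_speed`, `close_speed`), `side` (`L`/`R`), `mean`, `sd`, and
#'   optionally `slope_mean`, `slope_sd`.
#' @param n_hc number of healthy-control subjects behind the statistics.
#' @return object of class `normative_model`.
#' @export
normative_model <- function(stats, n_hc = NA_integer_) {
  need <- c("parameter", "side", "mean", "sd")
  if (!all(need %in% names(stats)))
    stop("stats needs columns parameter, side, mean, sd", call. = FALSE)
  grid <- classifier_grid()
  key <- paste(stats$parameter, stats$side)
  if (!setequal(key, paste(grid$parameter, grid$side)))
    stop("stats must cover all six parameter x side combinations",
         call. = FALSE)
  if (any(stats$sd <= 0))
    stop("degenerate normative model: zero variance in at least one parameter",
         call. = FALSE)
  stats$cutoff <- stats$mean - 2 * stats$sd
  if (!is.null(stats$slope_mean) && !is.null(stats$slope_sd)) {
    if (any(stats$slope_sd <= 0, na.rm = TRUE))
      stop("degenerate normative model: zero variance in at least one slope",
           call. = FALSE)
    stats$slope_cutoff <- stats$slope_mean - 2 * stats$slope_sd
  } else {
    stats$slope_mean <- stats$slope_sd <- stats$slope_cutoff <- NA_real_
  }
  rownames(stats) <- NULL
  structure(stats[c("parameter", "side", "mean", "sd", "cutoff",
                    "slope_mean", "slope_sd", "slope_cutoff")],
            class = c("normative_model", "data.frame"), n_hc = n_hc)
}

#' Fit the healthy-control normative model
#'
#' Per parameter (amplitude, peak open speed, peak close speed) and per
#' side, the mean and sample SD (n - 1 denominator) over healthy-control
#' subjects, with 2-SD cutoffs for values and for decrement slopes.
#' Sides are fitted independently.  Subjects missing a hand are excluded
#' with a warning.
#'
#' @param hc_summaries tapping summary table ([summarize_recording()]
#'   rows) for healthy controls: one row per subject x hand.
#' @return a `normative_model`.
#' @export
fit_normative_model <- function(hc_summaries) {
  tab <- table(hc_summaries$subject_id)
  complete <- names(tab)[tab == 2L]
  if (length(complete) < length(tab))
    warning(sprintf("%d HC subject(s) excluded: missing a hand",
                    length(tab) - length(complete)), call. = FALSE)
  if (length(complete) < 3)
    stop("need at least 3 HC subjects with both hands", call. = FALSE)
  s <- hc_summaries[hc_summaries$subject_id %in% complete, ]
  grid <- classifier_grid()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- grid$parameter[i]
    sd_ <- grid$side[i]
    vals <- s[s$hand == sd_, summary_column(p)]
    slopes <- s[s$hand == sd_, slope_column(p)]
    slopes <- slopes[is.finite(slopes)]
    data.frame(parameter = p, side = sd_,
               mean = mean(vals), sd = sd(vals),
               slope_mean = if (length(slopes) >= 3) mean(slopes)
                            else NA_real_,
               slope_sd = if (length(slopes) >= 3) sd(slopes)
                          else NA_real_,
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, rows)
  if (any(stats$sd <= 0 | !is.finite(stats$sd)))
    stop("degenerate normative model: zero variance in at least one parameter",
         call. = FALSE)
  normative_model(stats, n_hc = length(complete))
}

# internal: wide per-subject table (one row per subject, columns
# <param>_<side> and slope_<param>_<side>) from the long summary table
summaries_to_wide <- function(summaries) {
  ids <- unique(summaries$subject_id)
  grid <- classifier_grid()
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    p <- grid$parameter[i]
    sd_ <- grid$side[i]
    col <- paste0(p, "_", sd_)
    m <- match(paste(ids, rep(sd_, length(ids))),
               paste(summaries$subject_id, summaries$hand))
    out[[col]] <- summaries[[summary_column(p)]][m]
    out[[paste0("slope_", col)]] <- summaries[[slope_column(p)]][m]
  }
  out
}

#' Vectorized classification of a wide parameter table
#'
#' Applies the 2-SD rule to a table of subjects in wide format: one row
#' per subject, columns `<parameter>_<side>` (e.g. `amplitude_R`) and
#' optionally `slope_<parameter>_<side>`.  A value flag is raised when
#' the value is strictly below the cutoff; `is_mmi` is true when at
#' least one of the six flags is raised.  Decrement flags are raised
#' analogously on slopes when the model carries slope cutoffs.
#'
#' @param wide data.frame with `subject_id` and the six parameter
#'   columns (slope columns optional).
#' @param model a `normative_model`.
#' @return data.frame with six value flags, `n_flags`, `is_mmi`, six
#'   decrement flags, `has_progressive_decrement`.
#' @export
classify_values <- function(wide, model) {
  grid <- classifier_grid()
  flags <- matrix(NA, nrow(wide), nrow(grid))
  dec <- matrix(NA, nrow(wide), nrow(grid))
  fnames <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- grid$parameter[i]
    sd_ <- grid$side[i]
    row <- model[model$parameter == p & model$side == sd_, ]
    col <- paste0(p, "_", sd_)
    fnames[i] <- col
    flags[, i] <- wide[[col]] < row$cutoff            # strict inequality
    scol <- paste0("slope_", col)
    if (scol %in% names(wide) && is.finite(row$slope_cutoff))
      dec[, i] <- wide[[scol]] < row$slope_cutoff
  }
  colnames(flags) <- paste0("flag_", fnames)
  colnames(dec) <- paste0("decrement_", fnames)
  out <- data.frame(subject_id = wide$subject_id,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(flags))
  out$n_flags <- as.integer(rowSums(flags))
  out$is_mmi <- out$n_flags >= 1L
  out <- cbind(out, as.data.frame(dec))
  has_dec <- rowSums(dec, na.rm = TRUE) > 0
  has_dec[rowSums(!is.na(dec)) == 0L] <- NA
  out$has_progressive_decrement <- has_dec
  out
}

#' Classify one subject against the normative model
#'
#' A subject is flagged as having mild motor impairment (MMI) when at
#' least one of the six parameters (amplitude, peak open speed, peak
#' close speed, each side) is strictly below the healthy-control mean
#' minus 2 SD for that parameter and side.  Progressive decrement is
#' flagged analogously on the per-parameter slopes against the slope
#' cutoffs.
#'
#' @param summary_pair tapping summary rows for this subject, one per
#'   hand (both `L` and `R` required).
#' @param model a `normative_model`.
#' @return one-row classification data.frame: six value flags, `n_flags`,
#'   `is_mmi`, six decrement flags, `has_progressive_decrement`.
#' @export
classify_subject <- function(summary_pair, model) {
  if (!setequal(summary_pair$hand, c("L", "R")))
    stop("classification requires summaries for both hands", call. = FALSE)
  wide <- summaries_to_wide(summary_pair)
  if (anyNA(wide[paste0(classifier_grid()$parameter, "_",
                        classifier_grid()$side)]))
    stop("classification requires all six parameters", call. = FALSE)
  classify_values(wide, model)
}

#' Classify a cohort: fit on HC, classify RBD subjects
#'
#' Fits the normative model on healthy controls only, classifies every
#' RBD subject, and reassigns RBD subjects to observed groups `RBD-MMI` /
#' `RBD-N`.  HC subjects are never reassigned.
#'
#' @param summaries tapping summary table for all subjects (one row per
#'   subject x hand).
#' @param groups named character vector or data.frame mapping
#'   `subject_id` to group (`HC` and anything else, treated as RBD).
#' @return list with `model` (the fitted `normative_model`) and
#'   `classification` (per-RBD-subject flags plus `group_observed`; HC
#'   subjects appear with `group_observed = "HC"` and no flags).
#' @export
classify_cohort <- function(summaries, groups) {
  if (is.data.frame(groups))
    groups <- setNames(groups$group, groups$subject_id)
  g <- groups[summaries$subject_id]
  if (anyNA(g))
    stop("every summarized subject needs a group label", call. = FALSE)
  hc_ids <- names(groups)[groups == "HC"]
  if (!length(hc_ids))
    stop("no HC subjects: cannot fit the normative model", call. = FALSE)
  model <- fit_normative_model(summaries[summaries$subject_id %in% hc_ids, ])
  rbd_ids <- names(groups)[groups != "HC" &
                             names(groups) %in% summaries$subject_id]
  if (length(rbd_ids)) {
    wide <- summaries_to_wide(summaries[summaries$subject_id %in% rbd_ids, ])
    cls <- classify_values(wide, model)
    cls$group_input <- unname(groups[cls$subject_id])
    cls$group_observed <- ifelse(cls$is_mmi, "RBD-MMI", "RBD-N")
  } else {
    cls <- classify_values(summaries_to_wide(summaries[0, ]), model)
    cls$group_input <- character(0)
    cls$group_observed <- character(0)
  }
  list(model = model, classification = cls)
}

#' Serialize a normative model to JSON
#'
#' @param model a `normative_model`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_normative_model <- function(model, path) {
  jsonlite::write_json(list(n_hc = attr(model, "n_hc"),
                            parameters = as.data.frame(model)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a normative model from JSON
#'
#' @param path file written by [write_normative_model()].
#' @return a `normative_model`.
#' @export
read_normative_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  normative_model(x$parameters, n_hc = x$n_hc)
}
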
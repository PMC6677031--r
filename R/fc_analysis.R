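fisher_z_cap <- function() atanh(1 - 1e-7)

#' Fisher z-transformation of a correlation coefficient
#'
#' `atanh(r)`, with values capped at `atanh(1 - 1e-7)` so degenerate
#' perfect correlations remain finite (and flagged by sitting exactly at
#' the cap).
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("|r| > 1: not a correlation coefficient", call. = FALSE)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  atanh(r)
}

#' Zero-phase band-pass filter for ROI time series
#'
#' Second-order Butterworth band-pass applied forward and backward
#' (zero phase) to each ROI column after removing its mean.
#'
#' @param series numeric matrix, volumes x ROIs (a single series is also
#'   accepted).
#' @param band `c(f_lo, f_hi)` in Hz; requires `f_lo < f_hi < 1/(2 tr)`.
#' @param tr repetition time, seconds.
#' @return filtered matrix of identical dimensions; column means ~ 0.
#' @export
bandpass_filter <- function(series, band = c(0.008, 0.09), tr = 2.5) {
  x <- as.matrix(series)
  nyq <- 1 / (2 * tr)
  if (!(band[1] < band[2] && band[2] < nyq))
    stop(sprintf("band [%g, %g] Hz infeasible for tr = %g s (Nyquist %g Hz)",
                 band[1], band[2], tr, nyq), call. = FALSE)
  bf <- signal::butter(2, band / nyq, type = "pass")
  out <- apply(x, 2, function(col) {
    filtfilt_padded(bf, col - mean(col))
  })
  dimnames(out) <- dimnames(x)
  out
}

#' ROI-to-ROI correlation and Fisher-z matrices
#'
#' Pearson correlation between every pair of ROI columns and its Fisher
#' z-transform.  Zero-variance columns yield `NA` for their pairs, with a
#' warning.
#'
#' @param series numeric matrix, volumes x ROIs (>= 10 volumes).
#' @return object of class `fc_result`: list with symmetric `r` and `z`
#'   matrices.
#' @export
compute_fc_matrix <- function(series) {
  x <- as.matrix(series)
  if (nrow(x) < 10)
    stop("need at least 10 volumes", call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    warning(sprintf("%d zero-variance ROI column(s): their pairs set to NA",
                    sum(sds == 0)), call. = FALSE)
  r <- suppressWarnings(cor(x))
  z <- fisher_z(r)
  structure(list(r = r, z = z), class = "fc_result")
}

#' Long-format table of unique ROI pairs
#'
#' @param fc an `fc_result` (or correlation matrix).
#' @return data.frame `roi_1`, `roi_2`, `r`, `z` over the strict upper
#'   triangle.
#' @export
fc_pair_table <- function(fc) {
  r <- if (inherits(fc, "fc_result")) fc$r else as.matrix(fc)
  z <- if (inherits(fc, "fc_result")) fc$z else fisher_z(r)
  labs <- colnames(r) %||% paste0("ROI", seq_len(ncol(r)))
  ut <- upper.tri(r)
  idx <- which(ut, arr.ind = TRUE)
  data.frame(roi_1 = labs[idx[, 1]], roi_2 = labs[idx[, 2]],
             r = r[ut], z = z[ut], stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (the standard
#' `"BH"` adjustment); order-preserving and never smaller than the raw
#' p-value.
#'
#' @param p_values numeric vector in `[0, 1]` (NA allowed).
#' @return adjusted p-values.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Per-subject Fisher-z connectivity for a cohort
#'
#' Band-passes each subject's ROI time series (optional) and extracts the
#' Fisher-z values of all unique ROI pairs.
#'
#' @param roi_timeseries named list of volumes x ROI matrices.
#' @param band,tr band-pass settings; `band = NULL` skips filtering.
#' @return list with `z` (subjects x pairs matrix, rownames = subject
#'   ids) and `pairs` (data.frame `roi_1`, `roi_2`).
#' @export
cohort_fc <- function(roi_timeseries, band = c(0.008, 0.09), tr = 2.5) {
  ids <- names(roi_timeseries)
  first <- TRUE
  zmat <- NULL
  pairs <- NULL
  for (i in seq_along(roi_timeseries)) {
    x <- roi_timeseries[[i]]
    if (!is.null(band)) x <- bandpass_filter(x, band = band, tr = tr)
    tab <- fc_pair_table(compute_fc_matrix(x))
    if (first) {
      pairs <- tab[c("roi_1", "roi_2")]
      zmat <- matrix(NA_real_, length(roi_timeseries), nrow(tab),
                     dimnames = list(ids, paste(tab$roi_1, tab$roi_2,
                                                sep = "~")))
      first <- FALSE
    }
    zmat[i, ] <- tab$z
  }
  list(z = zmat, pairs = pairs)
}

#' Covariate-adjusted group contrasts of connectivity
#'
#' For each ROI pair and each pairwise group contrast, fits a linear
#' model of the Fisher-z value on a group indicator plus centered age and
#' sex (coded M = 0, F = 1), restricted to the two groups compared.  The
#' reported T statistic tests the indicator coefficient (first-listed
#' group minus reference); p-values are two-tailed and BH-FDR adjusted
#' across ROI pairs within each contrast (`fdr_scope = "analysis"`) or
#' within each seed ROI (`fdr_scope = "seed"`, grouping pairs by
#' `roi_1`).
#'
#' @param z subjects x pairs matrix of Fisher-z values (rownames =
#'   subject ids).
#' @param groups,age,sex per-subject covariates, aligned with the rows of
#'   `z` (names or order).
#' @param pairs data.frame `roi_1`, `roi_2` describing the columns of
#'   `z`.
#' @param contrasts list of `c(group, reference)` pairs; default: all
#'   Table-4-style pairwise contrasts among the groups present.
#' @param fdr_scope `"analysis"` or `"seed"`.
#' @return data.frame `roi_1`, `roi_2`, `contrast`, `delta_z`, `T`, `df`,
#'   `p`, `p_fdr`.
#' @export
test_group_differences <- function(z, groups, age, sex, pairs = NULL,
                                   contrasts = NULL,
                                   fdr_scope = c("analysis", "seed")) {
  fdr_scope <- match.arg(fdr_scope)
  z <- as.matrix(z)
  n <- nrow(z)
  if (length(groups) != n || length(age) != n || length(sex) != n)
    stop("groups, age and sex must match the rows of z", call. = FALSE)
  if (is.null(pairs)) {
    nm <- colnames(z) %||% paste0("pair", seq_len(ncol(z)))
    sp <- strsplit(nm, "~", fixed = TRUE)
    pairs <- data.frame(roi_1 = vapply(sp, `[`, "", 1),
                        roi_2 = vapply(sp, function(s) s[length(s)], ""),
                        stringsAsFactors = FALSE)
  }
  glev <- intersect(tapmark_groups(), unique(groups))
  if (length(glev) < 2) glev <- unique(groups)
  if (is.null(contrasts)) {
    contrasts <- list()
    cmb <- utils::combn(glev, 2)
    for (j in seq_len(ncol(cmb)))
      contrasts[[j]] <- c(cmb[2, j], cmb[1, j])  # later group vs earlier
  }
  sex01 <- if (is.numeric(sex)) sex else as.numeric(sex == "F")

  rows <- list()
  for (ct in contrasts) {
    idx <- which(groups %in% ct)
    if (length(unique(groups[idx])) < 2)
      stop(sprintf("contrast %s vs %s: a group is empty", ct[1], ct[2]),
           call. = FALSE)
    X <- cbind(intercept = 1,
               grp = as.numeric(groups[idx] == ct[1]),
               age = age[idx] - mean(age[idx]),
               sex = sex01[idx])
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
      stop(sprintf("rank-deficient design for contrast %s vs %s: collinear column(s) %s",
                   ct[1], ct[2], paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    df <- length(idx) - ncol(X)
    if (df <= 0)
      stop(sprintf("contrast %s vs %s leaves no residual degrees of freedom",
                   ct[1], ct[2]), call. = FALSE)
    fit <- lm.fit(X, z[idx, , drop = FALSE])
    cf <- fit$coefficients
    if (is.null(dim(cf))) cf <- matrix(cf, ncol = 1,
                                       dimnames = list(names(cf), NULL))
    beta <- cf["grp", ]
    res <- as.matrix(fit$residuals)
    sigma2 <- colSums(res^2) / df
    xtxi <- solve(crossprod(X))
    se <- sqrt(sigma2 * xtxi[2, 2])
    tval <- beta / se
    tval[sigma2 <= .Machine$double.eps] <- NA  # zero residual variance
    p <- 2 * pt(-abs(tval), df)
    lab <- sprintf("%s > %s", ct[1], ct[2])
    p_fdr <- if (fdr_scope == "analysis") {
      bh_fdr(p)
    } else {
      out <- rep(NA_real_, length(p))
      for (seed_roi in unique(pairs$roi_1)) {
        sel <- pairs$roi_1 == seed_roi
        out[sel] <- bh_fdr(p[sel])
      }
      out
    }
    rows[[lab]] <- data.frame(roi_1 = pairs$roi_1, roi_2 = pairs$roi_2,
                              contrast = lab, delta_z = unname(beta),
                              T = unname(tval), df = df, p = unname(p),
                              p_fdr = unname(p_fdr),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
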
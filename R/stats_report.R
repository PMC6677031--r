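#' One-way ANOVA with Tukey post-hoc comparisons
#'
#' Univariate ANOVA across groups followed by Tukey's honestly
#' significant difference test (Tukey-Kramer for unequal group sizes,
#' via [stats::TukeyHSD()]).  When every observation is identical the
#' degenerate case is reported as `F = 0`, `p = 1`.
#'
#' @param values numeric outcome.
#' @param group_labels group factor (>= 2 groups, each with >= 2
#'   observations).
#' @return list with `anova` (one row: `F`, `df1`, `df2`, `p`) and
#'   `tukey` (one row per group pair: `group_1`, `group_2`, `diff`,
#'   `p_adj`).
#' @export
anova_tukey <- function(values, group_labels) {
  keep <- is.finite(values) & !is.na(group_labels)
  values <- values[keep]
  g <- factor(group_labels[keep])
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("need at least 2 groups with at least 2 observations each",
         call. = FALSE)
  prs <- utils::combn(levels(g), 2)
  if (var(values) == 0) {
    return(list(
      anova = data.frame(F = 0, df1 = length(sizes) - 1,
                         df2 = length(values) - length(sizes), p = 1),
      tukey = data.frame(group_1 = prs[2, ], group_2 = prs[1, ],
                         diff = 0, p_adj = 1, stringsAsFactors = FALSE)))
  }
  fit <- aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  list(
    anova = data.frame(F = an[["F value"]][1], df1 = an[["Df"]][1],
                       df2 = an[["Df"]][2], p = an[["Pr(>F)"]][1]),
    tukey = data.frame(group_1 = vapply(cmp, `[`, "", 1),
                       group_2 = vapply(cmp, `[`, "", 2),
                       diff = unname(tk[, "diff"]),
                       p_adj = unname(tk[, "p adj"]),
                       stringsAsFactors = FALSE))
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with the pooled variance estimate and a two-tailed
#' p-value.  Degenerate inputs (zero pooled variance) give `t = 0, p =
#' 1` for equal means, or an infinite statistic with `p = 0` and a
#' `degenerate` flag otherwise.  Welch's unequal-variance form is
#' available via `welch = TRUE`.
#'
#' @param values_a,values_b the two samples (each n >= 2).
#' @param welch use the Welch-Satterthwaite test instead of the pooled
#'   form.
#' @return one-row data.frame: `t`, `df`, `p`, `mean_a`, `mean_b`,
#'   `degenerate`.
#' @export
two_sample_t <- function(values_a, values_b, welch = FALSE) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  md <- mean(a) - mean(b)
  if (welch) {
    va <- var(a) / na; vb <- var(b) / nb
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  if (!is.finite(se) || se == 0) {
    if (md == 0)
      return(data.frame(t = 0, df = df, p = 1, mean_a = mean(a),
                        mean_b = mean(b), degenerate = TRUE))
    return(data.frame(t = sign(md) * Inf, df = df, p = 0,
                      mean_a = mean(a), mean_b = mean(b),
                      degenerate = TRUE))
  }
  t <- md / se
  data.frame(t = t, df = df, p = 2 * pt(-abs(t), df), mean_a = mean(a),
             mean_b = mean(b), degenerate = FALSE)
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction by default (the Yates correction is
#' available as an option).  A zero row or column marginal is an error.
#'
#' @param contingency two-way count table (matrix, at least 2 x 2).
#' @param correct apply the Yates continuity correction.
#' @return one-row data.frame: `chi_square`, `df`, `p`.
#' @export
chi_square <- function(contingency, correct = FALSE) {
  m <- as.matrix(contingency)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal in contingency table", call. = FALSE)
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  data.frame(chi_square = unname(ct$statistic), df = unname(ct$parameter),
             p = ct$p.value)
}

#' Pearson correlation with a two-tailed t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, both non-constant).
#' @param x_name,y_name labels for the output row.
#' @return one-row data.frame: `x_name`, `y_name`, `kind`, `covariates`,
#'   `r`, `n`, `p`.
#' @export
pearson_correlation <- function(x, y, x_name = "x", y_name = "y") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant variable: correlation undefined", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  data.frame(x_name = x_name, y_name = y_name, kind = "pearson",
             covariates = "", r = unname(ct$estimate), n = n,
             p = ct$p.value, stringsAsFactors = FALSE)
}

#' Partial correlation controlling for covariates
#'
#' Residualizes `x` and `y` on an intercept plus the covariates by least
#' squares, takes the Pearson correlation of the residuals, and tests it
#' with `df = n - 2 - k` (k covariates).
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame or matrix of covariates (e.g. age, sex
#'   coded 0/1).
#' @param x_name,y_name labels for the output row.
#' @return one-row data.frame as in [pearson_correlation()], with
#'   `kind = "partial"` and the covariate names recorded.
#' @export
partial_correlation <- function(x, y, covariates, x_name = "x",
                                y_name = "y") {
  cv <- as.matrix(as.data.frame(covariates))
  keep <- is.finite(x) & is.finite(y) & complete.cases(cv)
  x <- x[keep]; y <- y[keep]; cv <- cv[keep, , drop = FALSE]
  n <- length(x); k <- ncol(cv)
  if (n < k + 3)
    stop("need at least k + 3 complete observations", call. = FALSE)
  X <- cbind(1, cv)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("collinear covariates: design is rank-deficient", call. = FALSE)
  rx <- qr.resid(qr_x, x)
  ry <- qr.resid(qr_x, y)
  # a variable fully explained by the covariates leaves no signal to
  # correlate: report a null partial correlation rather than 0/0 noise
  if (sd(rx) <= 1e-10 * max(sd(x), 1) || sd(ry) <= 1e-10 * max(sd(y), 1))
    return(data.frame(x_name = x_name, y_name = y_name, kind = "partial",
                      covariates = paste(colnames(cv) %||%
                                           paste0("z", seq_len(k)),
                                         collapse = ","),
                      r = 0, n = n, p = 1, stringsAsFactors = FALSE))
  r <- cor(rx, ry)
  df <- n - 2 - k
  t <- r * sqrt(df / (1 - r^2))
  data.frame(x_name = x_name, y_name = y_name, kind = "partial",
             covariates = paste(colnames(cv) %||%
                                  paste0("z", seq_len(k)), collapse = ","),
             r = r, n = n, p = 2 * pt(-abs(t), df),
             stringsAsFactors = FALSE)
}

#' Map a tapping hand to the contralateral striatal side
#'
#' Motor control is crossed: right-hand tapping is paired with
#' left-hemisphere striatal uptake and vice versa.
#'
#' @param side `"L"` or `"R"` (vectorized).
#' @return the opposite side label(s).
#' @export
contralateral_map <- function(side) {
  if (any(!side %in% c("L", "R")))
    stop("side must be 'L' or 'R'", call. = FALSE)
  unname(c(L = "R", R = "L")[side])
}
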
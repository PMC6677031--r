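test_that("one-way ANOVA matches the hand-computed F and degenerate cases", {
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("A", "B", "C"), each = 3)
  res <- anova_tukey(v, g)
  expect_equal(res$anova$F, 3, tolerance = 1e-12)
  expect_equal(res$anova$df1, 2)
  expect_equal(res$anova$df2, 6)

  same <- anova_tukey(rep(c(1, 2, 3), 3), rep(c("A", "B", "C"), each = 3))
  expect_equal(same$anova$F, 0, tolerance = 1e-12)
  expect_equal(same$anova$p, 1, tolerance = 1e-12)

  const <- anova_tukey(rep(5, 9), rep(c("A", "B", "C"), each = 3))
  expect_equal(const$anova$F, 0)
  expect_equal(const$anova$p, 1)
  expect_true(all(const$tukey$p_adj == 1))

  expect_error(anova_tukey(1:3, c("A", "A", "B")), "at least 2")
})

test_that("Tukey adjustment never undercuts the pooled-MSE pairwise p-value", {
  set.seed(14)
  v <- c(rnorm(10, 0), rnorm(8, 1.5), rnorm(12, 3))
  g <- rep(c("A", "B", "C"), c(10, 8, 12))
  res <- anova_tukey(v, g)
  # raw pairwise test in the same framework: pooled MSW, residual df
  msw <- sum(tapply(v, g, function(z) sum((z - mean(z))^2))) / (30 - 3)
  for (i in seq_len(nrow(res$tukey))) {
    a <- v[g == res$tukey$group_1[i]]
    b <- v[g == res$tukey$group_2[i]]
    t <- (mean(a) - mean(b)) /
      sqrt(msw * (1 / length(a) + 1 / length(b)))
    raw <- 2 * pt(-abs(t), 27)
    expect_gte(res$tukey$p_adj[i] + 1e-12, raw)
  }
})

test_that("ANOVA on two groups equals the squared pooled t", {
  set.seed(15)
  a <- rnorm(9, 0, 1); b <- rnorm(14, 0.8, 1)
  f <- anova_tukey(c(a, b), rep(c("A", "B"), c(9, 14)))$anova
  t <- two_sample_t(a, b)
  expect_equal(f$F, t$t^2, tolerance = 1e-10)
  expect_equal(f$p, t$p, tolerance = 1e-10)
})

test_that("pooled t matches the hand formula and is antisymmetric", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- c(1, 2, 3); b <- c(11, 12, 13)
  res <- two_sample_t(a, b)
  sp <- sqrt(((2) * var(a) + (2) * var(b)) / 4)
  expect_equal(res$t, -10 / (sp * sqrt(2 / 3)), tolerance = 1e-12)

  swapped <- two_sample_t(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)

  # agreement with the standard implementation on ordinary data
  set.seed(16)
  x <- rnorm(12); y <- rnorm(15, 0.4)
  ref <- t.test(x, y, var.equal = TRUE)
  mine <- two_sample_t(x, y)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  deg <- two_sample_t(c(1, 1, 1), c(2, 2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
})

test_that("chi-square matches hand computation and is transpose-invariant", {
  even <- chi_square(matrix(10, 2, 2))
  expect_equal(even$chi_square, 0)
  expect_equal(even$p, 1)

  diagm <- matrix(c(20, 0, 0, 20), 2, 2)
  res <- chi_square(diagm)
  expect_equal(res$chi_square, 40, tolerance = 1e-12)  # N(ad-bc)^2/products
  expect_equal(res$df, 1)

  m <- matrix(c(12, 5, 7, 9, 3, 8), 2, 3)
  expect_equal(chi_square(m)$chi_square, chi_square(t(m))$chi_square,
               tolerance = 1e-12)

  expect_error(chi_square(matrix(c(5, 5, 0, 0), 2, 2)), "marginal")
})

test_that("Pearson correlation matches hand values and rejects constants", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 1, 3))$r, 0.5,
               tolerance = 1e-12)
  expect_equal(pearson_correlation(1:10, -(1:10))$r, -1)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
})

test_that("partial correlation matches the matrix-inversion oracle", {
  set.seed(17)
  n <- 30
  covs <- data.frame(age = rnorm(n, 70, 5),
                     sex = rbinom(n, 1, 0.5))
  x <- rnorm(n) + 0.05 * covs$age
  y <- rnorm(n) + 0.03 * covs$age - 0.4 * covs$sex
  mine <- partial_correlation(x, y, covs)
  expect_equal(mine$r, oracle_partial_cor(x, y, covs), tolerance = 1e-10)

  # a covariate orthogonal to both variables leaves Pearson unchanged
  x2 <- rnorm(20); y2 <- rnorm(20) + 0.5 * x2
  z2 <- data.frame(z = qr.resid(qr(cbind(1, x2, y2)), rnorm(20)))
  expect_equal(partial_correlation(x2, y2, z2)$r,
               pearson_correlation(x2, y2)$r, tolerance = 1e-10)

  # y fully explained by a covariate: null partial correlation
  full <- partial_correlation(rnorm(20), covs$age[1:20],
                              covs[1:20, "age", drop = FALSE])
  expect_equal(full$r, 0)
  expect_equal(full$p, 1)
  expect_error(partial_correlation(x, y,
                                   data.frame(a = covs$age,
                                              b = 2 * covs$age)),
               "collinear")
})

test_that("contralateral mapping is an involution on {L, R}", {
  expect_equal(contralateral_map("R"), "L")
  expect_equal(contralateral_map("L"), "R")
  expect_equal(contralateral_map(contralateral_map(c("L", "R"))),
               c("L", "R"))
  expect_error(contralateral_map("X"), "side")
})

test_that("type-I error sits at the nominal level under the null", {
  set.seed(18)
  alpha_t <- mean(vapply(1:2000, function(i)
    two_sample_t(rnorm(8), rnorm(8))$p < 0.05, logical(1)))
  expect_lt(abs(alpha_t - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))

  alpha_f <- mean(vapply(1:600, function(i)
    anova_tukey(rnorm(18), rep(c("A", "B", "C"), 6))$anova$p < 0.05,
    logical(1)))
  expect_lt(abs(alpha_f - 0.05), 3 * sqrt(0.05 * 0.95 / 600))
})
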
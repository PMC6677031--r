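test_that("SBR follows its defining ratio and scale invariance", {
  expect_equal(compute_sbr(1000, 1000), 0)
  expect_equal(compute_sbr(2000, 1000), 1)
  expect_equal(compute_sbr(1500, 1000), 0.5)
  # multiplying all of a subject's counts leaves SBR unchanged
  expect_equal(compute_sbr(3.7 * 1500, 3.7 * 1000),
               compute_sbr(1500, 1000), tolerance = 1e-12)
  expect_error(compute_sbr(1500, 0), "positive")
})

test_that("asymmetry index is bounded, symmetric-zero and scale-invariant", {
  expect_equal(compute_asymmetry_index(2, 2), 0)
  expect_equal(compute_asymmetry_index(3, 1), 0.5)
  expect_equal(compute_asymmetry_index(1, 0), 1)
  expect_equal(compute_asymmetry_index(0.8 * 3, 0.8 * 1),
               compute_asymmetry_index(3, 1), tolerance = 1e-12)
  expect_true(is.na(compute_asymmetry_index(0, 0)))
  expect_warning(ai <- compute_asymmetry_index(-0.2, 0.4), "clipped")
  expect_equal(ai, 1)
})

make_uptake_cohort <- function(n_per_group, sbr_by_group, noise_sd,
                               seed0 = 1) {
  regions <- c("caudate", "ant_putamen", "post_putamen")
  groups <- rep(names(n_per_group), n_per_group)
  ids <- sprintf("S%03d", seq_along(groups))
  voi <- do.call(rbind, lapply(seq_along(ids), function(i) {
    sbr <- sbr_by_group[[groups[i]]]
    targets <- setNames(rep(sbr[regions], 2),
                        paste(rep(regions, 2), rep(c("R", "L"),
                                                   each = 3), sep = "_"))
    generate_voi_counts(targets, 1000, noise_sd = noise_sd,
                        seed = seed0 + i, subject_id = ids[i])
  }))
  list(voi = voi, groups = setNames(groups, ids))
}

test_that("zero-noise percent differences invert the configured reduction exactly", {
  sbrs <- list("HC" = c(caudate = 4.5, ant_putamen = 4.2,
                        post_putamen = 3.8),
               "RBD-N" = c(caudate = 4.5, ant_putamen = 4.2,
                           post_putamen = 3.8) * 0.96,
               "RBD-MMI" = c(caudate = 4.5, ant_putamen = 4.2,
                             post_putamen = 3.8) * 0.70)
  cc <- make_uptake_cohort(c("HC" = 3, "RBD-N" = 3, "RBD-MMI" = 3),
                           sbrs, noise_sd = 0)
  up <- uptake_from_counts(cc$voi)
  s <- summarize_uptake(up, cc$groups)
  pd <- s$percent_diff
  expect_equal(pd$percent_diff[pd$group == "RBD-MMI"], rep(30, 6),
               tolerance = 1e-9)
  expect_equal(pd$percent_diff[pd$group == "RBD-N"], rep(4, 6),
               tolerance = 1e-9)
})

test_that("percent difference is computed from group means (hand example)", {
  voi <- rbind(
    generate_voi_counts(setNames(rep(4, 6),
                                 paste(rep(c("caudate", "ant_putamen",
                                             "post_putamen"), 2),
                                       rep(c("R", "L"), each = 3),
                                       sep = "_")), 1000, 0,
                        subject_id = "H1"),
    generate_voi_counts(setNames(rep(4, 6),
                                 paste(rep(c("caudate", "ant_putamen",
                                             "post_putamen"), 2),
                                       rep(c("R", "L"), each = 3),
                                       sep = "_")), 1000, 0,
                        subject_id = "H2"),
    generate_voi_counts(setNames(rep(3, 6),
                                 paste(rep(c("caudate", "ant_putamen",
                                             "post_putamen"), 2),
                                       rep(c("R", "L"), each = 3),
                                       sep = "_")), 1000, 0,
                        subject_id = "P1"),
    generate_voi_counts(setNames(rep(3, 6),
                                 paste(rep(c("caudate", "ant_putamen",
                                             "post_putamen"), 2),
                                       rep(c("R", "L"), each = 3),
                                       sep = "_")), 1000, 0,
                        subject_id = "P2"))
  up <- uptake_from_counts(voi)
  s <- summarize_uptake(up, c(H1 = "HC", H2 = "HC",
                              P1 = "RBD-MMI", P2 = "RBD-MMI"))
  expect_equal(unique(s$percent_diff$percent_diff), 25, tolerance = 1e-9)
})

test_that("default generator preserves the graded reduction ordering", {
  sbr_tab <- default_sbr_means()
  by_group <- split(sbr_tab, sbr_tab$group)
  sbrs <- lapply(by_group, function(d) {
    out <- tapply(d$sbr, d$region, mean)
    out[c("caudate", "ant_putamen", "post_putamen")]
  })
  cc <- make_uptake_cohort(c("HC" = 100, "RBD-N" = 100, "RBD-MMI" = 100),
                           sbrs, noise_sd = 0.35, seed0 = 50)
  s <- summarize_uptake(uptake_from_counts(cc$voi), cc$groups)
  pd <- s$percent_diff[s$percent_diff$group == "RBD-MMI", ]
  by_region <- tapply(pd$percent_diff, pd$region, mean)
  expect_gt(by_region[["post_putamen"]], by_region[["ant_putamen"]])
  expect_gt(by_region[["ant_putamen"]], by_region[["caudate"]])
})

test_that("identically distributed groups rarely reach Tukey significance", {
  sbrs <- list("HC" = c(caudate = 4, ant_putamen = 4, post_putamen = 4),
               "RBD-N" = c(caudate = 4, ant_putamen = 4, post_putamen = 4),
               "RBD-MMI" = c(caudate = 4, ant_putamen = 4,
                             post_putamen = 4))
  n_sig <- 0L; n_tot <- 0L
  for (rep in 1:40) {
    cc <- make_uptake_cohort(c("HC" = 10, "RBD-N" = 10, "RBD-MMI" = 10),
                             sbrs, noise_sd = 0.3, seed0 = 1000 * rep)
    s <- summarize_uptake(uptake_from_counts(cc$voi), cc$groups)
    n_sig <- n_sig + sum(s$tukey_sbr$p_adj < 0.05)
    n_tot <- n_tot + nrow(s$tukey_sbr)
  }
  expect_lt(n_sig / n_tot, 0.10)
})
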
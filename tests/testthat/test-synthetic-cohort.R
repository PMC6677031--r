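test_that("cohort generation honours configured counts and is seed-deterministic", {
  cfg <- make_fixtures("tiny", seed = 7)
  cfg$n_per_group <- c("HC" = 4, "RBD-N" = 3, "RBD-MMI" = 2)
  co <- generate_cohort(cfg)
  expect_equal(as.vector(table(co$subjects$group)[c("HC", "RBD-N",
                                                    "RBD-MMI")]),
               c(4L, 3L, 2L))
  expect_length(co$waveforms, 9)
  expect_true(all(vapply(co$waveforms, function(w)
    setequal(names(w), c("L", "R")), logical(1))))
  # one VOI table (7 rows) and one ROI matrix per subject
  expect_equal(nrow(co$voi_counts), 9 * 7)
  expect_length(co$roi_timeseries, 9)

  co2 <- generate_cohort(cfg)
  expect_identical(co, co2)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(cohort_config(n_per_group = c("HC" = 0, "RBD-N" = 3,
                                             "RBD-MMI" = 3)),
               "n_per_group")
  expect_error(cohort_config(sampling_rate = 20), "sampling_rate")
  expect_error(cohort_config(n_volumes = 5), "n_volumes")
  bad_fc <- default_fc_targets()
  bad_fc[["HC"]][1, 2] <- 0.9   # asymmetric
  expect_error(cohort_config(fc_target_matrix_by_group = bad_fc),
               "symmetric")
})

test_that("tap waveform generator matches its closed forms", {
  rec <- generate_tap_waveform(60, 3, 15, slope = 0, noise_sd = 0,
                               sampling_rate = 200)
  # peak-to-trough excursion is the configured amplitude exactly
  expect_equal(max(rec$distance) - min(rec$distance), 60, tolerance = 1e-9)
  # complete cycles = duration * frequency
  truth <- attr(rec, "cycles")
  expect_equal(sum(cumsum(truth$duration_s) <= 15 + 1e-9), 45)
  expect_true(all(rec$distance >= 0))
  expect_error(generate_tap_waveform(-5, 3, 15), "amplitude")
  expect_error(generate_tap_waveform(60, 3, -1), "duration")
})

test_that("amplitude decrement lowers successive cycle excursions by the slope", {
  rec <- generate_tap_waveform(60, 3, 15, slope = -1, noise_sd = 0)
  res <- tap_kinematics(rec)
  d <- diff(res$cycles$amplitude)
  expect_equal(mean(d), -1, tolerance = 0.02)
  expect_true(all(abs(d + 1) < 0.2))
})

test_that("VOI count generation inverts the SBR definition", {
  targets <- c(caudate_L = 1.0, caudate_R = 0, post_putamen_L = 0.5,
               post_putamen_R = 2.2, ant_putamen_L = 1.4,
               ant_putamen_R = 1.1)
  tab <- generate_voi_counts(targets, cerebellar_count = 1000,
                             noise_sd = 0)
  expect_equal(tab$mean_count[tab$region == "caudate" & tab$side == "L"],
               2000)
  expect_equal(tab$mean_count[tab$region == "caudate" & tab$side == "R"],
               1000)
  up <- uptake_from_counts(tab)
  m <- match(paste(up$sbr$region, up$sbr$side, sep = "_"), names(targets))
  expect_equal(up$sbr$sbr, unname(targets[m]), tolerance = 1e-12)
  expect_error(generate_voi_counts(targets, cerebellar_count = 0),
               "cerebellar")
})

test_that("VOI count noise propagates to SBR at the configured SD", {
  targets <- c(post_putamen_L = 1.5, post_putamen_R = 1.5,
               ant_putamen_L = 1.5, ant_putamen_R = 1.5,
               caudate_L = 1.5, caudate_R = 1.5)
  sbrs <- vapply(1:2000, function(i) {
    tab <- generate_voi_counts(targets, 1000, noise_sd = 0.1, seed = i)
    uptake_from_counts(tab)$sbr$sbr
  }, numeric(6))
  expect_equal(sd(as.vector(sbrs)), 0.1, tolerance = 0.05)
  expect_equal(mean(sbrs), 1.5, tolerance = 0.01)
})

test_that("ROI time-series generator respects the target correlation", {
  # null target: off-diagonal sample correlations are O(1/sqrt(T))
  id4 <- diag(4); dimnames(id4) <- list(letters[1:4], letters[1:4])
  x <- generate_roi_timeseries(id4, n_volumes = 2000, seed = 3)
  rr <- cor(x)
  expect_lt(max(abs(rr[upper.tri(rr)])), 4 / sqrt(2000))

  # degenerate PSD case: duplicated ROI stays perfectly correlated
  dup <- matrix(c(1, 1, 1, 1), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  y <- generate_roi_timeseries(dup, 50, seed = 4)
  expect_equal(cor(y)[1, 2], 1, tolerance = 1e-12)

  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(generate_roi_timeseries(bad, 50), "eigenvalue")
})

test_that("lowering a group's amplitude mean cannot raise its extracted mean (replicate average)", {
  extract_mmi_mean <- function(amp_r) {
    means <- numeric(10)
    for (s in 1:10) {
      cfg <- make_fixtures("tiny", seed = 100 + s)
      cfg$n_per_group <- c("HC" = 1, "RBD-N" = 1, "RBD-MMI" = 2)
      cfg$amplitude_mean_by_group_side["RBD-MMI", "R"] <- amp_r
      co <- generate_cohort(cfg)
      ids <- co$subjects$subject_id[co$subjects$group == "RBD-MMI"]
      means[s] <- mean(vapply(ids, function(id)
        tap_kinematics(co$waveforms[[id]][["R"]])$summary$mean_amplitude,
        numeric(1)))
    }
    mean(means)
  }
  expect_gt(extract_mmi_mean(45), extract_mmi_mean(30))
})

test_that("written cohorts round-trip through the CSV layout", {
  cfg <- make_fixtures("tiny", seed = 5)
  cfg$n_per_group <- c("HC" = 3, "RBD-N" = 1, "RBD-MMI" = 1)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort_manifest.json")))
  back <- read_cohort(dir)
  expect_equal(back$subjects$subject_id, co$subjects$subject_id)
  id <- co$subjects$subject_id[1]
  expect_equal(back$waveforms[[id]]$R$distance,
               co$waveforms[[id]]$R$distance, tolerance = 1e-9)
  expect_equal(as.vector(back$roi_timeseries[[id]]),
               as.vector(co$roi_timeseries[[id]]), tolerance = 1e-9)
})
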
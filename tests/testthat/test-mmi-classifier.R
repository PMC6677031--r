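make_summary_row <- function(id, hand, amp = 60, open = 0.6, close = 0.6,
                             s_amp = -0.2, s_open = -0.01,
                             s_close = -0.01) {
  data.frame(subject_id = id, hand = hand, n_cycles = 45,
             mean_amplitude = amp, mean_peak_open_speed = open,
             mean_peak_close_speed = close, slope_amplitude = s_amp,
             slope_open_speed = s_open, slope_close_speed = s_close,
             speed_source = "derived", stringsAsFactors = FALSE)
}

hc_summaries <- function(amps_r = c(50, 60, 70)) {
  do.call(rbind, lapply(seq_along(amps_r), function(i) {
    rbind(make_summary_row(paste0("HC", i), "R", amp = amps_r[i],
                           open = 0.5 + 0.1 * i, close = 0.5 + 0.1 * i,
                           s_amp = -0.1 * i, s_open = -0.005 * i,
                           s_close = -0.005 * i),
          make_summary_row(paste0("HC", i), "L", amp = amps_r[i] - 5,
                           open = 0.45 + 0.1 * i, close = 0.45 + 0.1 * i,
                           s_amp = -0.1 * i, s_open = -0.005 * i,
                           s_close = -0.005 * i))
  }))
}

test_that("normative fitting uses sample SD and the 2-SD cutoff rule", {
  m <- fit_normative_model(hc_summaries())
  row <- m[m$parameter == "amplitude" & m$side == "R", ]
  expect_equal(row$mean, 60)
  expect_equal(row$sd, 10)        # n-1 denominator
  expect_equal(row$cutoff, 40)
  expect_equal(attr(m, "n_hc"), 3L)

  # slope cutoff follows the same rule: mean - 2 * SD
  stats <- data.frame(expand.grid(parameter = c("amplitude", "open_speed",
                                                "close_speed"),
                                  side = c("L", "R"),
                                  stringsAsFactors = FALSE),
                      mean = 60, sd = 10,
                      slope_mean = -0.17, slope_sd = 0.28)
  m2 <- normative_model(stats)
  expect_equal(m2$slope_cutoff[1], -0.73)

  ident <- hc_summaries(c(60, 60, 60))
  expect_error(fit_normative_model(ident), "zero variance")
})

test_that("subjects missing a hand are excluded from fitting with a warning", {
  s <- hc_summaries(c(50, 60, 70, 55))
  s <- s[!(s$subject_id == "HC4" & s$hand == "L"), ]
  expect_warning(m <- fit_normative_model(s), "missing a hand")
  expect_equal(attr(m, "n_hc"), 3L)
})

test_that("classification uses strict inequality and the >= 1 flag rule", {
  model <- population_model(mean = 60, sd = 10)
  at_mean <- data.frame(subject_id = "A", amplitude_L = 60,
                        amplitude_R = 60, open_speed_L = 60,
                        open_speed_R = 60, close_speed_L = 60,
                        close_speed_R = 60)
  r <- classify_values(at_mean, model)
  expect_false(r$is_mmi)
  expect_equal(r$n_flags, 0L)

  one_low <- at_mean
  one_low$amplitude_R <- 60 - 2.5 * 10
  r <- classify_values(one_low, model)
  expect_true(r$is_mmi)
  expect_equal(r$n_flags, 1L)
  expect_true(r$flag_amplitude_R)

  # exactly at the cutoff is NOT flagged ("less than" is strict)
  at_cut <- at_mean
  at_cut[, -1] <- 60 - 2 * 10
  r <- classify_values(at_cut, model)
  expect_false(r$is_mmi)
  expect_equal(r$n_flags, 0L)
})

test_that("decreasing any parameter never un-flags a subject", {
  model <- population_model(mean = 0, sd = 1)
  set.seed(9)
  cols <- paste0(rep(c("amplitude", "open_speed", "close_speed"), 2),
                 "_", rep(c("L", "R"), each = 3))
  for (i in 1:50) {
    vals <- setNames(as.list(rnorm(6, 0, 1.5)), cols)
    wide <- data.frame(subject_id = "S", vals)
    before <- classify_values(wide, model)$is_mmi
    j <- sample(cols, 1)
    wide[[j]] <- wide[[j]] - runif(1, 0, 3)
    after <- classify_values(wide, model)$is_mmi
    expect_true(!before || after)
  }
})

test_that("the decrement criterion is independent of the value criterion", {
  stats <- data.frame(expand.grid(parameter = c("amplitude", "open_speed",
                                                "close_speed"),
                                  side = c("L", "R"),
                                  stringsAsFactors = FALSE),
                      mean = 60, sd = 10, slope_mean = -0.2,
                      slope_sd = 0.1)
  model <- normative_model(stats)
  s <- rbind(make_summary_row("P1", "L", amp = 60, s_amp = -1),
             make_summary_row("P1", "R", amp = 60, s_amp = -1))
  s[c("mean_peak_open_speed", "mean_peak_close_speed")] <- 60
  s[c("slope_open_speed", "slope_close_speed")] <- -0.2
  r <- classify_subject(s, model)
  expect_false(r$is_mmi)                       # values at the means
  expect_true(r$has_progressive_decrement)     # slope far below cutoff
})

test_that("cohort classification fits on HC only and reassigns RBD groups", {
  hc <- hc_summaries()
  rbd <- rbind(make_summary_row("P1", "L", amp = 20),  # far below cutoff
               make_summary_row("P1", "R", amp = 20),
               make_summary_row("P2", "L", amp = 60, open = 0.6,
                                close = 0.6),
               make_summary_row("P2", "R", amp = 60, open = 0.6,
                                close = 0.6))
  groups <- c(HC1 = "HC", HC2 = "HC", HC3 = "HC",
              P1 = "RBD-N", P2 = "RBD-N")
  res <- classify_cohort(rbind(hc, rbd), groups)
  cl <- res$classification
  expect_equal(cl$group_observed[cl$subject_id == "P1"], "RBD-MMI")
  expect_equal(cl$group_observed[cl$subject_id == "P2"], "RBD-N")
  expect_false("HC1" %in% cl$subject_id)  # HC never reassigned

  # zero RBD subjects: empty classification, no error
  res0 <- classify_cohort(hc, c(HC1 = "HC", HC2 = "HC", HC3 = "HC"))
  expect_equal(nrow(res0$classification), 0L)

  expect_error(classify_cohort(rbd, c(P1 = "RBD-N", P2 = "RBD-N")),
               "no HC")
})

test_that("normative models survive a JSON round trip", {
  m <- fit_normative_model(hc_summaries())
  path <- withr::local_tempfile(fileext = ".json")
  write_normative_model(m, path)
  m2 <- read_normative_model(path)
  expect_equal(as.data.frame(m), as.data.frame(m2), tolerance = 1e-12)
})
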
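#' Build a synthetic cohort configuration
#'
#' Assembles the full set of generator parameters: group sizes, tapping
#' waveform parameters (amplitude by group and side, tap frequency,
#' open/close speed scales, decrement-slope distributions, sensor noise),
#' striatal specific-binding-ratio (SBR) means with noise, ROI
#' connectivity targets, and the demographics/clinical-score spec.
#' Defaults encode the study conditions the package emulates: 20/15/8
#' subjects (HC / RBD-N / RBD-MMI), 15-s taps at 200 Hz, 180 BOLD volumes
#' at TR 2.5 s, graded striatal reduction and Table-4-style connectivity
#' effects.
#'
#' @param n_per_group named integer vector with entries `HC`, `RBD-N`,
#'   `RBD-MMI`; each must be >= 1.
#' @param seed integer master seed; all generator randomness derives from
#'   it.
#' @param sampling_rate tap waveform sampling rate, Hz (>= 50).
#' @param tap_duration_s tap recording length, seconds.
#' @param tap_frequency_mean,tap_frequency_sd per-subject tap frequency
#'   distribution, Hz.
#' @param amplitude_mean_by_group_side 3x2 matrix (rows: groups, cols
#'   `R`,`L`) of mean tap amplitudes in mm.
#' @param amplitude_sd between-subject amplitude SD, mm.
#' @param open_speed_scale,close_speed_scale named per-group multipliers
#'   on the sinusoid-implied peak speed (amplitude * pi * frequency).
#' @param slope_mean_by_group,slope_sd_by_group per-group decrement-slope
#'   distributions; each is a list with elements `amplitude`,
#'   `open_speed`, `close_speed`, each a named `c(R=, L=)` vector
#'   (mm/cycle for amplitude, (m/s)/cycle for speeds).
#' @param noise_sd_distance additive Gaussian sensor noise on distance, mm.
#' @param sbr_mean_by_group_region_side data.frame with columns group,
#'   region, side, sbr (see [default_sbr_means()]).
#' @param sbr_noise_sd between-subject SBR SD (dimensionless).
#' @param cerebellar_count_mean mean cerebellar reference VOI count.
#' @param fc_target_matrix_by_group named list of ROI correlation
#'   matrices, one per group (see [default_fc_targets()]).
#' @param n_volumes number of BOLD volumes per subject (>= 10).
#' @param tr repetition time, seconds.
#' @param demographics_spec demographics/clinical-score spec (see
#'   [default_demographics_spec()]).
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_per_group = c("HC" = 20, "RBD-N" = 15,
                                          "RBD-MMI" = 8),
                          seed = 1L,
                          sampling_rate = 200,
                          tap_duration_s = 15,
                          tap_frequency_mean = 3.2,
                          tap_frequency_sd = 0.35,
                          amplitude_mean_by_group_side = NULL,
                          amplitude_sd = 9,
                          open_speed_scale = c("HC" = 1, "RBD-N" = 1,
                                               "RBD-MMI" = 0.85),
                          close_speed_scale = c("HC" = 1, "RBD-N" = 1,
                                                "RBD-MMI" = 0.75),
                          slope_mean_by_group = NULL,
                          slope_sd_by_group = NULL,
                          noise_sd_distance = 0.5,
                          sbr_mean_by_group_region_side = default_sbr_means(),
                          sbr_noise_sd = 0.35,
                          cerebellar_count_mean = 1000,
                          fc_target_matrix_by_group = NULL,
                          n_volumes = 180,
                          tr = 2.5,
                          demographics_spec = default_demographics_spec()) {
  groups <- tapmark_groups()
  if (is.null(amplitude_mean_by_group_side)) {
    amplitude_mean_by_group_side <- matrix(
      c(60, 55,   # HC  R, L
        58, 54,   # RBD-N
        38, 35),  # RBD-MMI
      nrow = 3, byrow = TRUE,
      dimnames = list(groups, c("R", "L")))
  }
  slope_def <- default_slope_spec()
  if (is.null(slope_mean_by_group))
    slope_mean_by_group <- setNames(rep(list(slope_def$mean), 3), groups)
  if (is.null(slope_sd_by_group))
    slope_sd_by_group <- setNames(rep(list(slope_def$sd), 3), groups)
  if (is.null(fc_target_matrix_by_group))
    fc_target_matrix_by_group <- default_fc_targets()

  cfg <- structure(list(
    n_per_group = n_per_group,
    seed = as.integer(seed),
    sampling_rate = sampling_rate,
    tap_duration_s = tap_duration_s,
    tap_frequency_mean = tap_frequency_mean,
    tap_frequency_sd = tap_frequency_sd,
    amplitude_mean_by_group_side = amplitude_mean_by_group_side,
    amplitude_sd = amplitude_sd,
    open_speed_scale = open_speed_scale,
    close_speed_scale = close_speed_scale,
    slope_mean_by_group = slope_mean_by_group,
    slope_sd_by_group = slope_sd_by_group,
    noise_sd_distance = noise_sd_distance,
    sbr_mean_by_group_region_side = sbr_mean_by_group_region_side,
    sbr_noise_sd = sbr_noise_sd,
    cerebellar_count_mean = cerebellar_count_mean,
    fc_target_matrix_by_group = fc_target_matrix_by_group,
    n_volumes = n_volumes,
    tr = tr,
    demographics_spec = demographics_spec
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks the generator invariants (group labels and counts, SD
#' non-negativity, correlation-matrix symmetry/unit-diagonal/positive
#' semidefiniteness, minimum sampling rate and volume count) and errors
#' naming the offending field.
#'
#' @param cfg a `cohort_config`.
#' @return the config, invisibly, if valid.
#' @export
validate_cohort_config <- function(cfg) {
  groups <- tapmark_groups()
  n <- cfg$n_per_group
  if (!setequal(names(n), groups))
    stop_config("n_per_group", "names must be exactly HC, RBD-N, RBD-MMI")
  if (any(!is.finite(n)) || any(n < 1) || any(n != round(n)))
    stop_config("n_per_group", "counts must be integers >= 1")
  if (!is.finite(cfg$sampling_rate) || cfg$sampling_rate < 50)
    stop_config("sampling_rate", "must be >= 50 Hz")
  if (cfg$tap_duration_s <= 0)
    stop_config("tap_duration_s", "must be positive")
  if (cfg$tap_frequency_mean <= 0.5 || cfg$tap_frequency_mean >= 8)
    stop_config("tap_frequency_mean", "must be in (0.5, 8) Hz")
  for (f in c("tap_frequency_sd", "amplitude_sd", "noise_sd_distance",
              "sbr_noise_sd"))
    if (cfg[[f]] < 0) stop_config(f, "SD must be >= 0")
  amp <- cfg$amplitude_mean_by_group_side
  if (!all(rownames(amp) == groups) || !setequal(colnames(amp), c("R", "L")))
    stop_config("amplitude_mean_by_group_side",
                "needs rows HC/RBD-N/RBD-MMI and columns R, L")
  if (any(amp <= 0))
    stop_config("amplitude_mean_by_group_side", "amplitudes must be > 0")
  if (cfg$n_volumes < 10)
    stop_config("n_volumes", "must be >= 10")
  if (cfg$tr <= 0) stop_config("tr", "must be positive")
  if (cfg$cerebellar_count_mean <= 0)
    stop_config("cerebellar_count_mean", "must be positive")
  fc <- cfg$fc_target_matrix_by_group
  if (!setequal(names(fc), groups))
    stop_config("fc_target_matrix_by_group", "must have one matrix per group")
  for (g in groups) {
    m <- fc[[g]]
    if (!isSymmetric(unname(m), tol = 1e-10))
      stop_config("fc_target_matrix_by_group",
                  sprintf("matrix for %s is not symmetric", g))
    if (any(abs(diag(m) - 1) > 1e-10))
      stop_config("fc_target_matrix_by_group",
                  sprintf("matrix for %s does not have a unit diagonal", g))
    ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      stop_config("fc_target_matrix_by_group",
                  sprintf("matrix for %s is not positive semidefinite (min eigenvalue %.3g)",
                          g, ev))
  }
  sbr <- cfg$sbr_mean_by_group_region_side
  need <- c("group", "region", "side", "sbr")
  if (!all(need %in% names(sbr)))
    stop_config("sbr_mean_by_group_region_side",
                "needs columns group, region, side, sbr")
  if (any(sbr$sbr <= -1))
    stop_config("sbr_mean_by_group_region_side", "SBR must be > -1")
  invisible(cfg)
}

#' Generate one finger-tapping distance waveform
#'
#' The base waveform is a train of raised-cosine half-cycles: cycle k has
#' peak-to-trough excursion `amplitude + slope * (k - 1)` (clipped below at
#' a small positive floor) above a constant baseline `dist_floor`.  Each
#' cycle is split into an opening and a closing phase whose durations are
#' chosen so that the peak opening/closing speeds hit their per-cycle
#' targets; with all scales at 1 and no slopes this reduces to a pure
#' raised cosine with peak speed `amplitude * pi * frequency` (mm/s) and
#' cycle period `1 / frequency`.  `open_close_asymmetry` multiplies the
#' closing-phase peak speed so closing can be faster (or slower) than
#' opening.  Gaussian noise is added to the distance and the result is
#' clamped at zero (distances are physical separations).
#'
#' @param amplitude first-cycle excursion, mm (> 0).
#' @param frequency nominal tap frequency, Hz, in (0.5, 8).
#' @param duration recording length, seconds (> 0).
#' @param slope amplitude decrement, mm/cycle (negative = decrement).
#' @param noise_sd additive distance noise SD, mm.
#' @param open_close_asymmetry ratio of closing to opening peak speed.
#' @param sampling_rate samples per second.
#' @param seed integer seed for the noise draw.
#' @param subject_id,hand identifiers carried on the recording.
#' @param dist_floor baseline thumb-index separation at full closure, mm.
#' @param open_speed_scale,close_speed_scale multipliers on the
#'   sinusoid-implied peak speed.
#' @param open_speed_slope,close_speed_slope additional per-cycle linear
#'   trends on the peak speed targets, (m/s)/cycle.
#' @return object of class `tap_recording`: list with `subject_id`,
#'   `hand`, `sampling_rate`, `duration`, `time`, `distance` (mm) and a
#'   `cycles` attribute table of generator ground truth (per-cycle
#'   amplitude and peak-speed targets).
#' @export
generate_tap_waveform <- function(amplitude, frequency, duration,
                                  slope = 0, noise_sd = 0,
                                  open_close_asymmetry = 1,
                                  sampling_rate = 200, seed = 1L,
                                  subject_id = "S001", hand = "R",
                                  dist_floor = 3,
                                  open_speed_scale = 1,
                                  close_speed_scale = 1,
                                  open_speed_slope = 0,
                                  close_speed_slope = 0) {
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("amplitude must be positive", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (frequency <= 0.5 || frequency >= 8)
    stop("frequency must be in (0.5, 8) Hz", call. = FALSE)
  if (open_close_asymmetry <= 0)
    stop("open_close_asymmetry must be positive", call. = FALSE)

  amp_floor <- 1          # mm, clip for decremented cycles
  speed_floor <- 5        # mm/s, keep per-cycle targets physical

  # enough cycles to cover the recording even when cycles lengthen
  n_cyc <- ceiling(duration * frequency * 3) + 5L
  k <- seq_len(n_cyc)
  a_k <- pmax(amplitude + slope * (k - 1), amp_floor)
  v_open <- pmax(open_speed_scale * a_k * pi * frequency +
                   1000 * open_speed_slope * (k - 1), speed_floor)
  v_close <- pmax(close_speed_scale * open_close_asymmetry * a_k * pi *
                    frequency + 1000 * close_speed_slope * (k - 1),
                  speed_floor)
  # half-cycle durations hitting the peak-speed targets exactly
  t_open <- a_k * pi / (2 * v_open)
  t_close <- a_k * pi / (2 * v_close)

  # interleave opening/closing segments
  seg_dur <- as.vector(rbind(t_open, t_close))
  seg_amp <- as.vector(rbind(a_k, a_k))
  seg_opening <- rep(c(TRUE, FALSE), n_cyc)
  seg_start <- c(0, cumsum(seg_dur))[seq_along(seg_dur)]

  n <- round(duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  j <- findInterval(t, seg_start)
  j[j < 1L] <- 1L
  j[j > length(seg_dur)] <- length(seg_dur)
  tau <- t - seg_start[j]
  phase <- pmin(tau / seg_dur[j], 1)
  d <- ifelse(seg_opening[j],
              dist_floor + (seg_amp[j] / 2) * (1 - cos(pi * phase)),
              dist_floor + (seg_amp[j] / 2) * (1 + cos(pi * phase)))
  if (noise_sd > 0)
    d <- d + with_seed(seed, rnorm(n, 0, noise_sd))
  d <- pmax(d, 0)

  truth <- data.frame(cycle = k, amplitude = a_k,
                      peak_open_speed = v_open / 1000,
                      peak_close_speed = v_close / 1000,
                      duration_s = t_open + t_close)
  structure(list(subject_id = subject_id, hand = hand,
                 sampling_rate = sampling_rate, duration = duration,
                 time = t, distance = d, speed = NULL,
                 speed_source = "none"),
            class = "tap_recording", cycles = truth)
}

#' Generate a striatal/cerebellar VOI count table from target SBR values
#'
#' Inverts the specific-binding-ratio definition: each striatal VOI mean
#' count is `cerebellar_count * (1 + SBR + e)` with `e ~ N(0, noise_sd)`,
#' so recomputing SBR from the table with zero noise returns the configured
#' values exactly.
#'
#' @param sbr_by_region_side named numeric vector, names `region_side`
#'   (e.g. `caudate_L`, `post_putamen_R`); all values > -1.
#' @param cerebellar_count mean cerebellar reference count (> 0).
#' @param noise_sd SD of the additive SBR noise.
#' @param seed integer seed.
#' @param subject_id identifier attached to every row.
#' @return data.frame with columns subject_id, region, side, mean_count;
#'   six striatal rows plus one cerebellum row (side `NA`).
#' @export
generate_voi_counts <- function(sbr_by_region_side, cerebellar_count,
                                noise_sd = 0, seed = 1L,
                                subject_id = "S001") {
  if (!is.finite(cerebellar_count) || cerebellar_count <= 0)
    stop("cerebellar_count must be positive", call. = FALSE)
  if (any(sbr_by_region_side <= -1))
    stop("target SBR values must be > -1", call. = FALSE)
  nm <- names(sbr_by_region_side)
  if (is.null(nm) || any(!grepl("_(L|R)$", nm)))
    stop("sbr_by_region_side names must end in _L or _R", call. = FALSE)
  side <- sub("^.*_(L|R)$", "\\1", nm)
  region <- sub("_(L|R)$", "", nm)
  eps <- if (noise_sd > 0)
    with_seed(seed, rnorm(length(nm), 0, noise_sd)) else 0
  counts <- cerebellar_count * (1 + sbr_by_region_side + eps)
  out <- data.frame(subject_id = subject_id,
                    region = c(region, "cerebellum"),
                    side = c(side, NA_character_),
                    mean_count = c(counts, cerebellar_count),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate a multivariate ROI time-series matrix
#'
#' Zero-mean multivariate Gaussian draws with the given target correlation
#' matrix, one row per volume; the expected sample correlation equals the
#' target.
#'
#' @param target_correlation symmetric positive-semidefinite matrix with
#'   unit diagonal; dimnames give the ROI labels.
#' @param n_volumes number of rows (>= 10).
#' @param seed integer seed.
#' @return numeric matrix `n_volumes x n_roi` with ROI column names.
#' @export
generate_roi_timeseries <- function(target_correlation, n_volumes,
                                    seed = 1L) {
  m <- as.matrix(target_correlation)
  if (!isSymmetric(unname(m), tol = 1e-10))
    stop("target correlation matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(m) - 1) > 1e-10))
    stop("target correlation matrix must have a unit diagonal",
         call. = FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("target matrix is not positive semidefinite (min eigenvalue %.3g)",
                 min(ev)), call. = FALSE)
  if (n_volumes < 10) stop("n_volumes must be >= 10", call. = FALSE)
  x <- with_seed(seed,
                 MASS::mvrnorm(n_volumes, mu = rep(0, ncol(m)), Sigma = m,
                               tol = 1e-6))
  colnames(x) <- colnames(m)
  x
}

#' Generate a complete synthetic cohort
#'
#' Draws the subjects table (demographics, clinical scores,
#' polysomnographic measures, head motion), two tapping waveforms per
#' subject, one VOI count table per subject and one ROI time-series matrix
#' per subject, with group effects taken from the configuration.  The
#' output is a pure function of the configuration (including its seed).
#'
#' @param config a [cohort_config()].
#' @return object of class `tap_cohort`: list with elements `subjects`
#'   (data.frame), `waveforms` (per subject, lists with `L` and `R`
#'   [generate_tap_waveform()] recordings), `voi_counts` (long
#'   data.frame), `roi_timeseries` (per-subject matrices), `roi_labels`,
#'   and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  groups <- tapmark_groups()
  n <- config$n_per_group[groups]
  prefix <- c("HC" = "HC", "RBD-N" = "RBDN", "RBD-MMI" = "RBDMMI")
  spec <- config$demographics_spec

  subj <- do.call(rbind, lapply(groups, function(g) {
    data.frame(subject_id = sprintf("%s_%02d", prefix[[g]],
                                    seq_len(n[[g]])),
               group = g, stringsAsFactors = FALSE)
  }))
  rownames(subj) <- NULL
  ns <- nrow(subj)

  # --- demographics ------------------------------------------------------
  subj$age <- NA_real_
  subj$sex <- NA_character_
  for (g in groups) {
    idx <- which(subj$group == g)
    arow <- spec$age[spec$age$group == g, ]
    subj$age[idx] <- round(with_seed(child_seed(config$seed, 11 + match(g, groups)),
                                     rtrunc_norm(length(idx), arow$mean,
                                                 arow$sd, 40, 95)), 1)
    n_male <- round(length(idx) * spec$p_male[[g]])
    subj$sex[idx] <- c(rep("M", n_male), rep("F", length(idx) - n_male))
  }

  # clinical scores (integer scales, truncated at their ranges)
  cl <- spec$clinical
  for (v in unique(cl$variable)) {
    subj[[v]] <- NA_real_
    for (g in groups) {
      idx <- which(subj$group == g)
      row <- cl[cl$variable == v & cl$group == g, ]
      sd_use <- max(row$sd, 1e-8)
      draw <- with_seed(child_seed(config$seed,
                                   100 + 10 * match(v, unique(cl$variable)) +
                                     match(g, groups)),
                        rtrunc_norm(length(idx), row$mean, sd_use,
                                    row$lower, row$upper))
      subj[[v]][idx] <- round(draw)
    }
  }

  # motor-exam items as small integer scores
  it <- spec$updrs_items
  for (item in unique(it$item)) {
    col <- paste0("updrs_item_", item)
    subj[[col]] <- NA_integer_
    for (g in groups) {
      idx <- which(subj$group == g)
      m <- it$mean[it$item == item & it$group == g]
      subj[[col]][idx] <- with_seed(
        child_seed(config$seed, 300 + 10 * match(item, unique(it$item)) +
                     match(g, groups)),
        rbinom(length(idx), 2L, min(m / 2, 1)))
    }
  }

  # polysomnography and disease duration: RBD groups only
  psg <- spec$psg
  for (v in unique(psg$variable)) {
    subj[[v]] <- NA_real_
    for (g in c("RBD-N", "RBD-MMI")) {
      idx <- which(subj$group == g)
      row <- psg[psg$variable == v & psg$group == g, ]
      subj[[v]][idx] <- round(with_seed(
        child_seed(config$seed, 500 + 10 * match(v, unique(psg$variable)) +
                     match(g, groups)),
        rtrunc_norm(length(idx), row$mean, row$sd, row$lower, row$upper)), 1)
    }
  }
  subj$disease_duration_y <- NA_real_
  for (g in c("RBD-N", "RBD-MMI")) {
    idx <- which(subj$group == g)
    row <- spec$disease_duration[spec$disease_duration$group == g, ]
    subj$disease_duration_y[idx] <- round(with_seed(
      child_seed(config$seed, 700 + match(g, groups)),
      rtrunc_norm(length(idx), row$mean, row$sd, 0.5, Inf)), 1)
  }
  subj$head_motion_fd <- NA_real_
  for (g in groups) {
    idx <- which(subj$group == g)
    row <- spec$head_motion_fd[spec$head_motion_fd$group == g, ]
    subj$head_motion_fd[idx] <- round(with_seed(
      child_seed(config$seed, 710 + match(g, groups)),
      rtrunc_norm(length(idx), row$mean, row$sd, 0.005, Inf)), 4)
  }

  # --- tapping waveforms -------------------------------------------------
  amp_m <- config$amplitude_mean_by_group_side
  slope_m <- config$slope_mean_by_group
  slope_s <- config$slope_sd_by_group
  waveforms <- vector("list", ns)
  names(waveforms) <- subj$subject_id
  for (i in seq_len(ns)) {
    g <- subj$group[i]
    s_open <- config$open_speed_scale[[g]]
    s_close <- config$close_speed_scale[[g]]
    pars <- with_seed(child_seed(config$seed, 1000 + i), {
      f <- rtrunc_norm(1, config$tap_frequency_mean,
                       config$tap_frequency_sd, 1.5, 6)
      amps <- setNames(rtrunc_norm(2, amp_m[g, c("R", "L")],
                                   config$amplitude_sd, 8, Inf),
                       c("R", "L"))
      sl <- lapply(tapmark_parameters(), function(p)
        setNames(rnorm(2, slope_m[[g]][[p]][c("R", "L")],
                       slope_s[[g]][[p]][c("R", "L")]), c("R", "L")))
      names(sl) <- tapmark_parameters()
      list(f = f, amps = amps, sl = sl)
    })
    hands <- list()
    for (h in c("L", "R")) {
      a <- pars$amps[[h]]
      # subtract the amplitude-slope-induced speed trend so the configured
      # speed-slope distribution is what the kinematics stage recovers
      induced_open <- s_open * pi * pars$f * pars$sl$amplitude[[h]] / 1000
      induced_close <- s_close * pi * pars$f * pars$sl$amplitude[[h]] / 1000
      hands[[h]] <- generate_tap_waveform(
        amplitude = a, frequency = pars$f,
        duration = config$tap_duration_s,
        slope = pars$sl$amplitude[[h]],
        noise_sd = config$noise_sd_distance,
        open_close_asymmetry = 1,
        sampling_rate = config$sampling_rate,
        seed = child_seed(config$seed, 2000 + 2 * i + (h == "R")),
        subject_id = subj$subject_id[i], hand = h,
        open_speed_scale = s_open, close_speed_scale = s_close,
        open_speed_slope = pars$sl$open_speed[[h]] - induced_open,
        close_speed_slope = pars$sl$close_speed[[h]] - induced_close)
    }
    waveforms[[i]] <- hands
  }

  # --- VOI counts --------------------------------------------------------
  sbr_tab <- config$sbr_mean_by_group_region_side
  voi <- vector("list", ns)
  for (i in seq_len(ns)) {
    g <- subj$group[i]
    rows <- sbr_tab[sbr_tab$group == g, ]
    targets <- setNames(rows$sbr, paste(rows$region, rows$side, sep = "_"))
    cereb <- with_seed(child_seed(config$seed, 4000 + i),
                       rtrunc_norm(1, config$cerebellar_count_mean,
                                   0.05 * config$cerebellar_count_mean,
                                   0.5 * config$cerebellar_count_mean, Inf))
    voi[[i]] <- generate_voi_counts(targets, cereb,
                                    noise_sd = config$sbr_noise_sd,
                                    seed = child_seed(config$seed, 4500 + i),
                                    subject_id = subj$subject_id[i])
  }
  voi_counts <- do.call(rbind, voi)

  # --- ROI time series ---------------------------------------------------
  roi_labels <- colnames(config$fc_target_matrix_by_group[[1]])
  roi_ts <- vector("list", ns)
  names(roi_ts) <- subj$subject_id
  for (i in seq_len(ns)) {
    g <- subj$group[i]
    roi_ts[[i]] <- generate_roi_timeseries(
      config$fc_target_matrix_by_group[[g]], config$n_volumes,
      seed = child_seed(config$seed, 6000 + i))
  }

  structure(list(subjects = subj, waveforms = waveforms,
                 voi_counts = voi_counts, roi_timeseries = roi_ts,
                 roi_labels = roi_labels, config = config),
            class = "tap_cohort")
}

#' Write a synthetic cohort to delimited text files
#'
#' Emits `subjects.csv`, one waveform CSV per hand
#' (`waveforms/<id>_<L|R>.csv` with columns `time_s`, `distance_mm`),
#' `voi_counts.csv`, one ROI time-series CSV per subject
#' (`roi_timeseries/<id>.csv`, one column per ROI), and a JSON manifest
#' listing every emitted path with its MD5 hash and the generator seed.
#'
#' @param cohort a `tap_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "waveforms"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "roi_timeseries"), showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "subjects.csv")
  write.csv(cohort$subjects, p, row.names = FALSE)
  paths <- c(paths, p)
  for (id in names(cohort$waveforms)) {
    for (h in c("L", "R")) {
      rec <- cohort$waveforms[[id]][[h]]
      p <- file.path(dir, "waveforms", sprintf("%s_%s.csv", id, h))
      write.csv(data.frame(time_s = rec$time, distance_mm = rec$distance),
                p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  p <- file.path(dir, "voi_counts.csv")
  write.csv(cohort$voi_counts, p, row.names = FALSE)
  paths <- c(paths, p)
  for (id in names(cohort$roi_timeseries)) {
    p <- file.path(dir, "roi_timeseries", sprintf("%s.csv", id))
    write.csv(as.data.frame(cohort$roi_timeseries[[id]]), p,
              row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    seed = cohort$config$seed,
    sampling_rate = cohort$config$sampling_rate,
    tr = cohort$config$tr,
    files = data.frame(path = sub(paste0("^", dir, "/?"), "", paths),
                       md5 = unname(tools::md5sum(paths)),
                       stringsAsFactors = FALSE)
  )
  mp <- file.path(dir, "cohort_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' Read a tapping waveform CSV
#'
#' @param path CSV with columns `time_s` and `distance_mm`.
#' @param subject_id,hand identifiers; if `NULL`, parsed from the filename
#'   (`<id>_<L|R>.csv`).
#' @return a `tap_recording`.
#' @export
read_waveform_csv <- function(path, subject_id = NULL, hand = NULL) {
  x <- read.csv(path)
  if (!all(c("time_s", "distance_mm") %in% names(x)))
    stop(sprintf("waveform file '%s' lacks time_s/distance_mm columns",
                 path), call. = FALSE)
  if (nrow(x) < 4 || any(!is.finite(x$distance_mm)) ||
      any(x$distance_mm < 0))
    stop(sprintf("waveform file '%s' is corrupt or non-physical", path),
         call. = FALSE)
  base <- sub("\\.csv$", "", basename(path))
  if (is.null(hand)) hand <- sub("^.*_", "", base)
  if (is.null(subject_id)) subject_id <- sub("_[LR]$", "", base)
  dt <- diff(x$time_s)
  fs <- 1 / stats::median(dt)
  structure(list(subject_id = subject_id, hand = hand,
                 sampling_rate = fs,
                 duration = nrow(x) / fs,
                 time = x$time_s, distance = x$distance_mm,
                 speed = NULL, speed_source = "none"),
            class = "tap_recording")
}

#' Read a cohort previously written with [write_cohort()]
#'
#' @param dir directory containing `subjects.csv`, `waveforms/`,
#'   `voi_counts.csv` and `roi_timeseries/`.
#' @return a `tap_cohort` (without a generator config).
#' @export
read_cohort <- function(dir) {
  sp <- file.path(dir, "subjects.csv")
  if (!file.exists(sp))
    stop(sprintf("missing input file '%s'", sp), call. = FALSE)
  subjects <- read.csv(sp, stringsAsFactors = FALSE)
  waveforms <- list()
  for (id in subjects$subject_id) {
    hands <- list()
    for (h in c("L", "R")) {
      wp <- file.path(dir, "waveforms", sprintf("%s_%s.csv", id, h))
      if (!file.exists(wp))
        stop(sprintf("missing waveform file '%s'", wp), call. = FALSE)
      hands[[h]] <- read_waveform_csv(wp, subject_id = id, hand = h)
    }
    waveforms[[id]] <- hands
  }
  vp <- file.path(dir, "voi_counts.csv")
  voi_counts <- if (file.exists(vp))
    read.csv(vp, stringsAsFactors = FALSE) else NULL
  roi_ts <- list()
  td <- file.path(dir, "roi_timeseries")
  if (dir.exists(td)) {
    for (id in subjects$subject_id) {
      tp <- file.path(td, sprintf("%s.csv", id))
      if (file.exists(tp)) roi_ts[[id]] <- as.matrix(read.csv(tp))
    }
  }
  structure(list(subjects = subjects, waveforms = waveforms,
                 voi_counts = voi_counts, roi_timeseries = roi_ts,
                 roi_labels = if (length(roi_ts))
                   colnames(roi_ts[[1]]) else NULL,
                 config = NULL),
            class = "tap_cohort")
}
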
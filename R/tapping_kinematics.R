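# zero-phase filtering with odd-reflection end padding to suppress the
# edge transients of plain forward-backward filtering
filtfilt_padded <- function(filt, x) {
  n <- length(x)
  np <- min(n - 1L, 200L)
  left <- 2 * x[1] - x[(np + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- as.numeric(signal::filtfilt(filt, c(left, x, right)))
  y[(np + 1):(np + n)]
}

#' Smooth a tapping waveform and derive its speed trace
#'
#' Zero-phase low-pass filtering (4th-order Butterworth applied forward
#' and backward) of the thumb-index distance, followed by a central-
#' difference derivative converted to m/s.  If the recording already
#' carries a device-measured speed trace it is kept and flagged as such.
#'
#' @param recording a `tap_recording`.
#' @param cutoff low-pass cutoff, Hz; must be below the Nyquist frequency.
#' @return the recording with smoothed `distance`, a `speed` series (m/s,
#'   signed: positive while opening) and `speed_source` set to `"device"`
#'   or `"derived"`.
#' @export
preprocess_waveform <- function(recording, cutoff = 20) {
  fs <- recording$sampling_rate
  if (cutoff >= fs / 2)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff, fs / 2), call. = FALSE)
  d <- recording$distance
  n <- length(d)
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  sm <- filtfilt_padded(bf, d)
  if (is.null(recording$speed)) {
    v <- numeric(n)
    v[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) * fs / 2
    v[1] <- (sm[2] - sm[1]) * fs
    v[n] <- (sm[n] - sm[n - 1]) * fs
    recording$speed <- v / 1000   # mm/s -> m/s
    recording$speed_source <- "derived"
  } else {
    recording$speed_source <- "device"
  }
  recording$distance <- sm
  recording$preprocessed <- TRUE
  recording
}

# valley prominence: walk out from the candidate to the first lower point
# (or the boundary) on each side; the barrier is the highest point passed;
# prominence is the lower of the two barriers minus the valley value
valley_prominence <- function(d, idx) {
  n <- length(d)
  vapply(idx, function(i) {
    lower_left <- which(d[seq_len(i - 1)] < d[i])
    lstart <- if (length(lower_left)) max(lower_left) + 1L else 1L
    lbar <- max(d[lstart:(i - 1)])
    right <- if (i < n) d[(i + 1):n] else numeric(0)
    lower_right <- which(right < d[i])
    rend <- if (length(lower_right)) i + min(lower_right) - 1L else n
    rbar <- max(d[(i + 1):rend])
    min(lbar, rbar) - d[i]
  }, numeric(1))
}

#' Segment a tapping recording into cycles
#'
#' Cycle boundaries are closing minima (valleys) of the smoothed distance:
#' local minima with prominence at least `min_prominence_frac` of the
#' recording's global excursion and pairwise separation of at least
#' `min_cycle_ms` (deeper valley wins, ties broken by the earlier sample).
#' The first/last samples are accepted as boundary valleys when they sit
#' at valley level, so complete first/last cycles are not lost; partial
#' segments outside the outermost valleys are discarded.  Cycles shorter
#' than `min_cycle_ms` or with excursion below `min_amplitude_mm` are
#' dropped.
#'
#' @param recording a preprocessed `tap_recording`.
#' @param min_cycle_ms minimum cycle duration and valley separation, ms.
#' @param min_amplitude_mm retention floor on the per-cycle excursion, mm.
#' @param min_prominence_frac valley prominence threshold as a fraction of
#'   the global excursion.
#' @return list with `valleys` (sample indices) and `cycles` (data.frame
#'   `cycle`, `start_idx`, `end_idx`, 1-based inclusive bounds).
#' @export
segment_cycles <- function(recording, min_cycle_ms = 100,
                           min_amplitude_mm = 5,
                           min_prominence_frac = 0.2) {
  d <- recording$distance
  n <- length(d)
  fs <- recording$sampling_rate
  exc <- max(d) - min(d)
  if (!is.finite(exc) || exc <= 0)
    stop("no complete cycles: waveform has no excursion", call. = FALSE)
  min_sep <- max(1L, round(min_cycle_ms / 1000 * fs))

  cand <- which(d[2:(n - 1)] < d[1:(n - 2)] & d[2:(n - 1)] <= d[3:n]) + 1L
  if (length(cand)) {
    prom <- valley_prominence(d, cand)
    cand <- cand[prom >= min_prominence_frac * exc]
  }
  # enforce separation: deeper valleys first, earlier sample wins ties
  kept <- integer(0)
  if (length(cand)) {
    ord <- order(d[cand], cand)
    for (i in cand[ord]) {
      if (!length(kept) || all(abs(kept - i) >= min_sep))
        kept <- c(kept, i)
    }
    kept <- sort(kept)
  }
  # boundary valleys: accept the end samples when they sit at valley level
  level <- min(d) + min_prominence_frac * exc
  if (d[1] <= level && (!length(kept) || min(kept) - 1L >= min_sep))
    kept <- c(1L, kept)
  if (d[n] <= level && (!length(kept) || n - max(kept) >= min_sep))
    kept <- c(kept, n)
  if (length(kept) < 2)
    stop("no complete cycles: fewer than two valleys detected",
         call. = FALSE)

  start <- kept[-length(kept)]
  end <- kept[-1]
  dur_ok <- (end - start) / fs * 1000 >= min_cycle_ms
  excursion <- vapply(seq_along(start), function(k) {
    max(d[start[k]:end[k]]) - mean(c(d[start[k]], d[end[k]]))
  }, numeric(1))
  keep <- dur_ok & excursion >= min_amplitude_mm
  cycles <- data.frame(cycle = seq_len(sum(keep)),
                       start_idx = start[keep], end_idx = end[keep])
  list(valleys = kept, cycles = cycles)
}

#' Compute per-cycle kinematic parameters
#'
#' For each cycle (valley-to-valley span): amplitude is the in-cycle
#' distance maximum minus the mean of the two bounding valley values;
#' peak opening speed is the largest positive speed between the opening
#' valley and the in-cycle maximum; peak closing speed is the largest
#' speed magnitude between the maximum and the closing valley.  Both
#' speeds are reported as positive magnitudes in m/s.  Cycles without an
#' interior maximum are dropped with a warning.
#'
#' @param recording a preprocessed `tap_recording` (with a speed trace).
#' @param cycles the `cycles` data.frame from [segment_cycles()], or the
#'   full [segment_cycles()] result.
#' @return data.frame: `cycle`, `start_idx`, `end_idx`, `amplitude` (mm),
#'   `peak_open_speed`, `peak_close_speed` (m/s).
#' @export
compute_cycle_parameters <- function(recording, cycles) {
  if (is.list(cycles) && !is.data.frame(cycles)) cycles <- cycles$cycles
  if (is.null(recording$speed))
    stop("recording has no speed trace; run preprocess_waveform() first",
         call. = FALSE)
  d <- recording$distance
  v <- recording$speed
  out <- vector("list", nrow(cycles))
  dropped <- 0L
  for (k in seq_len(nrow(cycles))) {
    s <- cycles$start_idx[k]
    e <- cycles$end_idx[k]
    m <- s + which.max(d[s:e]) - 1L
    if (m <= s || m >= e) {
      dropped <- dropped + 1L
      next
    }
    out[[k]] <- data.frame(
      cycle = cycles$cycle[k], start_idx = s, end_idx = e,
      amplitude = d[m] - mean(c(d[s], d[e])),
      peak_open_speed = max(v[s:m]),
      peak_close_speed = max(-v[m:e]))
  }
  if (dropped > 0L)
    warning(sprintf("%d cycle(s) dropped: no interior distance maximum",
                    dropped), call. = FALSE)
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cycle = integer(0), start_idx = integer(0),
                      end_idx = integer(0), amplitude = numeric(0),
                      peak_open_speed = numeric(0),
                      peak_close_speed = numeric(0))
  res$cycle <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Ordinary-least-squares slope of a per-cycle parameter
#'
#' Slope of the fitted linear regression of the parameter on the tap
#' cycle index (units: parameter unit per cycle).  With fewer than three
#' cycles the slope is not identified robustly and `NA` is returned with
#' a warning.
#'
#' @param values per-cycle parameter values.
#' @param cycle_index cycle indices (default `1..n`).
#' @return the OLS slope, or `NA_real_` when `n < 3`.
#' @export
fit_parameter_slope <- function(values, cycle_index = seq_along(values)) {
  n <- length(values)
  if (n < 3) {
    warning("fewer than 3 cycles: slope not estimated", call. = FALSE)
    return(NA_real_)
  }
  x <- cycle_index - mean(cycle_index)
  sum(x * (values - mean(values))) / sum(x^2)
}

#' Summarize a recording's cycles into per-hand tapping parameters
#'
#' Arithmetic means of amplitude and peak opening/closing speed over the
#' retained cycles, plus the per-parameter decrement slopes from
#' [fit_parameter_slope()].
#'
#' @param cycles per-cycle table from [compute_cycle_parameters()].
#' @param subject_id,hand identifiers for the output row (defaulted from
#'   the table's attributes if present).
#' @param speed_source `"derived"` or `"device"`.
#' @return one-row data.frame with `subject_id`, `hand`, `n_cycles`,
#'   `mean_amplitude`, `mean_peak_open_speed`, `mean_peak_close_speed`,
#'   `slope_amplitude`, `slope_open_speed`, `slope_close_speed`,
#'   `speed_source`.
#' @export
summarize_recording <- function(cycles, subject_id = "S001", hand = "R",
                                speed_source = "derived") {
  if (nrow(cycles) < 1)
    stop("no retained cycles to summarize", call. = FALSE)
  slopes <- if (nrow(cycles) >= 3) {
    c(fit_parameter_slope(cycles$amplitude),
      fit_parameter_slope(cycles$peak_open_speed),
      fit_parameter_slope(cycles$peak_close_speed))
  } else {
    warning("fewer than 3 cycles: slopes not estimated", call. = FALSE)
    rep(NA_real_, 3)
  }
  data.frame(subject_id = subject_id, hand = hand,
             n_cycles = nrow(cycles),
             mean_amplitude = mean(cycles$amplitude),
             mean_peak_open_speed = mean(cycles$peak_open_speed),
             mean_peak_close_speed = mean(cycles$peak_close_speed),
             slope_amplitude = slopes[1],
             slope_open_speed = slopes[2],
             slope_close_speed = slopes[3],
             speed_source = speed_source,
             stringsAsFactors = FALSE)
}

#' Full kinematic analysis of one recording
#'
#' Convenience wrapper: preprocess, segment, per-cycle parameters,
#' summary.
#'
#' @param recording a `tap_recording`.
#' @param cutoff low-pass cutoff, Hz.
#' @param ... retention parameters passed to [segment_cycles()].
#' @return list with `cycles` (per-cycle table) and `summary` (one row).
#' @export
tap_kinematics <- function(recording, cutoff = 20, ...) {
  rec <- preprocess_waveform(recording, cutoff = cutoff)
  seg <- segment_cycles(rec, ...)
  cyc <- compute_cycle_parameters(rec, seg)
  summ <- summarize_recording(cyc, subject_id = rec$subject_id,
                              hand = rec$hand,
                              speed_source = rec$speed_source)
  list(cycles = cyc, summary = summ)
}

#' Kinematic analysis of a whole cohort
#'
#' Runs [tap_kinematics()] on both hands of every subject.
#'
#' @param cohort a `tap_cohort` (or any list with a `waveforms` element).
#' @param cutoff low-pass cutoff, Hz.
#' @param ... passed to [segment_cycles()].
#' @return list with `cycles` (long per-cycle table including
#'   `subject_id`, `hand`) and `summaries` (one row per subject x hand).
#' @export
summarize_tapping <- function(cohort, cutoff = 20, ...) {
  cyc_list <- list()
  sum_list <- list()
  for (id in names(cohort$waveforms)) {
    for (h in c("L", "R")) {
      res <- tap_kinematics(cohort$waveforms[[id]][[h]], cutoff = cutoff,
                            ...)
      cc <- res$cycles
      if (nrow(cc)) {
        cc <- cbind(subject_id = id, hand = h, cc)
        cyc_list[[paste(id, h)]] <- cc
      }
      sum_list[[paste(id, h)]] <- res$summary
    }
  }
  cycles <- do.call(rbind, cyc_list)
  summaries <- do.call(rbind, sum_list)
  rownames(cycles) <- rownames(summaries) <- NULL
  list(cycles = cycles, summaries = summaries)
}
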
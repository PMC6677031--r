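# Default study conditions for the synthetic cohort generator.
#
# Group-level means/SDs mirror the published cohort structure this package
# targets: three groups (HC, RBD with normal motor function, RBD with mild
# motor impairment), clinical-score and polysomnographic summaries, graded
# striatal dopamine-transporter reduction with left-right asymmetry in the
# MMI group, and sensorimotor ROI connectivity effects in specific pairs.

#' Default ROI labels for the sensorimotor connectivity analysis
#'
#' Thirty regions: bilateral primary motor cortex (M1), premotor cortex
#' (PM), supplementary motor area (SMA), primary somatosensory cortex (S1),
#' superior and inferior parietal lobules (SPL, IPL), caudate, anterior and
#' posterior putamen, and cerebellar lobules II, III, IV-V, VI, VII, VIII.
#'
#' @return Character vector of 30 labels, `L_`/`R_` prefixed.
#' @export
default_roi_labels <- function() {
  base <- c("M1", "PM", "SMA", "S1", "SPL", "IPL",
            "caudate", "ant_putamen", "post_putamen",
            "cerebellum_II", "cerebellum_III", "cerebellum_IV_V",
            "cerebellum_VI", "cerebellum_VII", "cerebellum_VIII")
  paste(rep(c("L", "R"), each = length(base)), rep(base, 2L), sep = "_")
}

striatal_regions <- function() c("caudate", "ant_putamen", "post_putamen")

# FC pairs carrying the configured group effects: cortico-striatal coupling
# (striatum - superior parietal lobule) present in HC and reduced in both
# RBD groups; cerebello-cortical coupling (lobule VIII - S1/PM) elevated in
# the MMI group only.
fc_effect_pairs <- function() {
  list(
    striatal_spl = list(c("R_ant_putamen", "R_SPL"),
                        c("L_ant_putamen", "R_SPL"),
                        c("L_caudate",     "R_SPL")),
    cerebello_cortical = list(c("R_cerebellum_VIII", "R_S1"),
                              c("L_cerebellum_VIII", "R_S1"),
                              c("L_cerebellum_VIII", "L_S1"),
                              c("L_cerebellum_VIII", "R_PM"))
  )
}

#' Default group-wise target correlation matrices for ROI time series
#'
#' Identity baseline plus a configurable effect `delta_r` on the pairs that
#' differ between groups: the cortico-striatal pairs are present (r =
#' `delta_r`) in HC and absent in both RBD groups; the cerebello-cortical
#' pairs are present only in RBD-MMI.
#'
#' @param roi_labels ROI label vector (default [default_roi_labels()]).
#' @param delta_r effect size on the differing pairs (default 0.3, a
#'   desk-detectable effect at the default group sizes).
#' @return Named list of correlation matrices, one per group.
#' @export
default_fc_targets <- function(roi_labels = default_roi_labels(),
                               delta_r = 0.3) {
  p <- length(roi_labels)
  base <- diag(p)
  dimnames(base) <- list(roi_labels, roi_labels)
  set_pairs <- function(m, pairs, r) {
    for (pr in pairs) {
      m[pr[1], pr[2]] <- r
      m[pr[2], pr[1]] <- r
    }
    m
  }
  eff <- fc_effect_pairs()
  list(
    "HC"      = set_pairs(base, eff$striatal_spl, delta_r),
    "RBD-N"   = base,
    "RBD-MMI" = set_pairs(base, eff$cerebello_cortical, delta_r)
  )
}

#' Default striatal specific-binding-ratio means by group, region and side
#'
#' Encodes the graded nigrostriatal reduction (posterior putamen > anterior
#' putamen > caudate) with right-dominant asymmetry in the MMI group and a
#' small, mostly symmetric reduction in RBD-N.
#'
#' @return data.frame with columns group, region, side, sbr.
#' @export
default_sbr_means <- function() {
  hc <- c(caudate = 4.5, ant_putamen = 4.2, post_putamen = 3.8)
  # fractional reductions relative to HC, per (region, side)
  red <- rbind(
    data.frame(group = "HC", region = names(hc), R = 0, L = 0),
    data.frame(group = "RBD-N", region = names(hc),
               R = c(0.020, 0.046, 0.041), L = c(0.020, 0.010, 0.038)),
    data.frame(group = "RBD-MMI", region = names(hc),
               R = c(0.158, 0.220, 0.302), L = c(0.170, 0.201, 0.195))
  )
  out <- do.call(rbind, lapply(c("R", "L"), function(s) {
    data.frame(group = red$group, region = red$region, side = s,
               sbr = hc[red$region] * (1 - red[[s]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# clinical scores: per-group mean/SD, with integer rounding and bounds
default_clinical_spec <- function() {
  # columns: variable, then mean/sd per group, lower, upper
  v <- function(name, hc, n, mmi, lower = 0, upper = Inf) {
    data.frame(variable = name,
               group = c("HC", "RBD-N", "RBD-MMI"),
               mean = c(hc[1], n[1], mmi[1]),
               sd = c(hc[2], n[2], mmi[2]),
               lower = lower, upper = upper,
               stringsAsFactors = FALSE)
  }
  rbind(
    v("updrs3_total",    c(0.5, 0.9),  c(1.2, 1.6),  c(2.3, 2.2)),
    v("mmse",            c(28.7, 1.7), c(28.6, 1.2), c(29.3, 0.9), 0, 30),
    v("hads_total",      c(5.2, 5.0),  c(9.1, 4.8),  c(12.6, 8.0), 0, 42),
    v("hads_anxiety",    c(1.9, 2.3),  c(3.5, 2.5),  c(5.2, 5.9),  0, 21),
    v("hads_depression", c(3.3, 3.0),  c(5.0, 3.6),  c(7.3, 3.8),  0, 21),
    v("odor_test",       c(6.8, 1.5),  c(4.8, 1.7),  c(4.2, 2.4),  0, 12),
    v("rbdsq_j",         c(1.3, 1.8),  c(8.0, 2.5),  c(9.1, 1.8),  0, 13),
    v("epworth",         c(3.8, 2.6),  c(5.8, 2.9),  c(4.5, 3.5),  0, 24),
    v("pittsburgh",      c(3.0, 2.5),  c(5.0, 2.1),  c(6.3, 3.8),  0, 21)
  )
}

# motor-exam item means by group; items are small integer scores (0-4)
# drawn as Binomial(2, mean/2) so group means match the spec values
default_updrs_item_means <- function() {
  items <- c("speech", "facial_expression", "tremor_at_rest",
             "action_tremor", "rigidity", "rt_finger_tapping",
             "lt_finger_tapping", "hand_movements", "ram_hands",
             "leg_agility", "arising_from_chair", "posture", "gait",
             "postural_stability", "body_bradykinesia")
  data.frame(
    item = rep(items, times = 3),
    group = rep(c("HC", "RBD-N", "RBD-MMI"), each = length(items)),
    mean = c(
      # HC
      0, 0, 0, 0.05, 0.20, 0.05, 0.05, 0.10, 0, 0, 0, 0, 0, 0, 0.05,
      # RBD-N
      0.06, 0.06, 0, 0.06, 0.33, 0.13, 0, 0.13, 0.13, 0.13, 0, 0.06, 0,
      0.06, 0.13,
      # RBD-MMI
      0.12, 0, 0, 0.12, 0.25, 0.62, 0.50, 0.25, 0, 0.12, 0, 0, 0, 0, 0.12
    ),
    stringsAsFactors = FALSE
  )
}

# polysomnographic measures (RBD groups only; HC has none)
default_psg_spec <- function() {
  v <- function(name, n, mmi, lower = 0, upper = Inf) {
    data.frame(variable = name, group = c("RBD-N", "RBD-MMI"),
               mean = c(n[1], mmi[1]), sd = c(n[2], mmi[2]),
               lower = lower, upper = upper, stringsAsFactors = FALSE)
  }
  rbind(
    v("total_sleep_time_min",  c(405.7, 66.1), c(408.9, 71.3)),
    v("sleep_efficiency_pct",  c(77.3, 11.9),  c(78.9, 11.9), 0, 100),
    v("sleep_onset_latency_min", c(11.1, 7.3), c(12.0, 5.5)),
    v("rem_latency_min",       c(95.5, 45.8),  c(84.3, 74.8)),
    v("n1_pct",                c(23.0, 21.5),  c(15.1, 6.1), 0, 100),
    v("n2_pct",                c(57.0, 14.4),  c(57.9, 10.6), 0, 100),
    v("n3_pct",                c(2.4, 3.4),    c(3.5, 3.5), 0, 100),
    v("rem_pct",               c(26.5, 31.5),  c(21.3, 8.1), 0, 100),
    v("rswa_pct",              c(50.1, 23.7),  c(47.9, 22.2), 0, 100),
    v("arousal_index",         c(14.0, 6.4),   c(14.4, 3.6)),
    v("plm_index",             c(21.4, 21.1),  c(11.8, 16.9)),
    v("apnea_hypopnea_index",  c(5.5, 6.7),    c(4.9, 5.4))
  )
}

default_demographics_spec <- function() {
  list(
    age = data.frame(group = c("HC", "RBD-N", "RBD-MMI"),
                     mean = c(70.7, 70.8, 72.2),
                     sd = c(3.6, 4.0, 4.6), stringsAsFactors = FALSE),
    p_male = c("HC" = 11 / 20, "RBD-N" = 8 / 15, "RBD-MMI" = 4 / 8),
    clinical = default_clinical_spec(),
    updrs_items = default_updrs_item_means(),
    psg = default_psg_spec(),
    disease_duration = data.frame(group = c("RBD-N", "RBD-MMI"),
                                  mean = c(4.7, 5.6), sd = c(3.0, 3.9),
                                  stringsAsFactors = FALSE),
    head_motion_fd = data.frame(group = c("HC", "RBD-N", "RBD-MMI"),
                                mean = c(0.23, 0.22, 0.16),
                                sd = c(0.14, 0.11, 0.076),
                                stringsAsFactors = FALSE)
  )
}

# per-parameter, per-side decrement-slope distributions (identical across
# groups: progressive decrement is not a group effect under the defaults)
default_slope_spec <- function() {
  list(
    mean = list(amplitude   = c(R = -0.17,  L = -0.31),
                open_speed  = c(R = -0.009, L = -0.013),
                close_speed = c(R = -0.012, L = -0.016)),
    sd   = list(amplitude   = c(R = 0.28,  L = 0.32),
                open_speed  = c(R = 0.007, L = 0.006),
                close_speed = c(R = 0.008, L = 0.009))
  )
}
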
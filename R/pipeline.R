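stage_order <- function() c("simulate", "kinematics", "classify",
                            "spect", "fc", "report")

write_stage_manifest <- function(dir, stage, seed, files, params = list()) {
  files <- files[file.exists(files)]
  manifest <- list(
    stage = stage, seed = seed, params = params,
    files = data.frame(path = sub(paste0("^", dir, "/?"), "", files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
  p <- file.path(dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  p
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> kinematics -> classify -> spect -> fc ->
#' report as one reproducible run.  Every stage writes its tables as CSV
#' plus a JSON manifest (seed, parameters, MD5 hashes); rerunning with an
#' identical configuration produces byte-identical outputs.  When
#' `"simulate"` is not among the stages, inputs are read from
#' `input_dir` (in [write_cohort()] layout) and validated up front.
#'
#' @param config a [cohort_config()] (used when simulating; its seed
#'   drives all randomness).
#' @param out_dir run directory (created).
#' @param stages subset of
#'   `c("simulate","kinematics","classify","spect","fc","report")`;
#'   order is fixed.
#' @param input_dir cohort directory when not simulating.
#' @param cutoff_hz kinematics low-pass cutoff.
#' @param band,tr connectivity band-pass settings (defaults 0.008-0.09
#'   Hz at TR 2.5 s).
#' @param fdr_scope `"analysis"` or `"seed"` (see
#'   [test_group_differences()]).
#' @return invisibly, a list with the in-memory stage outputs
#'   (`cohort`, `kinematics`, `classification`, `uptake`, `fc`,
#'   `report`).
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         stages = stage_order(), input_dir = NULL,
                         cutoff_hz = 20, band = c(0.008, 0.09),
                         tr = NULL, fdr_scope = "analysis") {
  stages <- intersect(stage_order(), stages)  # fixed order
  if (!length(stages)) stop("no stages requested", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # upfront input validation when not simulating
  if (!("simulate" %in% stages)) {
    if (is.null(input_dir))
      stop("input_dir is required when the simulate stage is disabled",
           call. = FALSE)
    cohort <- read_cohort(input_dir)
  } else {
    validate_cohort_config(config)
    cohort <- generate_cohort(config)
  }
  tr <- tr %||% (if (!is.null(cohort$config)) cohort$config$tr else 2.5)
  seed <- if (!is.null(cohort$config)) cohort$config$seed else NA_integer_
  out <- list(cohort = cohort)

  if ("simulate" %in% stages) {
    write_cohort(cohort, out_dir)
    write_stage_manifest(out_dir, "simulate", seed,
                         file.path(out_dir, "subjects.csv"))
  }

  if ("kinematics" %in% stages) {
    kin <- summarize_tapping(cohort, cutoff = cutoff_hz)
    out$kinematics <- kin
    f1 <- file.path(out_dir, "tap_cycles.csv")
    f2 <- file.path(out_dir, "tap_summaries.csv")
    write.csv(kin$cycles, f1, row.names = FALSE)
    write.csv(kin$summaries, f2, row.names = FALSE)
    write_stage_manifest(out_dir, "kinematics", seed, c(f1, f2),
                         list(cutoff_hz = cutoff_hz))
  }

  if ("classify" %in% stages) {
    if (is.null(out$kinematics))
      stop("classify stage requires the kinematics stage", call. = FALSE)
    cls <- classify_cohort(out$kinematics$summaries, cohort$subjects)
    out$classification <- cls
    f1 <- file.path(out_dir, "classification.csv")
    write.csv(cls$classification, f1, row.names = FALSE)
    f2 <- file.path(out_dir, "normative_model.json")
    write_normative_model(cls$model, f2)
    write_stage_manifest(out_dir, "classify", seed, c(f1, f2))
  }

  if ("spect" %in% stages) {
    if (is.null(cohort$voi_counts))
      stop("spect stage requires VOI counts", call. = FALSE)
    upt <- uptake_from_counts(cohort$voi_counts)
    out$uptake <- upt
    f1 <- file.path(out_dir, "uptake_sbr.csv")
    f2 <- file.path(out_dir, "uptake_ai.csv")
    write.csv(upt$sbr, f1, row.names = FALSE)
    write.csv(upt$ai, f2, row.names = FALSE)
    write_stage_manifest(out_dir, "spect", seed, c(f1, f2))
  }

  if ("fc" %in% stages) {
    if (!length(cohort$roi_timeseries))
      stop("fc stage requires ROI time series", call. = FALSE)
    fcz <- cohort_fc(cohort$roi_timeseries, band = band, tr = tr)
    grp_obs <- setNames(cohort$subjects$group, cohort$subjects$subject_id)
    if (!is.null(out$classification) &&
        nrow(out$classification$classification) > 0) {
      cl <- out$classification$classification
      grp_obs[cl$subject_id] <- cl$group_observed
    }
    ids <- rownames(fcz$z)
    m <- match(ids, cohort$subjects$subject_id)
    contrasts <- test_group_differences(
      fcz$z, groups = unname(grp_obs[ids]), age = cohort$subjects$age[m],
      sex = cohort$subjects$sex[m], pairs = fcz$pairs,
      fdr_scope = fdr_scope)
    out$fc <- list(z = fcz$z, pairs = fcz$pairs, contrasts = contrasts)
    f1 <- file.path(out_dir, "fc_z_long.csv")
    zl <- data.frame(subject_id = rep(ids, each = nrow(fcz$pairs)),
                     roi_1 = rep(fcz$pairs$roi_1, length(ids)),
                     roi_2 = rep(fcz$pairs$roi_2, length(ids)),
                     z = as.vector(t(fcz$z)), stringsAsFactors = FALSE)
    write.csv(zl, f1, row.names = FALSE)
    f2 <- file.path(out_dir, "fc_contrasts.csv")
    write.csv(contrasts, f2, row.names = FALSE)
    write_stage_manifest(out_dir, "fc", seed, c(f1, f2),
                         list(band = band, tr = tr,
                              fdr_scope = fdr_scope))
  }

  if ("report" %in% stages) {
    rep_dir <- file.path(out_dir, "report")
    out$report <- build_report(
      subjects = cohort$subjects,
      tap_summaries = if (!is.null(out$kinematics))
        out$kinematics$summaries else NULL,
      classification = if (!is.null(out$classification))
        out$classification$classification else NULL,
      uptake = out$uptake,
      fc_contrasts = if (!is.null(out$fc)) out$fc$contrasts else NULL,
      fc_z = if (!is.null(out$fc)) out$fc$z else NULL,
      out_dir = rep_dir)
    write_stage_manifest(out_dir, "report", seed,
                         list.files(rep_dir, full.names = TRUE))
  }

  invisible(out)
}

#' Fixture configurations for testing and examples
#'
#' `tiny` (3 subjects per group, 5-s waveforms, 40 volumes) runs the full
#' pipeline in seconds and backs the test suite; `paper-like` uses the
#' emulated study sizes (20 HC, 15 RBD-N, 8 RBD-MMI; 15-s waveforms, 180
#' volumes).
#'
#' @param scale `"tiny"` or `"paper-like"`.
#' @param seed master seed.
#' @return a [cohort_config()].
#' @export
make_fixtures <- function(scale = c("tiny", "paper-like"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    cohort_config(n_per_group = c("HC" = 3, "RBD-N" = 3, "RBD-MMI" = 3),
                  seed = seed, tap_duration_s = 5, n_volumes = 40)
  } else {
    cohort_config(seed = seed)
  }
}
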
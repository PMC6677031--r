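#' Assemble the study report tables
#'
#' Builds the full set of result tables from the stage outputs:
#'
#' 1. `demographics` — clinical characteristics by observed group
#'    (ANOVA + Tukey for continuous scores, chi-square for sex);
#' 2. `updrs_items` — motor-exam item comparisons (ANOVA + Tukey);
#' 3. `psg` — polysomnographic measures and disease duration,
#'    RBD-MMI vs RBD-N pooled-variance t-tests;
#' 4. `tapping` — the six tapping parameters by observed group
#'    (ANOVA + Tukey);
#' 5. `uptake` — SBR group means, percent differences vs HC, ANOVA +
#'    Tukey per region/side and per asymmetry index;
#' 6. `fc_contrasts` — covariate-adjusted connectivity contrasts with
#'    FDR-adjusted p-values;
#' 7. `correlations` — Pearson correlations of tapping parameters and
#'    motor scores with contralateral striatal SBR, and partial
#'    correlations (age, sex) with the connectivity of pairs showing a
#'    significant group difference.
#'
#' Stages whose inputs are absent are skipped with a warning.  No
#' multiple-testing correction is applied across the correlation tables
#' (each is reported at its own two-tailed p-value); treat those tables
#' as exploratory.
#'
#' @param subjects subjects table (with `subject_id`, `group`, `age`,
#'   `sex` and score columns).
#' @param tap_summaries tapping summary table, or `NULL`.
#' @param classification classifier output (with `group_observed`), or
#'   `NULL` (observed groups then fall back to `subjects$group`).
#' @param uptake an `uptake_record`, or `NULL`.
#' @param fc_contrasts output of [test_group_differences()], or `NULL`.
#' @param fc_z subjects x pairs Fisher-z matrix (rownames = subject
#'   ids), or `NULL`.
#' @param out_dir if non-`NULL`, every table is written there as CSV.
#' @return named list of data.frames (the tables that could be built).
#' @export
build_report <- function(subjects, tap_summaries = NULL,
                         classification = NULL, uptake = NULL,
                         fc_contrasts = NULL, fc_z = NULL,
                         out_dir = NULL) {
  tables <- list()
  grp <- setNames(subjects$group, subjects$subject_id)
  if (!is.null(classification) && nrow(classification) > 0) {
    grp[classification$subject_id] <- classification$group_observed
  }
  subjects$group_observed <- unname(grp[subjects$subject_id])

  anova_row <- function(values, groups, variable) {
    ok <- is.finite(values)
    sizes <- table(groups[ok])
    if (length(sizes) < 2 || any(sizes < 2)) return(NULL)
    res <- tryCatch(anova_tukey(values[ok], groups[ok]),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    sig <- res$tukey[res$tukey$p_adj < 0.05, ]
    data.frame(variable = variable, test = "anova",
               statistic = res$anova$F, df1 = res$anova$df1,
               df2 = res$anova$df2, p = res$anova$p,
               significant_pairs = paste(
                 sprintf("%s>%s", sig$group_1, sig$group_2),
                 collapse = "; "),
               stringsAsFactors = FALSE)
  }

  # 1. demographics -------------------------------------------------------
  demo_vars <- intersect(
    c("age", unique(default_clinical_spec()$variable)), names(subjects))
  rows <- lapply(demo_vars, function(v)
    anova_row(subjects[[v]], subjects$group_observed, v))
  sex_tab <- table(subjects$group_observed, subjects$sex)
  sex_row <- tryCatch({
    cs <- chi_square(sex_tab)
    data.frame(variable = "sex", test = "chi_square",
               statistic = cs$chi_square, df1 = cs$df, df2 = NA_real_,
               p = cs$p, significant_pairs = "",
               stringsAsFactors = FALSE)
  }, error = function(e) NULL)
  tables$demographics <- do.call(rbind, c(rows, list(sex_row)))

  # 2. motor-exam items ----------------------------------------------------
  item_cols <- grep("^updrs_item_", names(subjects), value = TRUE)
  if (length(item_cols)) {
    rows <- lapply(item_cols, function(v)
      anova_row(subjects[[v]], subjects$group_observed,
                sub("^updrs_item_", "", v)))
    tables$updrs_items <- do.call(rbind, rows)
  }

  # 3. polysomnography: RBD-MMI vs RBD-N t-tests ---------------------------
  psg_vars <- intersect(c(unique(default_psg_spec()$variable),
                          "disease_duration_y"), names(subjects))
  if (length(psg_vars)) {
    mmi <- subjects$group_observed == "RBD-MMI"
    nrm <- subjects$group_observed == "RBD-N"
    rows <- lapply(psg_vars, function(v) {
      a <- subjects[[v]][mmi]; b <- subjects[[v]][nrm]
      if (sum(is.finite(a)) < 2 || sum(is.finite(b)) < 2) return(NULL)
      tt <- two_sample_t(a, b)
      data.frame(variable = v, test = "t_test", statistic = tt$t,
                 df1 = tt$df, df2 = NA_real_, p = tt$p,
                 significant_pairs = "", stringsAsFactors = FALSE)
    })
    tables$psg <- do.call(rbind, rows)
  }

  # 4. tapping parameters ---------------------------------------------------
  if (!is.null(tap_summaries)) {
    wide <- summaries_to_wide(tap_summaries)
    wide$group <- unname(grp[wide$subject_id])
    grid <- classifier_grid()
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      col <- paste0(grid$parameter[i], "_", grid$side[i])
      anova_row(wide[[col]], wide$group, col)
    })
    tables$tapping <- do.call(rbind, rows)
  } else {
    warning("tapping summaries missing: tapping table skipped",
            call. = FALSE)
  }

  # 5. uptake ----------------------------------------------------------------
  if (!is.null(uptake)) {
    us <- summarize_uptake(uptake, grp)
    tables$uptake_group_means <- us$group_means
    tables$uptake_percent_diff <- us$percent_diff
    tables$uptake_anova <- us$anova_sbr
    tables$uptake_tukey <- us$tukey_sbr
    tables$uptake_ai_anova <- us$anova_ai
    tables$uptake_ai_tukey <- us$tukey_ai
  } else {
    warning("uptake record missing: uptake tables skipped", call. = FALSE)
  }

  # 6. connectivity contrasts -------------------------------------------------
  if (!is.null(fc_contrasts)) {
    tables$fc_contrasts <- fc_contrasts
  } else {
    warning("connectivity contrasts missing: FC table skipped",
            call. = FALSE)
  }

  # 7. correlations -------------------------------------------------------------
  if (!is.null(tap_summaries) && !is.null(uptake)) {
    wide <- summaries_to_wide(tap_summaries)
    m <- match(wide$subject_id, subjects$subject_id)
    sbr <- uptake$sbr
    rows <- list()
    for (hand in c("R", "L")) {
      cside <- contralateral_map(hand)
      for (p in tapmark_parameters()) {
        xcol <- paste0(p, "_", hand)
        for (region in striatal_regions()) {
          sel <- sbr$side == cside & sbr$region == region
          y <- setNames(sbr$sbr[sel], sbr$subject_id[sel])[wide$subject_id]
          row <- tryCatch(pearson_correlation(
            wide[[xcol]], unname(y), x_name = xcol,
            y_name = paste0(region, "_", cside)),
            error = function(e) NULL)
          rows[[length(rows) + 1]] <- row
        }
      }
      # motor scores against the same contralateral regions
      score_cols <- intersect(
        c("updrs3_total",
          paste0("updrs_item_", tolower(hand), "t_finger_tapping")),
        names(subjects))
      for (sc in score_cols) {
        for (region in striatal_regions()) {
          sel <- sbr$side == cside & sbr$region == region
          y <- setNames(sbr$sbr[sel], sbr$subject_id[sel])[wide$subject_id]
          row <- tryCatch(pearson_correlation(
            subjects[[sc]][m], unname(y), x_name = paste0(sc, "_", hand),
            y_name = paste0(region, "_", cside)),
            error = function(e) NULL)
          rows[[length(rows) + 1]] <- row
        }
      }
    }
    tables$correlations_sbr <- do.call(rbind, rows)
  }

  if (!is.null(tap_summaries) && !is.null(fc_z) &&
      !is.null(fc_contrasts)) {
    sig <- unique(fc_contrasts[fc_contrasts$p_fdr < 0.05 &
                                 !is.na(fc_contrasts$p_fdr),
                               c("roi_1", "roi_2")])
    if (nrow(sig)) {
      wide <- summaries_to_wide(tap_summaries)
      ids <- intersect(rownames(fc_z), wide$subject_id)
      m <- match(ids, subjects$subject_id)
      cov <- data.frame(age = subjects$age[m],
                        sex = as.numeric(subjects$sex[m] == "F"))
      wm <- match(ids, wide$subject_id)
      rows <- list()
      grid <- classifier_grid()
      xcols <- paste0(grid$parameter, "_", grid$side)
      for (i in seq_len(nrow(sig))) {
        pair_col <- paste(sig$roi_1[i], sig$roi_2[i], sep = "~")
        if (!pair_col %in% colnames(fc_z)) next
        zv <- fc_z[ids, pair_col]
        for (xc in xcols) {
          row <- tryCatch(partial_correlation(
            wide[[xc]][wm], zv, cov, x_name = xc, y_name = pair_col),
            error = function(e) NULL)
          rows[[length(rows) + 1]] <- row
        }
      }
      tables$correlations_fc <- do.call(rbind, rows)
    } else {
      tables$correlations_fc <- data.frame()
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  tables
}
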
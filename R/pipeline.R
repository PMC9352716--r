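#' Run the four-step group analysis on a cohort table
#'
#' Step 1 compares the VR navigation variables (three VST components, two
#' wayfinding scores, flare accuracy) between groups with the
#' normality-gated test and pooled-SD Cohen's d, and re-tests the two
#' wayfinding effects with an inverse-transformed ANCOVA controlling for
#' map-view duration. Step 2 compares the two DNT route disorientation
#' scores. Step 3, on patients only, regresses the composite disorientation
#' score on each VR variable (standardized), with worst-score imputation for
#' wayfinding non-attempters. Step 4 predicts the high/low risk label from
#' each predictor that was significant in step 3, by binomial logistic
#' regression. Participants without a detour walk are excluded from steps
#' 2-4 (no composite score exists for them).
#'
#' @param cohort tibble with columns `participant_id`, `group`
#'   (control/patient), the score variables, `composite`, `risk`
#'   (as produced by [gen_cohort_scores()] or assembled from the scorers).
#' @param config an [analysis_config()].
#' @return object of class `navdis_results`: tibbles `step1_vr`,
#'   `step1_ancova`, `step2_dnt`, `step3_regression`, `step4_logistic`, and
#'   a `log` of every setting and data-handling decision applied.
#' @export
run_pipeline <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  req <- c("participant_id", "group")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop_navdis("cohort table: missing column %s",
                                paste(miss, collapse = ", "))
  cohort <- cohort[order(cohort$participant_id), , drop = FALSE]
  log <- c(sprintf("alpha_normality = %g", config$alpha_normality),
           sprintf("dnt.normalization = %s", config$dnt_normalization),
           sprintf("dnt.risk_tolerance = %g", config$dnt_risk_tolerance),
           sprintf("imputation = %s", config$imputation))
  ctrl <- cohort[cohort$group == "control", , drop = FALSE]
  pat <- cohort[cohort$group == "patient", , drop = FALSE]

  comparison_row <- function(var, label) {
    x <- ctrl[[var]][!is.na(ctrl[[var]])]
    y <- pat[[var]][!is.na(pat[[var]])]
    gc <- tryCatch(compare_groups(x, y, config$alpha_normality, var),
                   error = function(e) e)
    if (inherits(gc, "error")) {
      # degenerate variable (e.g. event scores all zero): report the group
      # summaries, no test — matching how all-zero rows are tabulated
      return(tibble::tibble(
        variable = var, label = label,
        controls_mean = mean(x), controls_sd = sd(x), n_controls = length(x),
        patients_mean = mean(y), patients_sd = sd(y), n_patients = length(y),
        test_used = NA_character_, statistic = NA_real_, p_value = NA_real_,
        significance = NA_character_, cohens_d = NA_real_))
    }
    tibble::tibble(variable = var, label = label,
                   controls_mean = gc$mean1, controls_sd = gc$sd1, n_controls = gc$n1,
                   patients_mean = gc$mean2, patients_sd = gc$sd2, n_patients = gc$n2,
                   test_used = gc$test_used, statistic = gc$statistic,
                   p_value = gc$p_value, significance = p_stars(gc$p_value),
                   cohens_d = gc$cohens_d)
  }
  labels <- setNames(reference_cohort_stats()$label, reference_cohort_stats()$variable)
  lab <- function(v) if (v %in% names(labels)) labels[[v]] else v

  vr_vars <- intersect(c("ego_pct", "allo_disp_pct", "head_pct",
                         "wf_distance", "wf_duration", "flare_accuracy"),
                       names(cohort))
  step1 <- dplyr::bind_rows(lapply(vr_vars, function(v) comparison_row(v, lab(v))))

  anc_rows <- list()
  if (all(c("map_view_s", "wf_distance") %in% names(cohort))) {
    for (v in intersect(c("wf_distance", "wf_duration"), names(cohort))) {
      af <- ancova_adjusted(cohort[[v]], cohort$group, cohort$map_view_s,
                            transform = "inverse")
      anc_rows[[v]] <- tibble::tibble(
        outcome = v, covariate = "map_view_s",
        F_statistic = af$F_statistic, df_between = af$df_between,
        df_within = af$df_within, p_value = af$p_value,
        significance = p_stars(af$p_value),
        transform_applied = af$transform_applied)
      log <- c(log, sprintf(
        "ANCOVA on %s: inverse transform, covariate map_view_s, n = %d", v, af$n))
    }
  }
  step1_ancova <- if (length(anc_rows)) dplyr::bind_rows(anc_rows) else tibble::tibble()

  dnt_vars <- intersect(c("original_score", "detour_score"), names(cohort))
  step2 <- dplyr::bind_rows(lapply(dnt_vars, function(v) comparison_row(v, lab(v))))
  if ("detour_score" %in% names(cohort)) {
    dropped <- cohort$participant_id[cohort$group == "patient" &
                                       is.na(cohort$detour_score)]
    if (length(dropped)) {
      log <- c(log, sprintf("no detour walk for %s: excluded from DNT comparison, regression and risk prediction",
                            paste(dropped, collapse = ", ")))
    }
  }

  # steps 3-4: patients only, with a composite score
  pat3 <- pat[!is.na(pat$composite), , drop = FALSE]
  predictors <- intersect(c("ego_pct", "allo_disp_pct", "head_pct",
                            "wf_distance", "wf_duration"), names(cohort))
  step3_rows <- list()
  for (v in predictors) {
    x <- setNames(pat3[[v]], pat3$participant_id)
    n_imputed <- 0L
    if (config$imputation && v %in% c("wf_distance", "wf_duration") && anyNA(x)) {
      missing_ids <- names(x)[is.na(x)]
      x <- impute_worst(x[!is.na(x)], missing_ids)[names(x)]
      n_imputed <- length(missing_ids)
      log <- c(log, sprintf("worst-score imputation on %s for %s", v,
                            paste(missing_ids, collapse = ", ")))
    }
    rf <- linear_regression_standardized(x, pat3$composite)
    step3_rows[[v]] <- tibble::tibble(
      predictor = v, label = lab(v), beta_standardized = rf$beta_standardized,
      p_value = rf$p_value, significance = p_stars(rf$p_value),
      r_squared = rf$r_squared, f_squared = rf$f_squared,
      residuals_normal = rf$residuals_normal, n = rf$n, n_imputed = n_imputed)
  }
  step3 <- dplyr::bind_rows(step3_rows)

  step4_rows <- list()
  sig <- step3$predictor[step3$p_value < 0.05]
  log <- c(log, sprintf("step 4 predictors (significant in step 3): %s",
                        if (length(sig)) paste(sig, collapse = ", ") else "none"))
  for (v in sig) {
    x <- setNames(pat3[[v]], pat3$participant_id)
    if (config$imputation && v %in% c("wf_distance", "wf_duration") && anyNA(x)) {
      x <- impute_worst(x[!is.na(x)], names(x)[is.na(x)])[names(x)]
    }
    lf <- tryCatch(logistic_risk(x, pat3$risk), error = function(e) e)
    step4_rows[[v]] <- if (inherits(lf, "error")) {
      log <- c(log, sprintf("logistic fit on %s failed: %s", v, conditionMessage(lf)))
      tibble::tibble(predictor = v, odds_ratio = NA_real_, p_value = NA_real_,
                     significance = NA_character_, n_high = NA_integer_,
                     n_low = NA_integer_, note = conditionMessage(lf))
    } else {
      tibble::tibble(predictor = v, odds_ratio = lf$odds_ratio,
                     p_value = lf$p_value, significance = p_stars(lf$p_value),
                     n_high = lf$n_high, n_low = lf$n_low, note = "")
    }
  }
  step4 <- if (length(step4_rows)) dplyr::bind_rows(step4_rows) else
    tibble::tibble(predictor = character(), odds_ratio = numeric(),
                   p_value = numeric(), significance = character(),
                   n_high = integer(), n_low = integer(), note = character())

  out <- list(step1_vr = step1, step1_ancova = step1_ancova, step2_dnt = step2,
              step3_regression = step3, step4_logistic = step4, log = log)
  class(out) <- "navdis_results"
  out
}

p_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' @export
print.navdis_results <- function(x, ...) {
  cat("Four-step navigation analysis\n")
  cat(sprintf("  step 1: %d VR comparisons (+%d ANCOVA), step 2: %d DNT comparisons\n",
              nrow(x$step1_vr), nrow(x$step1_ancova), nrow(x$step2_dnt)))
  cat(sprintf("  step 3: %d regressions (significant: %s)\n", nrow(x$step3_regression),
              paste(x$step3_regression$predictor[x$step3_regression$p_value < 0.05],
                    collapse = ", ")))
  cat(sprintf("  step 4: %d logistic fits\n", nrow(x$step4_logistic)))
  invisible(x)
}

#' Write pipeline results to disk
#'
#' One CSV per analysis step plus a combined markdown report mirroring the
#' standard summary layout (variable, group means (SD), test, significance,
#' d) and a log of every setting used. Output is deterministic for identical
#' inputs.
#'
#' @param results a `navdis_results` object from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "navdis_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  w(results$step1_vr, "step1_vr_group_differences.csv")
  if (nrow(results$step1_ancova)) w(results$step1_ancova, "step1_ancova.csv")
  w(results$step2_dnt, "step2_dnt_group_differences.csv")
  w(results$step3_regression, "step3_regression.csv")
  w(results$step4_logistic, "step4_logistic.csv")
  writeLines(results$log, file.path(dir, "pipeline_log.txt"))

  fmt_cmp <- function(df) {
    test_col <- ifelse(is.na(df$test_used), "-",
                       paste0(ifelse(df$test_used == "students_t", "t", "W"),
                              " = ", sprintf("%.2f", df$statistic)))
    paste0("| ", df$label, " | ",
           sprintf("%.2f (%.2f)", df$controls_mean, df$controls_sd), " | ",
           sprintf("%.2f (%.2f)", df$patients_mean, df$patients_sd), " | ",
           test_col, " | ",
           ifelse(is.na(df$significance), "-", df$significance), " | ",
           ifelse(is.na(df$cohens_d) | df$significance %in% "ns", "-",
                  sprintf("%.2f", df$cohens_d)),
           " |")
  }
  rpt <- c("# Group differences in VR/community navigation",
           "",
           "| Variable | Controls (Mean; SD) | Patients (Mean; SD) | Test | Significance | Cohen's d |",
           "|---|---|---|---|---|---|",
           fmt_cmp(results$step1_vr), fmt_cmp(results$step2_dnt), "")
  if (nrow(results$step1_ancova)) {
    rpt <- c(rpt, "## ANCOVA (controlling for map-view duration)", "",
             sprintf("- %s: F(%d,%d) = %.3f, p = %.4g (%s transform)",
                     results$step1_ancova$outcome, results$step1_ancova$df_between,
                     results$step1_ancova$df_within, results$step1_ancova$F_statistic,
                     results$step1_ancova$p_value, results$step1_ancova$transform_applied),
             "")
  }
  if (nrow(results$step3_regression)) {
    rpt <- c(rpt, "## Predicting the composite disorientation score (patients)", "",
             sprintf("- %s: beta = %.3f, p = %.4g, R^2 = %.3f, f^2 = %.3f%s",
                     results$step3_regression$label,
                     results$step3_regression$beta_standardized,
                     results$step3_regression$p_value,
                     results$step3_regression$r_squared,
                     results$step3_regression$f_squared,
                     ifelse(results$step3_regression$n_imputed > 0,
                            sprintf(" (%d imputed)", results$step3_regression$n_imputed), "")),
             "")
  }
  if (nrow(results$step4_logistic)) {
    rpt <- c(rpt, "## Predicting the high/low disorientation-risk label", "",
             sprintf("- %s: OR = %.2f, p = %.4g%s",
                     results$step4_logistic$predictor,
                     results$step4_logistic$odds_ratio,
                     results$step4_logistic$p_value,
                     ifelse(nzchar(results$step4_logistic$note),
                            paste0(" [", results$step4_logistic$note, "]"), "")),
             "")
  }
  writeLines(rpt, file.path(dir, "report.md"))
  invisible(dir)
}

#' Cohort table CSV round trip
#'
#' UTF-8, comma-separated, header required; missing values are empty
#' strings; rows sorted by `participant_id` for determinism.
#'
#' @param cohort cohort tibble.
#' @param path CSV file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort <- cohort[order(cohort$participant_id), , drop = FALSE]
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  miss <- setdiff(c("participant_id", "group"), names(df))
  if (length(miss)) stop_navdis("file %s: missing column %s", path,
                                paste(miss, collapse = ", "))
  df$group <- factor(df$group, levels = c("control", "patient"))
  tibble::as_tibble(df)
}
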
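#' @name report_pipeline
#' @title End-to-end validation study pipeline
#'
#' @description
#' Orchestrates scoring, intraoperative grading, association testing,
#' diagnostic-accuracy estimation, score-grade correlation and logistic
#' regression into a single deterministic report with per-variable
#' test-selection logging.
NULL

#' Configuration for [run_study()]
#'
#' @param cutoff score cutoff for the dichotomous prediction (strictly
#'   greater than), default 3.
#' @param ci_level confidence level for all intervals, default 0.95.
#' @param exact_threshold use an exact test whenever any expected cell
#'   count falls below this value (default 5), otherwise chi-square.
#' @param bands three-way preoperative category bands, see
#'   [categorize_preop()].
#' @param normality_alpha significance level of the normality screen that
#'   switches continuous comparisons from t to Mann-Whitney, default 0.05.
#' @param regression_predictors names of cohort columns (plus
#'   `"preop_score"`) entered in the multivariate logistic model.
#' @param age_inclusive see [score_component()].
#' @return List of class `study_config`.
#' @export
study_config <- function(cutoff = 3, ci_level = 0.95, exact_threshold = 5,
                         bands = c(5, 9), normality_alpha = 0.05,
                         regression_predictors = c("preop_score",
                                                   "hypertension",
                                                   "prior_hospitalization",
                                                   "gb_wall_thickened",
                                                   "pericholecystic_collection"),
                         age_inclusive = FALSE) {
  out <- list(cutoff = cutoff, ci_level = ci_level,
              exact_threshold = exact_threshold, bands = bands,
              normality_alpha = normality_alpha,
              regression_predictors = regression_predictors,
              age_inclusive = age_inclusive)
  class(out) <- "study_config"
  out
}

# contingency table of variable levels x (easy, difficult)
level_table <- function(values, levels, observed) {
  counts <- vapply(levels, function(l) c(sum(values == l & !observed),
                                         sum(values == l & observed)),
                   numeric(2))
  t(counts)  # rows = levels, cols = (easy, difficult)
}

# choose and run the association test for one contingency table,
# returning the test name, p-value, and the reason for the choice
select_association_test <- function(tab, exact_threshold) {
  keep <- rowSums(tab) > 0
  tab_used <- tab[keep, , drop = FALSE]
  if (nrow(tab_used) < 2L || any(colSums(tab_used) == 0))
    return(list(test = "none", p = NA_real_,
                reason = "degenerate table (fewer than 2 populated levels or empty outcome margin)"))
  expected <- outer(rowSums(tab_used), colSums(tab_used)) / sum(tab_used)
  if (any(expected < exact_threshold)) {
    if (nrow(tab_used) == 2L) {
      res <- fisher_exact_2x2(tab_used)
      list(test = "Fisher's exact test", p = res$p.value,
           reason = sprintf("min expected count %.2f < %g", min(expected),
                            exact_threshold))
    } else {
      res <- freeman_halton_rxc(tab_used)
      list(test = "Freeman-Halton exact test", p = res$p.value,
           reason = sprintf("min expected count %.2f < %g (r x c)",
                            min(expected), exact_threshold))
    }
  } else {
    res <- chi_square_test(tab_used)
    list(test = "Chi-square test", p = res$p.value,
         reason = sprintf("all expected counts >= %g", exact_threshold))
  }
}

#' Correlate the preoperative score with the intraoperative grade
#'
#' Spearman rank correlation of the score totals with the ordinal grade,
#' encoded easy = 0, difficult = 1, very difficult = 2 (Spearman operates
#' on ranks, so any order-preserving encoding is equivalent).
#'
#' @param scores a `preop_score` table or numeric totals.
#' @param grades a `difficulty_grade` table or ordered factor of grades.
#' @return An `htest` from [spearman_rho()].
#' @export
correlate_score_with_grade <- function(scores, grades) {
  tot <- score_totals(scores)
  g <- if (is.data.frame(grades)) grades$grade else grades
  if (!is.factor(g)) g <- factor(g, levels = grade_levels, ordered = TRUE)
  if (any(is.na(g))) stop("invalid grade value")
  spearman_rho(tot, as.integer(g) - 1L)
}

#' Run the full validation study
#'
#' Scores the cohort, grades the operations, tabulates associations of
#' each preoperative variable with the dichotomized outcome (selecting
#' exact vs chi-square tests by expected cell counts and logging every
#' choice), estimates diagnostic accuracy of the `> cutoff` prediction
#' with exact intervals and a ROC curve, correlates score with grade, and
#' fits the multivariate logistic model.  Deterministic: identical inputs
#' give identical reports.
#'
#' @param patients cohort table (see [validate_patient_records()]).
#' @param intraop intraoperative table (see
#'   [validate_intraop_records()]); patient_ids must match 1:1.
#' @param config a [study_config()].
#' @return Object of class `study_report`: list with `cohort_summary`,
#'   `association_table`, `diagnostic_summary`, `correlation`,
#'   `regression_table`, `discrepancy_notes`, `log`.
#' @examples
#' coh <- fixture_150()
#' rep <- run_study(coh$patients, coh$intraop)
#' rep$diagnostic_summary$metrics
#' @export
run_study <- function(patients, intraop, config = study_config()) {
  patients <- validate_patient_records(patients)
  intraop <- validate_intraop_records(intraop)
  only_p <- setdiff(patients$patient_id, intraop$patient_id)
  only_i <- setdiff(intraop$patient_id, patients$patient_id)
  if (length(only_p) || length(only_i))
    stop("patient_id mismatch between cohort and intraop tables; ",
         "cohort-only: ", paste(head(only_p, 5), collapse = ", "),
         if (length(only_p) > 5) " ..." else "",
         "; intraop-only: ", paste(head(only_i, 5), collapse = ", "),
         if (length(only_i) > 5) " ..." else "")
  intraop <- intraop[match(patients$patient_id, intraop$patient_id), ]
  log <- character()
  notes <- character()
  note <- function(msg) notes <<- c(notes, msg)
  logit <- function(...) log <<- c(log, sprintf(...))

  scores <- compute_preop_score(patients, age_inclusive = config$age_inclusive)
  predicted <- predict_difficult(scores, cutoff = config$cutoff)
  grades <- grade_operation(intraop)
  observed <- dichotomize_grade(grades)
  n <- nrow(patients)
  logit("scored %d patients; %d predicted difficult at cutoff > %g",
        n, sum(predicted), config$cutoff)
  logit("graded %d operations: %s", n,
        paste(sprintf("%s %d", grade_levels, table(grades$grade)), collapse = ", "))

  # -- cohort summary -------------------------------------------------
  grade_counts <- as.integer(table(grades$grade))
  cohort_summary <- list(
    n = n,
    grade_distribution = data.frame(
      grade = grade_levels, count = grade_counts,
      percent = round_half_up(100 * grade_counts / n, 2)),
    mean_score = mean(scores$total), sd_score = sd(scores$total),
    mean_age = mean(patients$age_years), sd_age = sd(patients$age_years),
    preop_category = data.frame(
      category = grade_levels,
      count = as.integer(table(categorize_preop(scores, config$bands)))))

  # -- association table ----------------------------------------------
  cat_vars <- list(
    sex = list(values = patients$sex, levels = c("female", "male")),
    diabetes = if ("diabetes" %in% names(patients))
      list(values = ifelse(patients$diabetes, "yes", "no"),
           levels = c("no", "yes")),
    hypertension = if ("hypertension" %in% names(patients))
      list(values = ifelse(patients$hypertension, "yes", "no"),
           levels = c("no", "yes")),
    prior_hospitalization = list(
      values = ifelse(patients$prior_hospitalization, "yes", "no"),
      levels = c("no", "yes")),
    bmi_band = list(
      values = c("under_25", "b25_to_27.5", "over_27.5")[
        1L + (patients$bmi >= 25) + (patients$bmi > 27.5)],
      levels = c("under_25", "b25_to_27.5", "over_27.5")),
    abdominal_scar = list(values = patients$abdominal_scar,
                          levels = scar_levels),
    palpable_gallbladder = list(
      values = ifelse(patients$palpable_gallbladder, "yes", "no"),
      levels = c("no", "yes")),
    gb_wall_thickened = list(
      values = ifelse(patients$gb_wall_thickened, "yes", "no"),
      levels = c("no", "yes")),
    impacted_stone = list(
      values = ifelse(patients$impacted_stone, "yes", "no"),
      levels = c("no", "yes")),
    pericholecystic_collection = list(
      values = ifelse(patients$pericholecystic_collection, "yes", "no"),
      levels = c("no", "yes")))
  cat_vars <- Filter(Negate(is.null), cat_vars)

  assoc_rows <- list()
  for (v in names(cat_vars)) {
    spec_v <- cat_vars[[v]]
    tab <- level_table(spec_v$values, spec_v$levels, observed)
    sel <- select_association_test(tab, config$exact_threshold)
    logit("association '%s': %s (%s)", v, sel$test, sel$reason)
    row_tot <- rowSums(tab)
    assoc_rows[[v]] <- data.frame(
      variable = v, level = spec_v$levels,
      n_easy = tab[, 1], n_difficult = tab[, 2],
      pct_easy = ifelse(row_tot > 0, round_half_up(100 * tab[, 1] / row_tot, 2), NA),
      pct_difficult = ifelse(row_tot > 0, round_half_up(100 * tab[, 2] / row_tot, 2), NA),
      test = sel$test, p_value = sel$p, stringsAsFactors = FALSE)
  }
  association_table <- do.call(rbind, c(assoc_rows, make.row.names = FALSE))

  # continuous comparisons: normality screen picks t vs Mann-Whitney
  cont <- list(age_years = patients$age_years, preop_score = scores$total)
  continuous_table <- do.call(rbind, lapply(names(cont), function(v) {
    x <- cont[[v]][!observed]; y <- cont[[v]][observed]
    use_mw <- TRUE
    reason <- "normality screen unavailable (group too small)"
    if (length(x) >= 5 && length(y) >= 5 && sd(x) > 0 && sd(y) > 0) {
      ks_p <- min(ks_normality(x)$p.value, ks_normality(y)$p.value)
      use_mw <- ks_p < config$normality_alpha
      reason <- sprintf("min KS normality p = %.3g", ks_p)
    }
    res <- if (use_mw) mann_whitney_u(x, y) else t_test_unpaired(x, y)
    logit("continuous '%s': %s (%s)", v,
          if (use_mw) "Mann-Whitney" else "t test", reason)
    data.frame(variable = v,
               mean_easy = mean(x), sd_easy = sd(x),
               mean_difficult = mean(y), sd_difficult = sd(y),
               test = if (use_mw) "Mann-Whitney" else "Unpaired t",
               p_value = res$p.value, stringsAsFactors = FALSE)
  }))

  # -- diagnostic accuracy ---------------------------------------------
  diagnostic_summary <- NULL
  if (any(observed) && !all(observed)) {
    ct <- confusion_table(predicted, observed)
    metrics <- diagnostic_metrics(ct, level = config$ci_level)
    roc <- roc_curve(scores$total, observed, level = config$ci_level)
    youden <- optimal_cutoff_youden(roc)
    if (any(metrics$undefined))
      note(paste("undefined diagnostic metric(s):",
                 paste(metrics$metric[metrics$undefined], collapse = ", ")))
    diagnostic_summary <- list(confusion = ct, metrics = metrics, roc = roc,
                               youden = youden, cutoff = config$cutoff)
    logit("diagnostics at cutoff > %g: AUC %.3f, Youden-optimal threshold %g",
          config$cutoff, roc$auc, youden$threshold)
  } else {
    note("only one outcome class observed: diagnostic accuracy skipped")
  }

  # -- correlation ------------------------------------------------------
  correlation <- withCallingHandlers(
    correlate_score_with_grade(scores, grades),
    warning = function(w) {
      note(paste("correlation:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })

  # -- multivariate logistic -------------------------------------------
  regression_table <- NULL
  regression_fit <- NULL
  if (any(observed) && !all(observed)) {
    df <- patients
    df$preop_score <- scores$total
    df$outcome <- observed
    preds <- intersect(config$regression_predictors, names(df))
    dropped <- setdiff(config$regression_predictors, names(df))
    if (length(dropped))
      note(paste("regression predictors absent from cohort:",
                 paste(dropped, collapse = ", ")))
    preds <- preds[vapply(preds, function(p) length(unique(df[[p]])) > 1L,
                          logical(1))]
    if (length(preds)) {
      fml <- stats::as.formula(paste("outcome ~", paste(preds, collapse = " + ")))
      regression_fit <- withCallingHandlers(
        tryCatch(fit_logistic(fml, data = df), error = function(e) {
          note(paste("logistic regression failed:", conditionMessage(e)))
          NULL
        }),
        warning = function(w) {
          note(paste("logistic regression:", conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      if (!is.null(regression_fit)) {
        regression_table <- regression_fit$table
        logit("logistic model: outcome ~ %s (%d iterations%s)",
              paste(preds, collapse = " + "), regression_fit$iterations,
              if (regression_fit$separation) ", separation flagged" else "")
      }
    } else {
      note("no usable regression predictors (all constant)")
    }
  }

  out <- list(cohort_summary = cohort_summary,
              association_table = association_table,
              continuous_table = continuous_table,
              diagnostic_summary = diagnostic_summary,
              correlation = correlation,
              regression_table = regression_table,
              regression_fit = regression_fit,
              discrepancy_notes = notes, log = log,
              config = config)
  class(out) <- "study_report"
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Validation study report: %d patients\n", x$cohort_summary$n))
  gd <- x$cohort_summary$grade_distribution
  cat("Operative difficulty: ",
      paste(sprintf("%s %d (%.2f%%)", gd$grade, gd$count, gd$percent),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$diagnostic_summary)) {
    m <- x$diagnostic_summary$metrics
    cat(sprintf("Score > %g vs observed difficulty:\n", x$diagnostic_summary$cutoff))
    for (i in seq_len(nrow(m)))
      cat(sprintf("  %-12s %s\n", m$metric[i],
                  if (m$undefined[i]) "undefined (zero denominator)"
                  else sprintf("%.2f%% (%.1f-%.1f%%)", 100 * m$estimate[i],
                               100 * m$lower[i], 100 * m$upper[i])))
    cat(sprintf("  AUC          %.3f (SE %.4f)\n",
                x$diagnostic_summary$roc$auc, x$diagnostic_summary$roc$auc_se))
  }
  if (!is.null(x$correlation) && !is.na(x$correlation$p.value))
    cat(sprintf("Score-grade Spearman rho %.3f (p = %.3g)\n",
                x$correlation$estimate, x$correlation$p.value))
  if (length(x$discrepancy_notes)) {
    cat("Notes:\n")
    for (nn in x$discrepancy_notes) cat("  -", nn, "\n")
  }
  invisible(x)
}

#' Serialize a study report
#'
#' Writes `report.json` plus per-table CSVs (`association.csv`,
#' `continuous.csv`, `diagnostics.csv`, `regression.csv`,
#' `roc_points.csv`, `grade_distribution.csv`) into `dir`.  The JSON
#' carries no timestamp, so identical reports serialize byte-identically.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the path of `report.json`.
#' @export
write_study_report <- function(report, dir) {
  if (!inherits(report, "study_report")) stop("'report' must be a study_report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- report$diagnostic_summary
  json <- list(
    cohort_summary = report$cohort_summary,
    association_table = report$association_table,
    continuous_table = report$continuous_table,
    diagnostics = if (!is.null(ds)) list(
      confusion = unclass(ds$confusion),
      metrics = ds$metrics,
      auc = ds$roc$auc, auc_se = ds$roc$auc_se, auc_ci = ds$roc$auc_ci,
      youden = ds$youden, cutoff = ds$cutoff),
    correlation = if (!is.null(report$correlation))
      list(rho = unname(report$correlation$estimate),
           p_value = report$correlation$p.value),
    regression_table = report$regression_table,
    discrepancy_notes = report$discrepancy_notes,
    log = report$log)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  write.csv(report$association_table, file.path(dir, "association.csv"),
            row.names = FALSE)
  write.csv(report$continuous_table, file.path(dir, "continuous.csv"),
            row.names = FALSE)
  write.csv(report$cohort_summary$grade_distribution,
            file.path(dir, "grade_distribution.csv"), row.names = FALSE)
  if (!is.null(ds)) {
    write.csv(ds$metrics, file.path(dir, "diagnostics.csv"), row.names = FALSE)
    write.csv(data.frame(threshold = ds$roc$thresholds, fpr = ds$roc$fpr,
                         tpr = ds$roc$tpr),
              file.path(dir, "roc_points.csv"), row.names = FALSE)
  }
  if (!is.null(report$regression_table))
    write.csv(report$regression_table, file.path(dir, "regression.csv"),
              row.names = FALSE)
  invisible(path)
}
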
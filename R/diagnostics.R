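#' @name diagnostics
#' @title Diagnostic accuracy of the score against observed difficulty
#'
#' @description
#' Confusion-table metrics (sensitivity, specificity, PPV, NPV, accuracy)
#' with Clopper-Pearson exact confidence intervals, empirical ROC curves
#' with trapezoidal AUC and DeLong variance, Youden-index cutoff
#' selection, reconstruction of an integer confusion table from rounded
#' published metrics, and the Buderer sample-size formula for diagnostic
#' studies.  "Positive" throughout means "difficult cholecystectomy".
NULL

#' Cross-tabulate predictions against observed outcomes
#'
#' @param predicted,observed logical vectors of equal positive length;
#'   `TRUE` = difficult.
#' @return An object of class `confusion_table`: a list with integer
#'   fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_table <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("'predicted' and 'observed' must have equal length")
  if (!length(predicted)) stop("empty input")
  predicted <- as.logical(predicted); observed <- as.logical(observed)
  if (any(is.na(predicted)) || any(is.na(observed)))
    stop("inputs must not contain NA")
  out <- list(tp = sum(predicted & observed),
              fp = sum(predicted & !observed),
              fn = sum(!predicted & observed),
              tn = sum(!predicted & !observed))
  out <- lapply(out, as.integer)
  class(out) <- "confusion_table"
  out
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("difficult", "easy"),
                              observed = c("difficult", "easy")))
  cat("Confusion table (positive = difficult)\n")
  print(m)
  invisible(x)
}

as_confusion_table <- function(tp, fp, fn, tn) {
  out <- list(tp = as.integer(tp), fp = as.integer(fp),
              fn = as.integer(fn), tn = as.integer(tn))
  class(out) <- "confusion_table"
  out
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact (beta-quantile) interval: lower bound
#' `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`), upper bound
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param x number of successes (0..n).
#' @param n number of trials (> 0).
#' @param level confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)`; for vector `x`/`n`, a
#'   two-column matrix.
#' @examples
#' clopper_pearson_ci(16, 28)   # ~ (0.372, 0.755)
#' @export
clopper_pearson_ci <- function(x, n, level = 0.95) {
  stopifnot_scalar_prob(level, "level")
  if (any(n <= 0) || any(x < 0) || any(x > n) || any(x != round(x)) ||
      any(n != round(n)))
    stop("'x' must be an integer in 0..n with n > 0")
  a <- (1 - level) / 2
  lower <- ifelse(x == 0, 0, qbeta(a, x, n - x + 1))
  upper <- ifelse(x == n, 1, qbeta(1 - a, x + 1, n - x))
  if (length(x) == 1L && length(n) == 1L)
    return(c(lower = lower, upper = upper))
  cbind(lower = lower, upper = upper)
}

#' Diagnostic accuracy metrics with exact confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and
#' negative predictive values `tp/(tp+fp)` and `tn/(tn+fn)`, and accuracy
#' `(tp+tn)/total`, each with a Clopper-Pearson interval.  A metric whose
#' denominator is zero is flagged `undefined` (estimate and interval
#' `NA`), never propagated as `NaN`.
#'
#' @param ct a [confusion_table()].
#' @param level confidence level for the intervals, default 0.95.
#' @return A data.frame of class `diagnostic_metrics` with columns
#'   `metric`, `successes`, `trials`, `estimate`, `lower`, `upper`,
#'   `undefined`.
#' @examples
#' ct <- confusion_table(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' diagnostic_metrics(ct)
#' @export
diagnostic_metrics <- function(ct, level = 0.95) {
  if (!inherits(ct, "confusion_table")) stop("'ct' must be a confusion_table")
  defs <- list(sensitivity = c(ct$tp, ct$tp + ct$fn),
               specificity = c(ct$tn, ct$tn + ct$fp),
               ppv         = c(ct$tp, ct$tp + ct$fp),
               npv         = c(ct$tn, ct$tn + ct$fn),
               accuracy    = c(ct$tp + ct$tn, ct$tp + ct$fp + ct$fn + ct$tn))
  rows <- lapply(names(defs), function(m) {
    s <- defs[[m]][1]; tr <- defs[[m]][2]
    if (tr == 0)
      return(data.frame(metric = m, successes = s, trials = tr,
                        estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_, undefined = TRUE))
    ci <- clopper_pearson_ci(s, tr, level)
    data.frame(metric = m, successes = s, trials = tr, estimate = s / tr,
               lower = ci[["lower"]], upper = ci[["upper"]],
               undefined = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  class(out) <- c("diagnostic_metrics", "data.frame")
  out
}

#' Empirical ROC curve with trapezoidal AUC and DeLong variance
#'
#' Operating points are generated at every distinct score value (plus
#' `-Inf`) under the positivity rule "score strictly greater than the
#' threshold", so the curve runs exactly from (0,0) (threshold = max
#' score) to (1,1) (threshold = -Inf).  The AUC is the trapezoidal area;
#' its standard error and confidence interval use DeLong's placement-value
#' method (ties counted half).
#'
#' @param scores numeric score per subject.
#' @param observed logical, `TRUE` = difficult; both classes must occur.
#' @param level confidence level for the AUC interval, default 0.95.
#' @return An object of class `roc_curve`: list with `thresholds`
#'   (descending), `fpr`, `tpr`, `auc`, `auc_se`, `auc_ci`, `n_pos`,
#'   `n_neg`.
#' @export
roc_curve <- function(scores, observed, level = 0.95) {
  if (length(scores) != length(observed)) stop("length mismatch")
  observed <- as.logical(observed)
  if (any(is.na(scores)) || any(is.na(observed))) stop("NA in input")
  n_pos <- sum(observed); n_neg <- sum(!observed)
  if (n_pos == 0L || n_neg == 0L)
    stop("both outcome classes must be present for a ROC curve")
  thr <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[observed] > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!observed] > t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  # DeLong placement values
  pos <- scores[observed]; neg <- scores[!observed]
  v10 <- vapply(pos, function(s) (sum(neg < s) + 0.5 * sum(neg == s)) / n_neg,
                numeric(1))
  v01 <- vapply(neg, function(s) (sum(pos > s) + 0.5 * sum(pos == s)) / n_pos,
                numeric(1))
  s10 <- if (n_pos > 1) var(v10) else 0
  s01 <- if (n_neg > 1) var(v01) else 0
  se <- sqrt(s10 / n_pos + s01 / n_neg)
  z <- qnorm(1 - (1 - level) / 2)
  ci <- c(lower = max(0, auc - z * se), upper = min(1, auc + z * se))
  out <- list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
              auc_se = se, auc_ci = ci, n_pos = n_pos, n_neg = n_neg)
  class(out) <- "roc_curve"
  out
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives, %d negatives, %d thresholds\n",
              x$n_pos, x$n_neg, length(x$thresholds)))
  cat(sprintf("AUC %.4f (SE %.4f, CI %.4f-%.4f)\n",
              x$auc, x$auc_se, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' Optimal cutoff by the Youden index
#'
#' Selects the threshold maximizing J = sensitivity + specificity - 1;
#' ties are broken toward higher specificity (and, among equals, the
#' higher threshold).
#'
#' @param curve a [roc_curve()].
#' @return List with `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
optimal_cutoff_youden <- function(curve) {
  if (!inherits(curve, "roc_curve")) stop("'curve' must be a roc_curve")
  j <- curve$tpr - curve$fpr
  ord <- order(-j, curve$fpr, -curve$thresholds)
  i <- ord[1]
  list(threshold = curve$thresholds[i], J = j[i],
       sensitivity = curve$tpr[i], specificity = 1 - curve$fpr[i])
}

#' Reconstruct an integer confusion table from rounded published metrics
#'
#' Exhaustively enumerates every integer table `(tp, fp, fn, tn)` summing
#' to `total` and keeps those whose metrics round (half-up) to the quoted
#' values at their printed precision.  A quoted metric constrains only
#' tables where its denominator is positive (a degenerate table cannot
#' contradict a metric it does not define).  The outcome is reported
#' explicitly: a unique table, the full list of ambiguous candidates, or
#' "no solution" - never a silent choice.
#'
#' @param metrics named numeric vector of quoted percentages, names among
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`
#'   (e.g. `c(specificity = 79.51, ppv = 39, npv = 89)`).
#' @param total cohort size.
#' @param digits optional named integer vector of printed decimal places;
#'   by default inferred from each quoted value (79.51 has 2, 39 has 0).
#' @return An object of class `confusion_reconstruction`: list with
#'   `status` ("unique", "ambiguous" or "none"), `candidates` (list of
#'   [confusion_table()] objects) and, when unique, `table`.
#' @examples
#' reconstruct_confusion_table(
#'   c(specificity = 79.51, ppv = 39, npv = 89), total = 150)
#' @export
reconstruct_confusion_table <- function(metrics, total, digits = NULL) {
  if (is.null(names(metrics)) || any(!nzchar(names(metrics))))
    stop("'metrics' must be a named vector")
  valid <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
  if (!all(names(metrics) %in% valid))
    stop("metric names must be among: ", paste(valid, collapse = ", "))
  if (total <= 0 || total != round(total)) stop("'total' must be a positive integer")
  if (is.null(digits))
    digits <- vapply(metrics, decimal_places, integer(1))
  digits <- digits[names(metrics)]

  g <- expand.grid(tp = 0:total, fp = 0:total, fn = 0:total)
  g <- g[g$tp + g$fp + g$fn <= total, , drop = FALSE]
  g$tn <- total - g$tp - g$fp - g$fn

  num <- list(sensitivity = g$tp, specificity = g$tn, ppv = g$tp,
              npv = g$tn, accuracy = g$tp + g$tn)
  den <- list(sensitivity = g$tp + g$fn, specificity = g$tn + g$fp,
              ppv = g$tp + g$fp, npv = g$tn + g$fn,
              accuracy = rep(total, nrow(g)))
  keep <- rep(TRUE, nrow(g))
  for (m in names(metrics)) {
    d <- den[[m]]
    val <- 100 * num[[m]] / d
    match_m <- d == 0 |
      abs(round_half_up(val, digits[[m]]) - metrics[[m]]) < 1e-9
    keep <- keep & match_m
  }
  cand <- g[keep, , drop = FALSE]
  candidates <- lapply(seq_len(nrow(cand)), function(i)
    as_confusion_table(cand$tp[i], cand$fp[i], cand$fn[i], cand$tn[i]))
  status <- if (nrow(cand) == 1L) "unique"
            else if (nrow(cand) == 0L) "none" else "ambiguous"
  out <- list(status = status, candidates = candidates,
              metrics = metrics, digits = digits, total = total)
  if (status == "unique") out$table <- candidates[[1]]
  class(out) <- "confusion_reconstruction"
  out
}

#' @export
print.confusion_reconstruction <- function(x, ...) {
  cat(sprintf("Confusion-table reconstruction (total = %d): %s\n",
              x$total, switch(x$status,
                              unique = "unique solution",
                              ambiguous = sprintf("%d candidate tables",
                                                  length(x$candidates)),
                              none = "no table matches the quoted metrics")))
  if (x$status == "unique") print(x$table)
  invisible(x)
}

#' Buderer sample size for estimating sensitivity or specificity
#'
#' `n = ceiling( z^2 p (1 - p) / d^2 / prev )` where `p` is the
#' anticipated sensitivity (divide by the prevalence) or specificity
#' (divide by one minus the prevalence), `d` the desired absolute
#' precision (half-width of the 95 percent interval), and
#' `z = qnorm(1 - alpha/2)`.
#'
#' @param p anticipated sensitivity or specificity, in (0,1).
#' @param precision desired absolute precision `d`, in (0,1).
#' @param alpha significance level, default 0.05.
#' @param prevalence anticipated prevalence of the condition.
#' @param measure `"sensitivity"` (default) or `"specificity"`.
#' @return Integer minimum sample size.
#' @examples
#' sample_size_diagnostic(0.9574, 0.10, prevalence = 1)   # 16
#' @export
sample_size_diagnostic <- function(p, precision, alpha = 0.05, prevalence,
                                   measure = c("sensitivity", "specificity")) {
  measure <- match.arg(measure)
  stopifnot_scalar_prob(p, "p")
  stopifnot_scalar_prob(precision, "precision")
  stopifnot_scalar_prob(alpha, "alpha")
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence < 0 || prevalence > 1)
    stop("'prevalence' must be a single probability")
  frac <- if (measure == "sensitivity") prevalence else 1 - prevalence
  if (frac <= 0)
    stop("prevalence leaves no subjects with the condition status that '",
         measure, "' is estimated from")
  z <- qnorm(1 - alpha / 2)
  as.integer(ceiling(z^2 * p * (1 - p) / precision^2 / frac))
}
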
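test_that("confusion tables cross-tabulate predictions against outcomes", {
  ct <- confusion_table(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_identical(unclass(ct)[c("tp", "fp", "fn", "tn")],
                   list(tp = 1L, fp = 0L, fn = 0L, tn = 1L))
  all_missed <- confusion_table(rep(FALSE, 7), rep(TRUE, 7))
  expect_identical(all_missed$fn, 7L)
  coh <- fixture_150()
  sc <- compute_preop_score(coh$patients)
  ct150 <- confusion_table(predict_difficult(sc),
                           dichotomize_grade(grade_operation(coh$intraop)))
  expect_identical(ct150$tp + ct150$fp + ct150$fn + ct150$tn, 150L)
  expect_error(confusion_table(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("Clopper-Pearson intervals hit the published bounds and a bisection oracle", {
  expect_identical(unname(clopper_pearson_ci(0, 10)[1]), 0)
  expect_identical(unname(clopper_pearson_ci(10, 10)[2]), 1)
  # published specificity interval: 97/122 -> 71.3%-86.3% at one decimal
  ci <- clopper_pearson_ci(97, 122)
  expect_equal(round(100 * ci, 1), c(lower = 71.3, upper = 86.3))
  # bisection oracle on the binomial CDF for 5/10:
  # lower solves P(X >= 5 | p) = 0.025, upper solves P(X <= 5 | p) = 0.025
  lower_fn <- function(p) 1 - pbinom(4, 10, p) - 0.025
  upper_fn <- function(p) pbinom(5, 10, p) - 0.025
  lo <- uniroot(lower_fn, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  hi <- uniroot(upper_fn, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  expect_equal(unname(clopper_pearson_ci(5, 10)), c(lo, hi), tolerance = 1e-9)
  expect_error(clopper_pearson_ci(11, 10), "0..n")
})

test_that("interval width shrinks with n and empirical coverage is conservative", {
  widths <- vapply(c(20, 50, 200, 1000), function(n) {
    ci <- clopper_pearson_ci(round(0.3 * n), n)
    ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  set.seed(607)
  for (p in c(0.1, 0.35, 0.6, 0.9)) {
    for (n in c(25, 80)) {
      xs <- rbinom(3000, n, p)
      ci <- clopper_pearson_ci(xs, n)
      covered <- ci[, "lower"] <= p & p <= ci[, "upper"]
      expect_gte(mean(covered), 0.95)
    }
  }
})

test_that("diagnostic metrics reproduce the reconstructed validation table", {
  ct <- as_ct <- structure(list(tp = 16L, fp = 25L, fn = 12L, tn = 97L),
                           class = "confusion_table")
  m <- diagnostic_metrics(ct)
  est <- setNames(m$estimate, m$metric)
  expect_equal(round(100 * est[["sensitivity"]], 2), 57.14)
  expect_equal(round(100 * est[["specificity"]], 2), 79.51)
  expect_equal(round(100 * est[["ppv"]], 2), 39.02)
  expect_equal(round(100 * est[["npv"]], 2), 88.99)
  expect_equal(round(100 * est[["accuracy"]], 2), 75.33)
  sens <- m[m$metric == "sensitivity", ]
  expect_equal(round(100 * c(sens$lower, sens$upper), 1), c(37.2, 75.5))
  # estimates sit inside their intervals
  ok <- !m$undefined
  expect_true(all(m$lower[ok] <= m$estimate[ok] & m$estimate[ok] <= m$upper[ok]))
})

test_that("degenerate denominators are flagged undefined, perfect tables score 1", {
  perfect <- confusion_table(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  m <- diagnostic_metrics(perfect)
  expect_true(all(m$estimate == 1))
  no_pos <- confusion_table(c(FALSE, FALSE), c(FALSE, FALSE))
  m2 <- diagnostic_metrics(no_pos)
  expect_true(all(m2$undefined[m2$metric %in% c("sensitivity", "ppv")]))
  expect_false(any(is.nan(m2$estimate)))
})

test_that("accuracy equals the prevalence-weighted mix of sensitivity and specificity", {
  set.seed(88)
  for (i in 1:30) {
    cells <- sample(0:40, 4, replace = TRUE)
    if (sum(cells) == 0) next
    ct <- structure(list(tp = cells[1], fp = cells[2], fn = cells[3],
                         tn = cells[4]), class = "confusion_table")
    m <- diagnostic_metrics(ct)
    est <- setNames(m$estimate, m$metric)
    P <- cells[1] + cells[3]; N <- cells[2] + cells[4]
    if (P == 0 || N == 0) next
    expect_equal(est[["accuracy"]],
                 unname((est[["sensitivity"]] * P + est[["specificity"]] * N) /
                          (P + N)))
  }
})

test_that("ROC curves span (0,0) to (1,1), and AUC equals the rank statistic", {
  sep <- roc_curve(c(1, 2, 3, 10, 11, 12), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(sep$auc, 1)
  expect_equal(c(sep$fpr[1], sep$tpr[1]), c(0, 0))
  expect_equal(c(sep$fpr[length(sep$fpr)], sep$tpr[length(sep$tpr)]), c(1, 1))
  set.seed(505)
  big <- roc_curve(sample(0:12, 4000, replace = TRUE),
                   sample(c(TRUE, FALSE), 4000, replace = TRUE))
  mc_sd <- sqrt((big$n_pos + big$n_neg + 1) / (12 * big$n_pos * big$n_neg))
  expect_lt(abs(big$auc - 0.5), 3 * mc_sd)
  # AUC == U / (n1 n0) with midrank ties, on assorted tied inputs
  for (i in 1:30) {
    n <- sample(10:60, 1)
    scores <- sample(0:8, n, replace = TRUE)
    obs <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(obs) || all(obs)) next
    rc <- roc_curve(scores, obs)
    u <- unname(mann_whitney_u(scores[obs], scores[!obs])$statistic)
    expect_equal(rc$auc, u / (sum(obs) * sum(!obs)), tolerance = 1e-12)
    # monotone operating points
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    # invariant under strictly monotone score transforms
    expect_equal(roc_curve(exp(scores / 3), obs)$auc, rc$auc)
  }
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both")
})

test_that("DeLong AUC standard error matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  for (i in 1:10) {
    n <- 120
    obs <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.3, 0.7))
    scores <- rpois(n, 3) + 3 * obs
    if (!any(obs) || all(obs)) next
    rc <- roc_curve(scores, obs)
    pr <- pROC::roc(obs, scores, quiet = TRUE, direction = "<")
    expect_equal(rc$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
    expect_equal(rc$auc_se, sqrt(pROC::var(pr, method = "delong")),
                 tolerance = 1e-8)
  }
})

test_that("Youden cutoff maximizes J and breaks ties toward specificity", {
  sep <- roc_curve(c(1, 1, 2, 5, 6), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  opt <- optimal_cutoff_youden(sep)
  expect_equal(opt$J, 1)
  expect_equal(opt$threshold, 2)
  flat <- roc_curve(c(1, 1, 1, 2, 2, 2), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(optimal_cutoff_youden(flat)$J, 0)
  # tie on J: prefer the point with the lower false-positive rate
  rc <- roc_curve(c(0, 1, 2, 3), c(FALSE, FALSE, TRUE, TRUE))
  opt2 <- optimal_cutoff_youden(rc)
  expect_equal(opt2$specificity, 1)
  # cutoff recovery: strong score effect at a known changepoint
  set.seed(42)
  n <- 600
  score <- sample(0:12, n, replace = TRUE)
  diff_p <- ifelse(score > 3, 0.85, 0.10)
  obs <- runif(n) < diff_p
  opt3 <- optimal_cutoff_youden(roc_curve(score, obs))
  expect_equal(opt3$threshold, 3)
})

test_that("confusion-table reconstruction finds the unique published table", {
  rec <- reconstruct_confusion_table(
    c(specificity = 79.51, ppv = 39, npv = 89), total = 150)
  expect_equal(rec$status, "unique")
  expect_identical(unclass(rec$table)[c("tp", "fp", "fn", "tn")],
                   list(tp = 16L, fp = 25L, fn = 12L, tn = 97L))
  # round trip: the reconstructed table reproduces every quoted figure
  m <- diagnostic_metrics(rec$table)
  est <- setNames(m$estimate, m$metric)
  expect_equal(round(100 * est[["sensitivity"]], 2), 57.14)
  expect_equal(round(100 * est[["specificity"]], 2), 79.51)
  expect_equal(round(100 * est[["ppv"]], 0), 39)
  expect_equal(round(100 * est[["npv"]], 0), 89)
})

test_that("reconstruction reports ambiguity and inconsistency explicitly", {
  amb <- reconstruct_confusion_table(
    c(sensitivity = 100, specificity = 100), total = 2)
  expect_equal(amb$status, "ambiguous")
  cand <- t(vapply(amb$candidates,
                   function(ct) c(ct$tp, ct$fp, ct$fn, ct$tn), integer(4)))
  expect_equal(nrow(cand), 3)
  expect_true(all(apply(cand, 1, paste, collapse = ",") %in%
                    c("1,0,0,1", "2,0,0,0", "0,0,0,2")))
  # the published specificity and PPV are inconsistent with NPV 85%:
  # no integer table at n = 150 reproduces all three
  none <- reconstruct_confusion_table(
    c(specificity = 79.51, ppv = 39, npv = 85), total = 150)
  expect_equal(none$status, "none")
  expect_length(none$candidates, 0)
})

test_that("Buderer sample sizes match direct arithmetic and scale as expected", {
  expect_identical(sample_size_diagnostic(0.9574, 0.10, 0.05, prevalence = 1), 16L)
  # shrinks monotonically in the precision
  ns <- vapply(c(0.02, 0.05, 0.1, 0.2), function(d)
    sample_size_diagnostic(0.5, d, prevalence = 0.5), integer(1))
  expect_true(all(diff(ns) < 0))
  # quadruple when the normal quantile doubles (alpha chosen so z doubles)
  z1 <- qnorm(0.975)
  alpha2 <- 2 * pnorm(-2 * z1)
  n1 <- sample_size_diagnostic(0.8, 0.05, 0.05, prevalence = 1)
  n4 <- sample_size_diagnostic(0.8, 0.05, alpha2, prevalence = 1)
  expect_equal(n4, 4 * n1, tolerance = 0.01)
  # specificity divides by the complement of the prevalence
  expect_identical(
    sample_size_diagnostic(0.7368, 0.10, prevalence = 0.3, measure = "specificity"),
    as.integer(ceiling(qnorm(0.975)^2 * 0.7368 * 0.2632 / 0.01 / 0.7)))
  expect_error(sample_size_diagnostic(0.9, 0.1, prevalence = 1,
                                      measure = "specificity"), "prevalence")
})
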
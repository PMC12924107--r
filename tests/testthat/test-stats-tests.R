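test_that("Fisher's exact test reproduces the published 2x2 p-values", {
  # p-values round to the printed three-decimal figures
  expect_equal(round(fisher_exact_2x2(printed_tables$hypertension)$p.value, 3),
               0.002)
  expect_equal(round(fisher_exact_2x2(printed_tables$pericholecystic)$p.value, 3),
               0.001)
  # one-off margin: p is exactly 42/150
  expect_equal(fisher_exact_2x2(printed_tables$impacted_stone)$p.value,
               42 / 150, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
})

test_that("Fisher p matches brute-force enumeration for all totals <= 30", {
  # every 2x2 count table with grand total up to 30
  worst <- 0
  for (n in 1:30) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    parts <- parts[parts$a + parts$b + parts$c <= n, ]
    parts$d <- n - parts$a - parts$b - parts$c
    for (i in seq_len(nrow(parts))) {
      m <- matrix(unlist(parts[i, ]), 2, 2, byrow = TRUE)
      if (sum(m) == 0) next
      worst <- max(worst, abs(fisher_exact_2x2(m)$p.value -
                                fisher_bruteforce_p(m)))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("Fisher p agrees with the reference implementation on random tables", {
  set.seed(314)
  for (i in 1:200) {
    m <- random_table(2, 2, max_cell = 25)
    if (sum(m) == 0) next
    expect_equal(fisher_exact_2x2(m)$p.value, fisher.test(m)$p.value,
                 tolerance = 1e-7, info = paste(m, collapse = ","))
  }
})

test_that("Fisher p is invariant to transposition and row/column swaps", {
  set.seed(21)
  for (i in 1:50) {
    m <- random_table(2, 2, max_cell = 20)
    if (sum(m) == 0 ) next
    p <- fisher_exact_2x2(m)$p.value
    expect_equal(fisher_exact_2x2(t(m))$p.value, p)
    expect_equal(fisher_exact_2x2(m[2:1, ])$p.value, p)
    expect_equal(fisher_exact_2x2(m[, 2:1])$p.value, p)
  }
  expect_error(fisher_exact_2x2(matrix(0:5, 2)), "freeman_halton_rxc")
})

test_that("chi-square test reproduces the published uncorrected p-values", {
  expect_equal(round(chi_square_test(printed_tables$hospitalization)$p.value, 3),
               0.025)
  expect_equal(round(chi_square_test(printed_tables$gender)$p.value, 3),
               0.588)
  expect_equal(round(chi_square_test(printed_tables$diabetes)$p.value, 3),
               0.127)
  expect_lt(chi_square_test(printed_tables$gb_wall)$p.value, 0.0001)
  even <- matrix(c(50, 50, 50, 50), 2)
  res <- chi_square_test(even)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)
})

test_that("chi-square matches the reference implementation and its invariances", {
  set.seed(99)
  for (i in 1:50) {
    m <- random_table(sample(2:3, 1), sample(2:3, 1), max_cell = 30) + 1
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    mine <- chi_square_test(m)
    expect_equal(unname(mine$statistic), unname(ref$statistic))
    expect_equal(unname(mine$parameter), unname(ref$parameter))
    expect_equal(mine$p.value, ref$p.value)
    perm <- chi_square_test(m[sample(nrow(m)), sample(ncol(m))])
    expect_equal(unname(perm$statistic), unname(mine$statistic))
  }
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "exact")
})

test_that("Fisher and chi-square p agree closely for large-margin tables", {
  # the exact two-sided p approaches the Pearson p only at O(1/sqrt(n)),
  # so "large margins" means cells in the thousands
  set.seed(404)
  for (i in 1:30) {
    m <- matrix(rpois(4, lambda = 3000) + 100, 2)
    expect_lt(abs(fisher_exact_2x2(m)$p.value - chi_square_test(m)$p.value),
              0.02)
  }
})

test_that("Freeman-Halton extension reduces to Fisher on 2x2 and handles r x c", {
  set.seed(55)
  for (i in 1:30) {
    m <- random_table(2, 2, max_cell = 12)
    if (sum(m) == 0) next
    expect_equal(freeman_halton_rxc(m)$p.value, fisher_exact_2x2(m)$p.value,
                 tolerance = 1e-10)
  }
  expect_equal(freeman_halton_rxc(matrix(c(1, 0, 0, 1), 2))$p.value, 1)
  # r x c tables against the reference network-algorithm implementation
  for (i in 1:25) {
    m <- random_table(3, sample(2:3, 1), max_cell = 6)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(freeman_halton_rxc(m)$p.value, fisher.test(m)$p.value,
                 tolerance = 1e-6, info = paste(m, collapse = ","))
  }
  # the published 3-level tables run through the same machinery
  expect_equal(freeman_halton_rxc(printed_tables$bmi_3level)$p.value,
               fisher.test(printed_tables$bmi_3level)$p.value,
               tolerance = 1e-6)
  expect_error(freeman_halton_rxc(matrix(50, 4, 4), max_tables = 100),
               "max_tables")
})

test_that("Mann-Whitney U handles separation, ties and the exact small-sample tail", {
  expect_equal(unname(mann_whitney_u(1:3, 4:6)$statistic), 0)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  # n_x = 2, n_y = 1: one-sided tail 1/3, doubled
  expect_equal(mann_whitney_u(c(1, 2), 3)$p.value, 2 / 3, tolerance = 1e-12)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney matches the reference implementation", {
  set.seed(123)
  for (i in 1:30) {
    x <- rnorm(sample(3:15, 1)); y <- rnorm(sample(3:15, 1), mean = 0.5)
    mine <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(unname(mine$statistic), unname(ref$statistic))
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
    # U_x + U_y = n_x * n_y without ties
    expect_equal(unname(mine$statistic) +
                   unname(mann_whitney_u(y, x)$statistic),
                 length(x) * length(y))
  }
  # tied / large samples: tie-corrected normal approximation, no continuity
  for (i in 1:10) {
    x <- sample(1:6, 30, replace = TRUE); y <- sample(2:7, 25, replace = TRUE)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(mann_whitney_u(x, y)$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("unpaired t test matches hand and reference computations", {
  same <- t_test_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  # frozen from the closed form: pooled SD = sqrt(2), SE = sqrt(2)
  hand <- t_test_unpaired(c(0, 2), c(1, 3))
  expect_equal(unname(hand$statistic), -1 / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(hand$parameter), 2)
  expect_equal(hand$p.value, t.test(c(0, 2), c(1, 3), var.equal = TRUE)$p.value)
  # Welch equals pooled for equal n and equal variances
  x <- c(1, 2, 6); y <- c(3, 4, 8)
  expect_equal(t_test_unpaired(x, y, pooled = FALSE)$p.value,
               t_test_unpaired(x, y, pooled = TRUE)$p.value)
  set.seed(8)
  a <- rnorm(12); b <- rnorm(9, sd = 2)
  expect_equal(t_test_unpaired(a, b, pooled = FALSE)$p.value,
               t.test(a, b)$p.value)
  expect_error(t_test_unpaired(c(1, 1), c(1, 1)), "variance")
})

test_that("Spearman correlation matches the rank formula and flags constants", {
  expect_equal(unname(spearman_rho(1:5, 2 * (1:5))$estimate), 1)
  expect_equal(unname(spearman_rho(1:5, 6 - (1:5))$estimate), -1)
  # 1 - 6*4 / (4*15) = 0.6
  expect_equal(unname(spearman_rho(1:4, c(2, 1, 4, 3))$estimate), 0.6)
  set.seed(17)
  x <- rnorm(40); y <- x + rnorm(40)
  ref <- cor.test(x, y, method = "spearman")
  mine <- spearman_rho(x, y)
  expect_equal(unname(mine$estimate), unname(ref$estimate))
  expect_warning(res <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$estimate))
})

test_that("KS normality screen behaves on normal and two-point samples", {
  set.seed(2024)
  x <- rnorm(500)
  expect_gt(ks_normality(x)$p.value, 0.05)
  two_point <- rep(c(0, 1), each = 40)
  res <- ks_normality(two_point)
  expect_gte(unname(res$statistic), 0.25)
  expect_lt(res$p.value, 0.01)
  for (i in 1:20) {
    d <- unname(ks_normality(rnorm(30, sd = sample(1:5, 1)))$statistic)
    expect_true(d >= 0 && d <= 1)
  }
  expect_error(ks_normality(c(1, 2)), "at least 5")
})

test_that("every test returns a p-value in (0, 1]", {
  results <- list(
    fisher_exact_2x2(printed_tables$gb_wall),
    chi_square_test(printed_tables$gender),
    freeman_halton_rxc(printed_tables$scar_3level),
    mann_whitney_u(rnorm(10), rnorm(10)),
    t_test_unpaired(rnorm(10), rnorm(10)),
    spearman_rho(1:10, (1:10)^2),
    ks_normality(rnorm(20)))
  for (r in results) {
    expect_gt(r$p.value, 0)
    expect_lte(r$p.value, 1)
  }
})
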
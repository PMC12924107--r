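#' @name stats_tests
#' @title Hypothesis tests used in the validation analysis
#'
#' @description
#' Self-contained implementations of the tests the validation pipeline
#' relies on.  All functions return `htest` objects (the base-R convention)
#' with the p-value, any statistic and degrees of freedom, and a method
#' label, so results print like those of `stats` tests.  Exact tests use
#' full enumeration; the chi-square test is Pearson's without continuity
#' correction (the convention that reproduces standard clinical-software
#' output for 2x2 tables).
NULL

check_table <- function(x, name = "x") {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("'", name, "' must be a matrix of non-negative integer counts",
         call. = FALSE)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("'", name, "' must have at least 2 rows and 2 columns", call. = FALSE)
  if (sum(x) <= 0) stop("'", name, "' has zero grand total", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum, over all
#' tables with the observed margins, of hypergeometric probabilities no
#' larger than that of the observed table (ties admitted within a relative
#' tolerance of 1e-7).  No approximation is involved.
#'
#' @param x 2x2 matrix of non-negative integer counts.
#' @return An `htest` with the exact two-sided `p.value` and the sample
#'   odds ratio as `estimate` (ad-hoc, `NA` when a margin is zero).
#' @examples
#' fisher_exact_2x2(matrix(c(107, 1, 36, 6), nrow = 2))  # p ~ 0.002
#' @export
fisher_exact_2x2 <- function(x) {
  x <- check_table(x)
  if (nrow(x) != 2L || ncol(x) != 2L)
    stop("table is not 2x2; use freeman_halton_rxc() for r x c tables",
         call. = FALSE)
  r1 <- sum(x[1, ]); r2 <- sum(x[2, ]); c1 <- sum(x[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  dens <- dhyper(support, r1, r2, c1)
  d_obs <- dhyper(x[1, 1], r1, r2, c1)
  p <- min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
  or <- if (all(rowSums(x) > 0) && all(colSums(x) > 0) && x[1, 2] * x[2, 1] > 0)
    (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1]) else NA_real_
  make_htest("Fisher's exact test (two-sided, probability-mass rule)",
             p.value = p, estimate = c(`sample odds ratio` = or),
             data.name = sprintf("%d x %d contingency table", nrow(x), ncol(x)))
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson X^2 = sum (O-E)^2 / E without continuity correction, with
#' df = (r-1)(c-1) and the upper-tail chi-square p-value.  Uncorrected by
#' design: applying the Yates correction to 2x2 tables changes p-values
#' materially (e.g. 0.025 -> 0.042 on the hospitalization table this
#' package's acceptance checks reproduce).
#'
#' @param x r x c matrix of non-negative integer counts; every expected
#'   count must be positive.
#' @return An `htest` with `statistic` (X-squared), `parameter` (df) and
#'   `p.value`.
#' @examples
#' chi_square_test(matrix(c(86, 22, 26, 16), nrow = 2))  # p ~ 0.025
#' @export
chi_square_test <- function(x) {
  x <- check_table(x)
  expected <- outer(rowSums(x), colSums(x)) / sum(x)
  if (any(expected <= 0))
    stop("zero expected count (empty row or column margin); ",
         "use an exact test", call. = FALSE)
  stat <- sum((x - expected)^2 / expected)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  make_htest("Pearson's chi-square test (no continuity correction)",
             p.value = pchisq(stat, df, lower.tail = FALSE),
             statistic = c(`X-squared` = stat), parameter = c(df = df),
             data.name = sprintf("%d x %d contingency table", nrow(x), ncol(x)))
}

# enumerate all r x c tables with the given margins, accumulating the
# total probability of tables no more probable than the observed one;
# cells are filled row-major, the last cell of each row being forced by
# the row margin (so only free cells are looped over)
fh_enumerate <- function(row_sums, col_sums, log_const, log_p_obs, max_tables) {
  r <- length(row_sums); cc <- length(col_sums)
  n_seen <- 0L
  p_le <- 0
  cell <- matrix(0, r, cc)
  lfact <- function(n) lgamma(n + 1)
  recurse <- function(i, j, row_left, col_left) {
    if (i > r) {
      if (any(col_left != 0)) return()
      n_seen <<- n_seen + 1L
      if (n_seen > max_tables)
        stop("enumeration bound exceeded (max_tables = ", max_tables, ")",
             call. = FALSE)
      log_p <- log_const - sum(lfact(cell))
      if (log_p <= log_p_obs + log1p(1e-7)) p_le <<- p_le + exp(log_p)
      return()
    }
    if (j == cc) {
      v <- row_left
      if (v < 0 || v > col_left[j]) return()
      cell[i, j] <<- v
      cl <- col_left; cl[j] <- cl[j] - v
      recurse(i + 1L, 1L, if (i < r) row_sums[i + 1L] else 0, cl)
      return()
    }
    hi <- min(row_left, col_left[j])
    if (hi < 0) return()
    for (v in 0:hi) {
      cell[i, j] <<- v
      cl <- col_left; cl[j] <- cl[j] - v
      recurse(i, j + 1L, row_left - v, cl)
    }
  }
  recurse(1L, 1L, row_sums[1L], col_sums)
  list(p = p_le, n_tables = n_seen)
}

#' Freeman-Halton exact test for an r x c table
#'
#' Extends Fisher's exact test beyond 2x2 by full enumeration of all
#' tables sharing the observed margins; the two-sided p-value sums the
#' multivariate hypergeometric probabilities of tables no more probable
#' than the observed one (probability-mass rule, relative tie tolerance
#' 1e-7).  For a 2x2 input the result coincides with
#' [fisher_exact_2x2()].
#'
#' @param x r x c matrix of non-negative integer counts.
#' @param max_tables enumeration bound; the test aborts (with the bound in
#'   the message) rather than run unboundedly on large tables.
#' @return An `htest` with the exact `p.value`; the number of enumerated
#'   tables is reported in `parameter`.
#' @export
freeman_halton_rxc <- function(x, max_tables = 2e6) {
  x <- check_table(x)
  rs <- rowSums(x); cs <- colSums(x); n <- sum(x)
  lfact <- function(n) lgamma(n + 1)
  log_const <- sum(lfact(rs)) + sum(lfact(cs)) - lfact(n)
  log_p_obs <- log_const - sum(lfact(x))
  res <- fh_enumerate(rs, cs, log_const, log_p_obs, max_tables)
  make_htest("Freeman-Halton exact test (full enumeration)",
             p.value = min(1, res$p),
             parameter = c(`tables enumerated` = res$n_tables),
             data.name = sprintf("%d x %d contingency table", nrow(x), ncol(x)))
}

#' Mann-Whitney U test
#'
#' U is computed from midranks (ties shared).  When neither sample is tied
#' and `n_x * n_y` does not exceed `exact_limit`, the two-sided p-value is
#' exact: twice the smaller tail of the null U distribution, capped at 1.
#' Otherwise a normal approximation with tie-corrected variance is used,
#' without continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_limit use the exact null distribution when
#'   `length(x) * length(y) <= exact_limit` and there are no ties.
#' @return An `htest` with `statistic` U (for `x`) and `p.value`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 400) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (any(is.na(x)) || any(is.na(y))) stop("samples must not contain NA")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && nx * ny <= exact_limit) {
    p_lo <- pwilcox(u, nx, ny)
    p_hi <- pwilcox(u - 1, nx, ny, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "Mann-Whitney U test (exact)"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  make_htest(method, p.value = p, statistic = c(U = u),
             data.name = "x vs y")
}

#' Unpaired two-sample t test
#'
#' @param x,y numeric samples with at least two observations each.
#' @param pooled if `TRUE` (default) the classical equal-variance test;
#'   otherwise Welch's test with Satterthwaite degrees of freedom.
#' @return An `htest` with `statistic` t, `parameter` df, and `p.value`.
#' @export
t_test_unpaired <- function(x, y, pooled = TRUE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each sample needs at least 2 observations")
  vx <- var(x); vy <- var(y)
  if (pooled) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    if (sp2 <= 0) stop("degenerate (zero) pooled variance")
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
    method <- "Unpaired t test (pooled variance)"
  } else {
    if (vx / nx + vy / ny <= 0) stop("degenerate (zero) variance")
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    method <- "Welch's unpaired t test"
  }
  tstat <- (mean(x) - mean(y)) / se
  make_htest(method, p.value = 2 * pt(-abs(tstat), df),
             statistic = c(t = tstat), parameter = c(df = df),
             data.name = "x vs y")
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks; the p-value uses the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees
#' of freedom.  Constant input leaves rho undefined: the result carries
#' `estimate = NA` with a warning rather than a silent number.
#'
#' @param x,y paired numeric samples, `n >= 3`.
#' @return An `htest` with `estimate` rho and `p.value`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must be paired (equal length)")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (any(is.na(x)) || any(is.na(y))) stop("samples must not contain NA")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warning("constant input: Spearman's rho is undefined")
    return(make_htest("Spearman rank correlation (undefined: constant input)",
                      p.value = NA_real_, estimate = c(rho = NA_real_),
                      data.name = "x vs y"))
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin  # perfectly (anti)concordant ranks
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- max(2 * pt(-abs(tstat), n - 2), .Machine$double.xmin)
  }
  make_htest("Spearman rank correlation (t approximation)",
             p.value = p, estimate = c(rho = rho), data.name = "x vs y")
}

#' Kolmogorov-Smirnov normality check (plug-in mean and SD)
#'
#' One-sample KS statistic of the sample against a normal distribution
#' with the sample's own mean and standard deviation, with the asymptotic
#' Kolmogorov p-value.  Because the null parameters are estimated from the
#' same sample, the p-value is approximate (anti-conservative relative to
#' Lilliefors critical values); it is flagged as such in the method label
#' and intended for descriptive normality screening only.
#'
#' @param x numeric sample, `n >= 5`.
#' @return An `htest` with `statistic` D and the approximate `p.value`.
#' @export
ks_normality <- function(x) {
  n <- length(x)
  if (n < 5L) stop("need at least 5 observations")
  if (any(is.na(x))) stop("sample must not contain NA")
  s <- sd(x)
  if (s == 0) stop("degenerate sample (zero standard deviation)")
  z <- sort((x - mean(x)) / s)
  cdf <- pnorm(z)
  i <- seq_len(n)
  d <- max(i / n - cdf, cdf - (i - 1) / n)
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  p <- min(1, max(p, .Machine$double.xmin))
  make_htest("Kolmogorov-Smirnov normality check (plug-in parameters; p approximate)",
             p.value = p, statistic = c(D = d), data.name = "x")
}
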
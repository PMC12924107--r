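#' @name logistic
#' @title Logistic regression by iteratively reweighted least squares
#'
#' @description
#' Binary logistic regression fitted by Newton/IRLS maximum likelihood,
#' with Wald standard errors from the inverse observed information,
#' odds ratios `exp(beta)` with 95 percent Wald intervals
#' `exp(beta +/- z * SE)`, step-halving to keep the log-likelihood
#' non-decreasing, and quasi-complete-separation diagnostics.  Sparse
#' contingency cells (common in small surgical cohorts) produce exploding
#' Wald intervals; the fit is still returned, flagged, with an optional
#' Firth bias-reduction penalty as a remedial alternative.
NULL

#' Fit a binary logistic regression
#'
#' @param x model formula (with `data`) or numeric predictor matrix
#'   (without intercept column; one is added).
#' @param ... passed between methods.
#' @return An object of class `logistic_fit`; see
#'   [fit_logistic.default()] for fields.
#' @export
fit_logistic <- function(x, ...) UseMethod("fit_logistic")

#' @rdname fit_logistic
#' @param data data.frame in which the formula is evaluated; factors and
#'   character columns expand to reference-coded indicators via
#'   [stats::model.matrix()].
#' @export
fit_logistic.formula <- function(x, data, ...) {
  mf <- model.frame(x, data = data, drop.unused.levels = TRUE)
  y <- model.response(mf)
  mm <- model.matrix(attr(mf, "terms"), mf)
  int <- which(colnames(mm) == "(Intercept)")
  xm <- if (length(int)) mm[, -int, drop = FALSE] else mm
  fit <- fit_logistic.default(xm, y, ...)
  fit$formula <- x
  fit
}

#' @rdname fit_logistic
#' @param y outcome: logical, 0/1 numeric, or two-level factor
#'   (second level = event).
#' @param max_iter maximum IRLS iterations, default 50.
#' @param tol convergence tolerance: converged when the maximum absolute
#'   score (gradient) falls below `tol` or the relative log-likelihood
#'   change does, default 1e-8.
#' @param firth apply Firth's bias-reduction penalty (Jeffreys prior);
#'   default `FALSE`, i.e. plain maximum likelihood.
#' @param level confidence level for the odds-ratio intervals.
#' @return A `logistic_fit`: list with `coefficients`, `se`, `z`,
#'   `p_values`, `odds_ratios` (with `or_lower`, `or_upper`), `table`
#'   (tidy per-term data.frame), `log_likelihood`, `iterations`,
#'   `converged`, `separation`, `loglik_trace`, `vcov`.
#' @export
fit_logistic.default <- function(x, y, max_iter = 50, tol = 1e-8,
                                 firth = FALSE, level = 0.95, ...) {
  xm <- as.matrix(x)
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("factor outcome must have exactly 2 levels")
    y <- as.integer(y) - 1L
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1, logical or 2-level factor)")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  n <- length(y)
  if (nrow(xm) != n) stop("nrow(x) must equal length(y)")
  if (is.null(colnames(xm)))
    colnames(xm) <- paste0("x", seq_len(ncol(xm)))
  if (ncol(xm) > 0) {
    const <- apply(xm, 2, function(col) length(unique(col)) == 1L)
    if (any(const))
      stop("constant predictor column(s): ",
           paste(colnames(xm)[const], collapse = ", "))
  }
  X <- cbind(`(Intercept)` = 1, xm)
  p <- ncol(X)
  if (n <= p) stop("need more observations than parameters")

  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - log1p(exp(eta)))
  }
  beta <- rep(0, p)
  ll <- loglik(beta)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  score <- rep(Inf, p)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    info <- crossprod(X, X * w)
    score <- drop(crossprod(X, y - mu))
    if (firth) {
      # Jeffreys-prior adjusted score: U*_j = U_j + sum_i h_i (1/2 - mu_i) x_ij
      h <- rowSums((X %*% solve(info)) * X) * w
      score_use <- drop(crossprod(X, (y - mu) + h * (0.5 - mu)))
    } else {
      score_use <- score
    }
    delta <- tryCatch(solve(info, score_use),
                      error = function(e) stop("information matrix is singular; ",
                                               "check for collinear predictors",
                                               call. = FALSE))
    objective <- function(b) {
      if (!firth) return(loglik(b))
      e <- drop(X %*% b); m <- plogis(e)
      wi <- pmax(m * (1 - m), 1e-12)
      loglik(b) + 0.5 * determinant(crossprod(X, X * wi))$modulus
    }
    obj_old <- objective(beta)
    step <- 1
    for (h in 0:10) {
      cand <- beta + step * delta
      obj_new <- objective(cand)
      if (is.finite(obj_new) && obj_new >= obj_old - 1e-12) break
      step <- step / 2
    }
    beta_new <- beta + step * delta
    ll_new <- loglik(beta_new)
    trace <- c(trace, ll_new)
    rel_change <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    beta <- beta_new
    ll <- ll_new
    if (max(abs(score)) < tol || rel_change < tol) {
      converged <- TRUE
      break
    }
  }

  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(X, X * w)
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  zval <- beta / se
  pval <- 2 * pnorm(-abs(zval))
  zq <- qnorm(1 - (1 - level) / 2)
  or <- exp(beta)
  or_lo <- exp(beta - zq * se)
  or_hi <- exp(beta + zq * se)
  # quasi-complete separation: fitted probabilities pinned at 0/1, or a
  # diverging coefficient while the gradient has already vanished
  separation <- any(pmin(mu, 1 - mu) < 1e-8) ||
    (max(abs(beta)) > 15 && max(abs(score)) < 1e-3)
  if (separation && !firth)
    warning("possible quasi-complete separation: estimates and Wald ",
            "intervals are unstable (consider firth = TRUE)")
  if (!converged)
    warning("IRLS did not converge in ", max_iter, " iterations")

  tab <- data.frame(term = colnames(X), beta = beta, se = se, z = zval,
                    p = pval, odds_ratio = or, or_lower = or_lo,
                    or_upper = or_hi, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- list(coefficients = setNames(beta, colnames(X)),
              se = setNames(se, colnames(X)), z = zval, p_values = pval,
              odds_ratios = setNames(or, colnames(X)),
              or_ci = cbind(lower = or_lo, upper = or_hi),
              table = tab, log_likelihood = ll, iterations = iter,
              converged = converged, separation = separation,
              loglik_trace = trace, vcov = vcov, level = level,
              firth = firth, n = n)
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic regression (%s), n = %d, logLik = %.3f%s%s\n",
              if (x$firth) "Firth-penalized" else "maximum likelihood",
              x$n, x$log_likelihood,
              if (x$converged) "" else " [NOT converged]",
              if (x$separation) " [separation suspected]" else ""))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, digits = 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Univariate screen: one single-predictor fit per candidate
#'
#' Fits `outcome ~ predictor` separately for each candidate, yielding
#' unadjusted odds ratios; a failure for one predictor (e.g. a constant
#' column) is captured in the summary rather than aborting the screen.
#'
#' @param data data.frame holding outcome and predictors.
#' @param outcome name of the binary outcome column.
#' @param predictors character vector of predictor column names.
#' @param ... passed to [fit_logistic()].
#' @return List with `fits` (named list of `logistic_fit` or `NULL`) and
#'   `summary` (one row per non-intercept term: predictor, term, beta,
#'   se, p, odds_ratio, CI bounds, error message if any).
#' @export
univariate_screen <- function(data, outcome, predictors, ...) {
  if (!outcome %in% names(data)) stop("outcome column '", outcome, "' not found")
  fits <- setNames(vector("list", length(predictors)), predictors)
  rows <- list()
  for (pr in predictors) {
    res <- tryCatch({
      f <- stats::as.formula(paste(outcome, "~", pr))
      fit_logistic(f, data = data, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[pr]] <- data.frame(predictor = pr, term = NA_character_,
                               beta = NA_real_, se = NA_real_, p = NA_real_,
                               odds_ratio = NA_real_, or_lower = NA_real_,
                               or_upper = NA_real_,
                               error = conditionMessage(res),
                               stringsAsFactors = FALSE)
    } else {
      fits[[pr]] <- res
      tab <- res$table[res$table$term != "(Intercept)", , drop = FALSE]
      if (nrow(tab))
        rows[[pr]] <- data.frame(predictor = pr, tab[, c("term", "beta", "se",
                                                         "p", "odds_ratio",
                                                         "or_lower", "or_upper")],
                                 error = NA_character_,
                                 stringsAsFactors = FALSE)
    }
  }
  list(fits = fits,
       summary = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
                 else data.frame())
}
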
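# Single-eVariant aFC estimation from total gene expression.
#
# Model: with t in {0,1,2} alternative alleles and delta = 2^s the allelic
# fold change, expected expression is e(t) = [(2 - t) + t * delta] * e0.
# M1 fits the linear form on the linear scale (additive noise), M2 solves the
# log-scale nonlinear least-squares problem (multiplicative noise), and M3
# approximates M2 in linear time from four candidate estimates.

# Drop missing pairs and validate a genotype/expression pairing.
.paired_input <- function(expr, geno, min_obs = 2L) {
  if (length(expr) != length(geno))
    stop_domain("expression and genotype vectors must have equal length")
  geno <- as.numeric(geno)
  bad <- !is.na(geno) & !(geno %in% c(0, 1, 2))
  if (any(bad))
    stop_domain("genotypes must be 0, 1, 2 or NA (count of alternative alleles)")
  keep <- !is.na(geno) & is.finite(expr)
  expr <- expr[keep]
  geno <- as.integer(geno[keep])
  if (length(expr) < min_obs)
    stop_degenerate(sprintf("fewer than %d usable genotype/expression pairs", min_obs))
  classes <- unique(geno)
  if (length(classes) < 2L)
    stop_degenerate("all individuals fall in a single genotype class; aFC is not identifiable")
  small <- vapply(classes, function(k) sum(geno == k) < 3L, logical(1))
  if (any(small))
    afc_warning("small_class",
                sprintf("genotype class(es) %s have fewer than 3 individuals; estimates may be unstable",
                        paste(sort(classes[small]), collapse = ", ")))
  list(expr = expr, geno = geno)
}

# Per-genotype-class sufficient statistics of log2 expression: size, mean and
# within-class sum of squares, indexed 1:3 for t = 0,1,2 (NA if absent).
.class_stats <- function(z, t) {
  n <- m <- ss <- rep(NA_real_, 3L)
  for (k in 0:2) {
    zk <- z[t == k]
    if (length(zk)) {
      n[k + 1L] <- length(zk)
      m[k + 1L] <- mean(zk)
      ss[k + 1L] <- sum((zk - m[k + 1L])^2)
    }
  }
  list(n = n, m = m, ss = ss)
}

# Residual sum of squares of z_n - log2[(2-t_n) + t_n 2^s] - l0 with the
# intercept l0 (= log2 e0) profiled out at its least-squares optimum.
# Equals (n-1) times the residual variance used for candidate selection.
.profiled_rss <- function(cs, s) {
  delta <- 2^s
  g <- log2(c(2, 1 + delta, 2 * delta))
  p <- !is.na(cs$n)
  l0 <- sum(cs$n[p] * (cs$m[p] - g[p])) / sum(cs$n[p])
  sum(cs$ss[p] + cs$n[p] * (cs$m[p] - g[p] - l0)^2)
}

#' Linear (M1) aFC estimator from linear-scale expression
#'
#' Fits ordinary least squares `y = b0 + b1 * t + e` of linear-scale
#' expression on the count of alternative alleles and converts the
#' coefficients to an allelic fold change, `delta = 2 * b1 / b0 + 1`. This is
#' the maximum-likelihood estimate under additive Gaussian noise and is the
#' fastest of the three eQTL-based estimators.
#'
#' When noise pushes `2 * b1 / b0 + 1` to zero or below (possible for strong
#' negative effects), `delta` is floored at 1/100, mirroring the
#' `+/- log2(100)` cap, so that the estimator remains total.
#'
#' @param expr Per-individual expression on the linear scale (non-negative).
#' @param geno Per-individual count of alternative alleles (0/1/2, `NA`
#'   allowed; missing pairs are dropped).
#' @param conf_level Confidence level for the coefficient intervals of the
#'   underlying linear fit.
#'
#' @return A list with components `estimate` (an [afc_estimate] with method
#'   `"M1"`; its `residual_variance` is on the linear scale) and `fit` (the
#'   raw linear fit: intercept, slope, their confidence intervals, scale tag).
#' @seealso [fit_nonlinear_afc()], [fit_approx_afc()]
#' @export
fit_linear_afc <- function(expr, geno, conf_level = 0.95) {
  y <- .expr_values(expr, "linear")
  if (any(y < 0, na.rm = TRUE))
    stop_domain("linear-scale expression must be non-negative")
  v <- .paired_input(y, geno, min_obs = 3L)
  y <- v$expr; t <- v$geno
  n <- length(y)

  tbar <- mean(t)
  sxx <- sum((t - tbar)^2)
  b1 <- sum((t - tbar) * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * tbar
  r <- y - b0 - b1 * t
  sigma2 <- sum(r^2) / max(n - 2L, 1L)
  se_b1 <- sqrt(sigma2 / sxx)
  se_b0 <- sqrt(sigma2 * (1 / n + tbar^2 / sxx))
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = max(n - 2L, 1L))
  fit <- structure(
    list(intercept = b0, slope = b1,
         intercept_ci = c(b0 - tcrit * se_b0, b0 + tcrit * se_b0),
         slope_ci = c(b1 - tcrit * se_b1, b1 + tcrit * se_b1),
         scale = "linear"),
    class = "afc_linear_fit"
  )

  if (b0 <= 0)
    stop(afc_error("undefined_baseline",
                   "regression intercept is non-positive; reference expression undefined"))
  delta <- 2 * b1 / b0 + 1
  floored <- FALSE
  if (delta <= 1 / 100) {     # floor mirrors the cap's reciprocal
    delta <- 1 / 100
    floored <- TRUE
  }
  cl <- cap_log_afc(log2(delta))
  est <- afc_estimate(cl$value, "M1",
                      residual_variance = stats::var(r),
                      capped = cl$capped || floored, n_used = n)
  list(estimate = est, fit = fit)
}

#' Nonlinear (M2) aFC estimator from log2 expression
#'
#' Solves the log-scale nonlinear least-squares problem
#' `min sum_n (z_n - log2[(2 - t_n) + t_n * 2^s] - log2 e0)^2`
#' over `(log2 e0, s)`, with `s` bounded to `+/- log2(100)`. The intercept
#' `log2 e0` is linear given `s` and is profiled out exactly, leaving a
#' one-dimensional bounded optimization solved by Brent's method on
#' per-genotype-class sufficient statistics.
#'
#' The optimizer is initialized at the M3 estimate (or at `init`), and the
#' returned solution is never worse, in residual variance, than its
#' initialization. An initialization with exactly zero residual variance
#' (noiseless data) is returned as-is.
#'
#' @param expr Per-individual expression on the log2 scale.
#' @param geno Count of alternative alleles (0/1/2, `NA` allowed).
#' @param init Optional starting value for `s` (log2 aFC). Defaults to the
#'   M3 estimate, or 0 when M3 has no valid candidate.
#' @param tol Convergence tolerance on the objective (relative).
#'
#' @return An [afc_estimate] with method `"M2"`; `residual_variance` is the
#'   sample variance of the log2-scale residuals at the optimum.
#' @export
fit_nonlinear_afc <- function(expr, geno, init = NULL, tol = 1e-10) {
  z <- .expr_values(expr, "log2")
  v <- .paired_input(z, geno)
  z <- v$expr; t <- v$geno
  cs <- .class_stats(z, t)

  if (is.null(init)) {
    init <- tryCatch(
      suppressWarnings(fit_approx_afc(z, t)$log2_afc),
      afc_error = function(e) 0
    )
  }
  init <- max(min(init, AFC_CAP), -AFC_CAP)
  f_init <- .profiled_rss(cs, init)

  if (f_init < 1e-20) {        # exact solution (noiseless data)
    s_hat <- init
  } else {
    opt <- stats::optim(init, function(s) .profiled_rss(cs, s),
                        method = "Brent", lower = -AFC_CAP, upper = AFC_CAP,
                        control = list(reltol = tol))
    if (opt$convergence != 0)
      stop(afc_error("convergence",
                     "nonlinear optimization did not converge",
                     best_so_far = opt$par))
    s_hat <- if (f_init < opt$value) init else opt$par
  }

  n <- length(z)
  rv <- if (n > 1) .profiled_rss(cs, s_hat) / (n - 1) else 0
  cl <- cap_log_afc(s_hat)
  afc_estimate(cl$value, "M2",
               residual_variance = rv,
               capped = abs(s_hat) >= AFC_CAP - 1e-12,
               n_used = n)
}

#' Four candidate aFC estimates from per-class summaries
#'
#' Computes the four candidate allelic fold changes used by the linear-time
#' approximation (M3): three from ratios of per-genotype-class geometric mean
#' expression and one from the log-scale regression slope,
#' `delta*1 = m2/m0`, `delta*2 = (2 m1/m2 - 1)^-1`, `delta*3 = 2 m1/m0 - 1`,
#' `delta*4 = 2^(2 c1)`.
#'
#' @param m0,m1,m2 Geometric means of linear-scale expression for the
#'   genotype classes t = 0, 1, 2; `NA` when the class is absent.
#' @param c1 Slope of the OLS regression of log2 expression on genotype;
#'   `NA` when unavailable.
#'
#' @return Numeric vector of length 4 with the candidate `delta` values;
#'   candidates that are undefined (absent class) or non-positive are `NA`.
#' @export
candidate_estimates <- function(m0 = NA, m1 = NA, m2 = NA, c1 = NA) {
  d <- rep(NA_real_, 4L)
  if (!is.na(m0) && !is.na(m2)) d[1] <- m2 / m0
  if (!is.na(m1) && !is.na(m2)) d[2] <- 1 / (2 * m1 / m2 - 1)
  if (!is.na(m0) && !is.na(m1)) d[3] <- 2 * m1 / m0 - 1
  if (!is.na(c1))               d[4] <- 2^(2 * c1)
  d[!is.finite(d) | d <= 0] <- NA_real_
  if (all(is.na(d)))
    stop_degenerate("no valid candidate estimate (fewer than two usable genotype classes?)")
  d
}

#' Residual variance of the log2-scale fit at a given aFC
#'
#' Evaluates the residuals `r_n = z_n - log2[(2 - t_n) + t_n * delta]` and
#' returns their sample variance. The residuals retain the constant
#' `log2 e0`, which does not affect the variance; minimizing this quantity
#' over candidate `delta` values is the selection rule of the M3 estimator.
#'
#' @param expr Log2-scale expression.
#' @param geno Count of alternative alleles (0/1/2, `NA` allowed).
#' @param delta Allelic fold change (> 0) to evaluate.
#'
#' @return Sample variance of the residuals.
#' @export
residual_variance <- function(expr, geno, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta <= 0)
    stop_domain("delta must be a single positive number")
  z <- .expr_values(expr, "log2")
  v <- .paired_input(z, geno)
  r <- v$expr - log2((2 - v$geno) + v$geno * delta)
  stats::var(r)
}

#' Linear-time approximate (M3) aFC estimator from log2 expression
#'
#' Computes the four candidate estimates of [candidate_estimates()] from the
#' per-genotype-class geometric means and the log-linear regression slope,
#' evaluates the residual variance of each valid candidate under the
#' log-scale model, and reports the candidate with the lowest residual
#' variance (ties broken by candidate index, 1 through 4). Candidates that
#' require an absent genotype class are skipped, so the estimator remains
#' usable in cohorts lacking rare homozygotes.
#'
#' @inheritParams fit_nonlinear_afc
#'
#' @return An [afc_estimate] with method `"M3"`. Extra fields: `candidates`
#'   (the four candidate log2 aFC values, `NA` where invalid) and
#'   `selected_candidate` (index 1-4 of the winner).
#' @export
fit_approx_afc <- function(expr, geno) {
  z <- .expr_values(expr, "log2")
  v <- .paired_input(z, geno)
  z <- v$expr; t <- v$geno
  cs <- .class_stats(z, t)

  m <- 2^cs$m                           # geometric means: 2^(mean of log2)
  tbar <- mean(t)
  c1 <- sum((t - tbar) * (z - mean(z))) / sum((t - tbar)^2)
  d <- candidate_estimates(m[1], m[2], m[3], c1)

  valid <- which(!is.na(d))
  n <- length(z)
  rv <- rep(NA_real_, 4L)
  rv[valid] <- vapply(valid, function(i) .profiled_rss(cs, log2(d[i])) / (n - 1),
                      numeric(1))
  sel <- valid[which.min(rv[valid])]    # which.min takes the first minimum
  cl <- cap_log_afc(log2(d[sel]))
  afc_estimate(cl$value, "M3",
               residual_variance = rv[sel],
               capped = cl$capped, n_used = n,
               candidates = log2(d), selected_candidate = sel)
}
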
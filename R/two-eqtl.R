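# Joint aFC estimation for one eGene with two cis-eVariants.
#
# Haplotype expression under regulatory independence multiplies the allelic
# fold changes of the two variants (log effects add); the relaxed model gives
# the double-alternative haplotype its own effect, so that departures from
# independence (epistasis, dosage compensation, LD artifacts) show up as a
# better relaxed fit. Total expression is always the sum of the two
# haplotype expressions, so the observed log2 expression is
#   z_n = log2 e0 + log2(delta_hapA + delta_hapB) + alpha C_n + eps_n.

#' Phased diplotypes at two eVariants
#'
#' @param hap_a,hap_b Integer matrices (or 2-column data frames) with one
#'   row per individual and columns giving the allele (0 reference, 1
#'   alternative) at eVariant 1 and eVariant 2 on that haplotype. Haplotype
#'   order is as produced by phasing.
#'
#' @return An integer matrix of class `phased_diplotypes` with columns
#'   `a1, a2, b1, b2`.
#' @export
phased_diplotypes <- function(hap_a, hap_b) {
  hap_a <- as.matrix(hap_a); hap_b <- as.matrix(hap_b)
  if (ncol(hap_a) != 2L || ncol(hap_b) != 2L || nrow(hap_a) != nrow(hap_b))
    stop_domain("hap_a and hap_b must be 2-column matrices with equal row count")
  d <- cbind(hap_a, hap_b)
  storage.mode(d) <- "integer"
  if (any(is.na(d)) || !all(d %in% c(0L, 1L)))
    stop_domain("diplotype allele codes must be 0 or 1")
  colnames(d) <- c("a1", "a2", "b1", "b2")
  class(d) <- c("phased_diplotypes", class(d))
  d
}

# Haplotype class index: 1 = 00, 2 = 10, 3 = 01, 4 = 11.
.hap_index <- function(h1, h2) 1L + h1 + 2L * h2

.diplo_haps <- function(diplos) {
  d <- unclass(as.matrix(diplos))
  list(ka = .hap_index(d[, 1], d[, 2]), kb = .hap_index(d[, 3], d[, 4]))
}

# Objective machinery: given log2 aFC per haplotype class (s4, with
# s4[1] == 0), the mean structure is l0 + log2(2^s4[ka] + 2^s4[kb]) + alpha C.
# The linear part (l0, alpha) is profiled out exactly. Without covariates the
# data collapse to per-diplotype-class sufficient statistics.
.two_eqtl_problem <- function(z, diplos, C = NULL) {
  if (!is.null(C)) C <- .check_cov(z, seq_along(z), C)
  h <- .diplo_haps(diplos)
  if (length(h$ka) != length(z))
    stop_domain("expression and diplotypes must have equal length")
  n <- length(z)
  if (is.null(C) || nrow(C) == 0L) {
    key <- pmin(h$ka, h$kb) * 10L + pmax(h$ka, h$kb)
    sp <- split(z, key)
    pair <- do.call(rbind, lapply(strsplit(names(sp), ""), function(x)
      as.integer(c(x[1], x[2]))))
    cn <- lengths(sp)
    cm <- vapply(sp, mean, numeric(1))
    css <- vapply(sp, function(x) sum((x - mean(x))^2), numeric(1))
    obj <- function(s4) {
      g <- log2(2^s4[pair[, 1]] + 2^s4[pair[, 2]])
      l0 <- sum(cn * (cm - g)) / n
      sum(css + cn * (cm - g - l0)^2)
    }
    linear_coef <- function(s4) {
      g <- log2(2^s4[h$ka] + 2^s4[h$kb])
      c(`(Intercept)` = mean(z - g))
    }
  } else {
    X <- cbind(`(Intercept)` = 1, t(C))
    qx <- qr(X)
    if (qx$rank < ncol(X))
      stop(afc_error("collinearity", "covariate design matrix is rank deficient"))
    obj <- function(s4) {
      g <- log2(2^s4[h$ka] + 2^s4[h$kb])
      sum(qr.resid(qx, z - g)^2)
    }
    linear_coef <- function(s4) {
      g <- log2(2^s4[h$ka] + 2^s4[h$kb])
      qr.coef(qx, z - g)
    }
  }
  list(n = n, n_cov = if (is.null(C)) 0L else nrow(C), Cmat = C,
       ka = h$ka, kb = h$kb, obj = obj, linear_coef = linear_coef)
}

.finish_two_fit <- function(prob, z, model, s, s4, par_names) {
  coefs <- prob$linear_coef(s4)
  g <- log2(2^s4[prob$ka] + 2^s4[prob$kb])
  if (prob$n_cov > 0) {
    alpha <- coefs[-1]
    r <- z - g - coefs[1] - drop(t(prob$Cmat) %*% alpha)
  } else {
    alpha <- numeric(0)
    r <- z - g - coefs[1]
  }
  names(s) <- par_names
  structure(
    list(model = model, log2_e0 = unname(coefs[1]), s = s, alpha = alpha,
         residuals = r, rss = sum(r^2),
         n_params = prob$n_cov + if (model == "independent") 3L else 4L,
         n = prob$n, converged = TRUE),
    class = "afc_two_eqtl_fit"
  )
}

#' Fit the regulatory-independence model for two eVariants
#'
#' Least-squares fit of
#' `z_n = log2 e0 + log2(delta_v1^i1 delta_v2^i2 + delta_v1^j1 delta_v2^j2) + alpha C_n`
#' over `(log2 e0, s_v1, s_v2, alpha)`, where `(i1, i2)` and `(j1, j2)` are
#' the alleles on the two haplotypes and the reference-allele effect is 1 by
#' definition. Both log2 aFC parameters are bounded to `+/- log2(100)`; the
#' linear parameters are profiled out exactly, and the optimizer is
#' initialized from single-variant M3 estimates.
#'
#' @param z Log2-scale expression vector.
#' @param diplos A [phased_diplotypes] matrix (or any 4-column 0/1 matrix
#'   with columns `a1, a2, b1, b2`).
#' @param C Optional covariate matrix (covariates x samples).
#' @param s_v2_fixed Optionally pin `s_v2` to a known value and optimize only
#'   `s_v1` (used e.g. to reduce to the single-eQTL model when the second
#'   variant has no effect).
#'
#' @return An object of class `afc_two_eqtl_fit` with fields `log2_e0`,
#'   `s` (named `s_v1`, `s_v2`), `alpha`, `residuals`, `rss`, `n_params`.
#' @export
fit_independent_two_eqtl <- function(z, diplos, C = NULL, s_v2_fixed = NULL) {
  z <- .expr_values(z, "log2")
  prob <- .two_eqtl_problem(z, diplos, C)
  d <- unclass(as.matrix(diplos))
  t1 <- d[, 1] + d[, 3]
  t2 <- d[, 2] + d[, 4]
  if (length(unique(t1)) < 2L)
    stop(afc_error("identifiability", "eVariant 1 has a single genotype class; s_v1 not identifiable"))
  if (is.null(s_v2_fixed) && length(unique(t2)) < 2L)
    stop(afc_error("identifiability", "eVariant 2 has a single genotype class; s_v2 not identifiable"))

  init_s <- function(t) tryCatch(
    suppressWarnings(fit_approx_afc(z, t)$log2_afc),
    afc_error = function(e) 0)

  if (is.null(s_v2_fixed)) {
    init <- c(init_s(t1), init_s(t2))
    f <- function(p) prob$obj(c(0, p[1], p[2], p[1] + p[2]))
    opt <- stats::optim(init, f, method = "L-BFGS-B",
                        lower = -AFC_CAP, upper = AFC_CAP,
                        control = list(factr = 1e2, maxit = 500))
    par <- if (f(init) < opt$value) init else opt$par
    s4 <- c(0, par[1], par[2], par[1] + par[2])
    .finish_two_fit(prob, z, "independent", par, s4, c("s_v1", "s_v2"))
  } else {
    f <- function(p) prob$obj(c(0, p, s_v2_fixed, p + s_v2_fixed))
    opt <- stats::optim(init_s(t1), f, method = "Brent",
                        lower = -AFC_CAP, upper = AFC_CAP,
                        control = list(reltol = 1e-12))
    par <- c(opt$par, s_v2_fixed)
    s4 <- c(0, par[1], par[2], par[1] + par[2])
    .finish_two_fit(prob, z, "independent", par, s4, c("s_v1", "s_v2"))
  }
}

#' Fit the relaxed (four-allele) model for two eVariants
#'
#' Treats the joint genotype of the two eVariants as one variant with four
#' alleles (haplotypes 00, 10, 01, 11) and fits
#' `z_n = log2 e0 + log2(delta_{hapA,00} + delta_{hapB,00}) + alpha C_n`
#' over `(log2 e0, s_10, s_01, s_11, alpha)` with `delta_00,00 = 1`. The
#' model nests the independence model (`s_11 = s_10 + s_01`), so its
#' minimized residual sum of squares can never exceed the independence fit's.
#'
#' @inheritParams fit_independent_two_eqtl
#' @param init Optional starting values `c(s_10, s_01, s_11)`; defaults to
#'   the independence solution with `s_11 = s_10 + s_01`.
#'
#' @return An `afc_two_eqtl_fit` with `s` named `s_10`, `s_01`, `s_11`.
#' @export
fit_relaxed_two_eqtl <- function(z, diplos, C = NULL, init = NULL) {
  z <- .expr_values(z, "log2")
  prob <- .two_eqtl_problem(z, diplos, C)
  present <- sort(unique(c(prob$ka, prob$kb)))
  if (length(present) < 4L) {
    missing_h <- c("00", "10", "01", "11")[setdiff(1:4, present)]
    stop(afc_error("identifiability",
                   sprintf("haplotype class(es) %s unobserved; relaxed model not identifiable",
                           paste(missing_h, collapse = ", "))))
  }
  if (is.null(init)) {
    init <- tryCatch({
      fi <- fit_independent_two_eqtl(z, diplos, C)
      c(fi$s[1], fi$s[2], fi$s[1] + fi$s[2])
    }, afc_error = function(e) c(0, 0, 0))
  }
  init <- pmax(pmin(init, AFC_CAP), -AFC_CAP)
  f <- function(p) prob$obj(c(0, p))
  opt <- stats::optim(init, f, method = "L-BFGS-B",
                      lower = -AFC_CAP, upper = AFC_CAP,
                      control = list(factr = 1e2, maxit = 500))
  par <- if (f(init) < opt$value) init else opt$par
  .finish_two_fit(prob, z, "relaxed", par, c(0, par), c("s_10", "s_01", "s_11"))
}

#' @export
print.afc_two_eqtl_fit <- function(x, ...) {
  cat(sprintf("two-eQTL fit (%s model), n = %d\n", x$model, x$n))
  cat(sprintf("  log2 e0 = %.4f\n", x$log2_e0))
  for (nm in names(x$s)) cat(sprintf("  %s = %.4f\n", nm, x$s[[nm]]))
  cat(sprintf("  RSS = %.4g on %d mean parameters\n", x$rss, x$n_params))
  invisible(x)
}

.s4_of_fit <- function(fit) {
  if (fit$model == "independent")
    c(0, fit$s[["s_v1"]], fit$s[["s_v2"]], fit$s[["s_v1"]] + fit$s[["s_v2"]])
  else
    c(0, fit$s[["s_10"]], fit$s[["s_01"]], fit$s[["s_11"]])
}

.as_diplo_matrix <- function(diplo) {
  if (is.null(dim(diplo))) diplo <- matrix(as.integer(diplo), nrow = 1)
  unclass(as.matrix(diplo))
}

#' Predicted log expression ratio between the two haplotypes
#'
#' For a given diplotype, returns the model-predicted log2 ratio of the
#' expression of haplotype A to haplotype B. Under independence the
#' haplotype effects add per variant (`s = s_v1 (i1 - j1) + s_v2 (i2 - j2)`);
#' under the relaxed model it is the difference of the joint haplotype
#' effects. Identical haplotypes always predict 0.
#'
#' @param fit An `afc_two_eqtl_fit`.
#' @param diplo A diplotype: vector `c(i1, i2, j1, j2)` or a 4-column matrix.
#'
#' @return Predicted log2 haplotype expression ratio(s).
#' @export
predict_haplotype_log_ratio <- function(fit, diplo) {
  d <- .as_diplo_matrix(diplo)
  s4 <- .s4_of_fit(fit)
  ka <- .hap_index(d[, 1], d[, 2])
  kb <- .hap_index(d[, 3], d[, 4])
  unname(s4[ka] - s4[kb])
}

#' Predicted total eGene expression for a diplotype
#'
#' Total expression is the sum of the two predicted haplotype expressions,
#' `e0 * (delta_hapA + delta_hapB)`, on the linear scale. The all-reference
#' diplotype predicts `2 e0`.
#'
#' @inheritParams predict_haplotype_log_ratio
#'
#' @return Predicted total expression (linear scale).
#' @export
predict_total_expression <- function(fit, diplo) {
  d <- .as_diplo_matrix(diplo)
  s4 <- .s4_of_fit(fit)
  ka <- .hap_index(d[, 1], d[, 2])
  kb <- .hap_index(d[, 3], d[, 4])
  unname(2^fit$log2_e0 * (2^s4[ka] + 2^s4[kb]))
}

.bic_of <- function(rss, n, n_params) {
  sigma2 <- rss / n                      # ML residual variance
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  -2 * loglik + n_params * log(n)
}

.delta_bic <- function(z, diplos, C) {
  fi <- fit_independent_two_eqtl(z, diplos, C)
  fr <- fit_relaxed_two_eqtl(z, diplos, C,
                             init = c(fi$s[1], fi$s[2], fi$s[1] + fi$s[2]))
  rss_r <- min(fr$rss, fi$rss)           # nesting guard against optimizer noise
  .bic_of(rss_r, fr$n, fr$n_params) - .bic_of(fi$rss, fi$n, fi$n_params)
}

#' Compare the independence and relaxed two-eQTL models by BIC
#'
#' Computes the Gaussian log-likelihood of the residuals of each fit (with
#' the maximum-likelihood residual standard deviation) and the Bayesian
#' information criterion `BIC = -2 log L + lambda log N`, where `lambda`
#' counts the mean-structure parameters (covariate coefficients plus 3 for
#' the independence model, plus 4 for the relaxed model). When
#' `Delta BIC = BIC(relaxed) - BIC(independent)` is negative, a BCa
#' bootstrap over individuals (refitting both models per replicate) yields a
#' confidence interval for Delta BIC; the relaxed model is selected only if
#' the interval's upper bound is below zero. Bootstrap replicates in which a
#' haplotype class disappears are skipped (counted as failures; more than
#' 20% failures raises an unstable-comparison error).
#'
#' @inheritParams fit_independent_two_eqtl
#' @param n_boot Bootstrap replicates for the Delta BIC interval.
#' @param seed Optional seed for the bootstrap.
#' @param level Confidence level of the interval.
#'
#' @return An object of class `afc_model_comparison`: `bic_independent`,
#'   `bic_relaxed`, `delta_bic`, `delta_bic_ci` (or `NULL` when Delta BIC is
#'   non-negative), `selected` (`"independent"` or `"relaxed"`), and the two
#'   fits.
#' @export
compare_models <- function(z, diplos, C = NULL, n_boot = 1000, seed = NULL,
                           level = 0.95) {
  z <- .expr_values(z, "log2")
  fi <- fit_independent_two_eqtl(z, diplos, C)
  fr <- fit_relaxed_two_eqtl(z, diplos, C,
                             init = c(fi$s[1], fi$s[2], fi$s[1] + fi$s[2]))
  bic_i <- .bic_of(fi$rss, fi$n, fi$n_params)
  bic_r <- .bic_of(min(fr$rss, fi$rss), fr$n, fr$n_params)
  delta <- bic_r - bic_i

  ci <- NULL
  selected <- "independent"
  if (delta < 0) {
    d <- .as_diplo_matrix(diplos)
    bs <- bca_interval(
      seq_along(z),
      function(idx) .delta_bic(z[idx], d[idx, , drop = FALSE],
                               if (is.null(C)) NULL else C[, idx, drop = FALSE]),
      n_boot = n_boot, level = level, seed = seed
    )
    ci <- c(bs$ci_low, bs$ci_high)
    if (ci[2] < 0) selected <- "relaxed"
  }
  structure(
    list(bic_independent = bic_i, bic_relaxed = bic_r, delta_bic = delta,
         delta_bic_ci = ci, selected = selected,
         fit_independent = fi, fit_relaxed = fr),
    class = "afc_model_comparison"
  )
}

#' @export
print.afc_model_comparison <- function(x, ...) {
  cat(sprintf("two-eQTL model comparison: Delta BIC = %.3f (relaxed - independent)\n",
              x$delta_bic))
  if (!is.null(x$delta_bic_ci))
    cat(sprintf("  Delta BIC 95%% CI: [%.3f, %.3f]\n",
                x$delta_bic_ci[1], x$delta_bic_ci[2]))
  cat(sprintf("  selected model: %s\n", x$selected))
  invisible(x)
}
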
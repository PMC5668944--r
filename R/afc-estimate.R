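#' Cap on the magnitude of log allelic fold change
#'
#' Estimates of log2 aFC are constrained to a 100-fold expression ratio in
#' either direction, i.e. `|log2 aFC| <= log2(100)` (about 6.64). The cap
#' keeps estimators total in degenerate configurations (e.g. a haplotype with
#' essentially no expression) where the unconstrained estimate diverges.
#'
#' @format A numeric scalar, `log2(100)`.
#' @export
AFC_CAP <- log2(100)

#' Construct an aFC estimate
#'
#' Container for a single log2 allelic fold change estimate, as produced by
#' the eQTL-based estimators ([fit_linear_afc()], [fit_nonlinear_afc()],
#' [fit_approx_afc()]) and the ASE-based estimator
#' ([afc_from_phased_counts()]).
#'
#' @param log2_afc Point estimate of log2 aFC (`NA` for a not-estimable
#'   outcome).
#' @param method One of `"M1"`, `"M2"`, `"M3"`, `"ASE"`.
#' @param residual_variance Sample variance of the fit residuals at the
#'   estimate, or `NA` when the notion does not apply.
#' @param ci_low,ci_high Optional 95% confidence bounds.
#' @param capped `TRUE` if the raw estimate exceeded `AFC_CAP` in magnitude
#'   and was clipped.
#' @param n_used Number of individuals that entered the fit.
#' @param ... Further method-specific fields (e.g. candidate values for M3).
#'
#' @return An object of class `afc_estimate`.
#' @export
afc_estimate <- function(log2_afc, method,
                         residual_variance = NA_real_,
                         ci_low = NA_real_, ci_high = NA_real_,
                         capped = FALSE, n_used = NA_integer_, ...) {
  method <- match.arg(method, c("M1", "M2", "M3", "ASE"))
  if (!is.na(residual_variance) && residual_variance < 0)
    stop_domain("residual_variance must be non-negative")
  structure(
    list(log2_afc = log2_afc, method = method,
         residual_variance = residual_variance,
         ci_low = ci_low, ci_high = ci_high,
         capped = isTRUE(capped), n_used = n_used, ...),
    class = "afc_estimate"
  )
}

#' @export
print.afc_estimate <- function(x, ...) {
  cat(sprintf("log2 aFC estimate (%s): %.4f%s\n", x$method,
              x$log2_afc, if (x$capped) " [capped]" else ""))
  if (!is.na(x$ci_low) || !is.na(x$ci_high))
    cat(sprintf("  95%% CI: [%.4f, %.4f]\n", x$ci_low, x$ci_high))
  if (!is.na(x$residual_variance))
    cat(sprintf("  residual variance: %.4g\n", x$residual_variance))
  if (!is.na(x$n_used))
    cat(sprintf("  individuals used: %d\n", x$n_used))
  invisible(x)
}

#' Clip a log2 aFC value to the +/- log2(100) bound
#'
#' @param s Log2 aFC value; may be infinite (e.g. a median allelic ratio of
#'   zero or infinity), which maps to the corresponding bound.
#'
#' @return A list with elements `value` (the clipped log2 aFC) and `capped`
#'   (`TRUE` iff the input exceeded the bound in magnitude).
#' @examples
#' cap_log_afc(1)    # unchanged
#' cap_log_afc(10)   # clipped to log2(100)
#' @export
cap_log_afc <- function(s) {
  if (length(s) != 1L || !is.numeric(s))
    stop_domain("s must be a single numeric value")
  if (is.na(s))
    stop_domain("s is NaN/NA; cannot cap an undefined log2 aFC")
  if (s > AFC_CAP) return(list(value = AFC_CAP, capped = TRUE))
  if (s < -AFC_CAP) return(list(value = -AFC_CAP, capped = TRUE))
  list(value = s, capped = FALSE)
}

#' Tag an expression vector with its scale
#'
#' Estimators consume expression either on the linear scale
#' ([fit_linear_afc()]) or on the log2 scale ([fit_nonlinear_afc()],
#' [fit_approx_afc()]). Plain numeric vectors are accepted everywhere and
#' assumed to be on the scale the estimator documents; wrapping a vector with
#' `expr_vector()` makes the scale explicit so that passing it to the wrong
#' estimator raises an error instead of silently producing nonsense.
#'
#' @param values Numeric vector of per-individual expression.
#' @param scale `"linear"` or `"log2"`. Linear-scale values must be >= 0.
#'
#' @return The numeric vector with class `afc_expr` and a `scale` attribute.
#' @export
expr_vector <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.numeric(values)) stop_domain("expression values must be numeric")
  if (scale == "linear" && any(values < 0, na.rm = TRUE))
    stop_domain("linear-scale expression must be non-negative")
  structure(as.numeric(values), class = "afc_expr", scale = scale)
}

# Strip the tag, verifying the scale if one is present.
.expr_values <- function(expr, expected_scale) {
  if (inherits(expr, "afc_expr")) {
    got <- attr(expr, "scale")
    if (!identical(got, expected_scale))
      stop_domain(sprintf("expression is tagged '%s' but the estimator requires the %s scale",
                          got, expected_scale))
    return(as.numeric(expr))
  }
  as.numeric(expr)
}
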
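# Two-step covariate correction of log2 expression before eQTL-based aFC
# estimation. Step 1 fits the joint model z = mu + alpha C + beta t + eps and
# discards covariates whose coefficient is not significant; step 2 refits
# with the reduced matrix and removes only the covariate contribution,
# leaving the genotype effect in the data.

.check_cov <- function(z, geno, C) {
  if (!is.matrix(C)) stop_domain("covariates must be a matrix (covariates x samples)")
  if (ncol(C) != length(z) || length(z) != length(geno))
    stop_domain("covariate columns, expression and genotypes must share the sample dimension")
  if (is.null(rownames(C)) && nrow(C) > 0)
    rownames(C) <- paste0("cov", seq_len(nrow(C)))
  C
}

# Joint least-squares fit of z on [1, C', t]; errors on rank deficiency,
# naming the offending columns.
.joint_fit <- function(z, geno, C, conf_level = 0.95) {
  X <- cbind(`(Intercept)` = 1, t(C), genotype = as.numeric(geno))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(afc_error("collinearity",
                   sprintf("design matrix is rank deficient; offending column(s): %s",
                           paste(dropped, collapse = ", "))))
  }
  beta <- qr.coef(qx, z)
  r <- z - drop(X %*% beta)
  df <- length(z) - ncol(X)
  if (df <= 0) stop_degenerate("not enough samples to fit the covariate model")
  sigma2 <- sum(r^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(X)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  list(coef = beta, ci_low = beta - tcrit * se, ci_high = beta + tcrit * se,
       residuals = r)
}

#' Discard covariates without a significant joint effect
#'
#' Fits the joint linear model `z = mu + alpha C + beta t + eps` by least
#' squares and removes every covariate row whose coefficient's confidence
#' interval (standard linear-model t-interval, default 95%) contains zero.
#' Significance is assessed in the single joint regression, not
#' covariate-by-covariate; the intercept and the genotype term are always
#' kept in the model and are never pruned.
#'
#' @param z Log2-scale expression vector.
#' @param geno Count of alternative alleles per sample (0/1/2).
#' @param C Covariate matrix, covariates in rows and samples in columns, in
#'   the same sample order as `z` and `geno`.
#' @param conf_level Confidence level of the pruning interval.
#'
#' @return The reduced covariate matrix (possibly with zero rows).
#' @export
prune_covariates <- function(z, geno, C, conf_level = 0.95) {
  z <- .expr_values(z, "log2")
  C <- .check_cov(z, geno, C)
  if (nrow(C) == 0L) return(C)
  fit <- .joint_fit(z, geno, C, conf_level)
  idx <- seq_len(nrow(C)) + 1L            # covariate coefficients
  keep <- fit$ci_low[idx] > 0 | fit$ci_high[idx] < 0
  C[keep, , drop = FALSE]
}

#' Remove covariate effects from log2 expression
#'
#' Refits the joint model `z = mu + alpha C + beta t + eps` with the reduced
#' covariate matrix and returns `z - alpha C`. The genotype term is part of
#' the fit but is deliberately not removed, so the corrected expression
#' retains the regulatory signal (and the intercept) and stays on the log2
#' scale; applying the correction twice with the same matrix is a no-op.
#'
#' @inheritParams prune_covariates
#' @param C_reduced Covariate matrix as returned by [prune_covariates()]
#'   (or any caller-supplied covariates-by-samples matrix).
#'
#' @return The corrected log2 expression vector.
#' @export
correct_expression <- function(z, geno, C_reduced) {
  z <- .expr_values(z, "log2")
  C_reduced <- .check_cov(z, geno, C_reduced)
  if (nrow(C_reduced) == 0L) return(z)
  fit <- .joint_fit(z, geno, C_reduced)
  alpha <- fit$coef[seq_len(nrow(C_reduced)) + 1L]
  z - drop(t(C_reduced) %*% alpha)
}
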
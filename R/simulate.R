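# Simulation of eQTL, ASE and two-eQTL data sets under the cis-regulatory
# model, and the estimator benchmark built on them.
#
# The default configuration reproduces the benchmark conditions: 10,000
# eQTLs in 200 individuals, reference allele frequency uniform on (0, 1),
# genotypes from two Bernoulli trials (Hardy-Weinberg), basal haplotype
# expression spanning four orders of magnitude (log10 e0 ~ U[0, 4]), log2
# aFC uniform on [-5, 5], and multiplicative log-normal noise with
# log10 eps ~ N(0, 0.17) — about a 40% coefficient of variation within a
# genotype class, matching what is observed in population RNA-seq data.

#' Simulation configuration for single-eQTL data sets
#'
#' @param n_individuals Cohort size.
#' @param n_eqtls Number of eGene/eQTL pairs to simulate.
#' @param log2_afc_range Range of the uniform distribution of the true
#'   log2 aFC.
#' @param log10_e0_range Range of uniform log10 basal haplotype expression.
#' @param f0_range Range of the uniform reference-allele frequency.
#' @param noise_sigma_log10 Standard deviation of the log10-scale
#'   multiplicative noise (0.17 corresponds to ~40% CV).
#' @param seed Integer seed; the same configuration always yields the same
#'   data set.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 200L, n_eqtls = 10000L,
                       log2_afc_range = c(-5, 5), log10_e0_range = c(0, 4),
                       f0_range = c(0, 1), noise_sigma_log10 = 0.17,
                       seed = 1L) {
  stopifnot(n_individuals >= 2, n_eqtls >= 1,
            diff(log2_afc_range) >= 0, diff(log10_e0_range) >= 0,
            f0_range[1] >= 0, f0_range[2] <= 1, diff(f0_range) >= 0,
            noise_sigma_log10 >= 0)
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_eqtls = as.integer(n_eqtls),
         log2_afc_range = log2_afc_range, log10_e0_range = log10_e0_range,
         f0_range = f0_range, noise_sigma_log10 = noise_sigma_log10,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a set of single-eQTL data sets
#'
#' For each eQTL: the reference allele frequency `f0` is drawn uniformly;
#' each individual's genotype is the sum of two Bernoulli(1 - f0) draws;
#' noiseless expression follows `e(t) = [(2 - t) + t * delta] * e0`; and
#' multiplicative log-normal noise is applied (`log10 eps ~ N(0, sigma)`).
#'
#' @param config A [sim_config()].
#'
#' @return A list of class `sim_eqtl_dataset` with elements `genotypes`
#'   (eQTLs x individuals integer matrix), `expression` (linear-scale
#'   matrix of the same shape), `truth` (data frame with `f0`, `e0`,
#'   `s_true` per eQTL) and `config`.
#' @export
simulate_eqtl_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ne <- config$n_eqtls; ni <- config$n_individuals

  f0 <- stats::runif(ne, config$f0_range[1], config$f0_range[2])
  e0 <- 10^stats::runif(ne, config$log10_e0_range[1], config$log10_e0_range[2])
  s_true <- stats::runif(ne, config$log2_afc_range[1], config$log2_afc_range[2])

  geno <- matrix(stats::rbinom(ne * ni, 2L, rep(1 - f0, each = ni)),
                 nrow = ne, ncol = ni, byrow = TRUE)
  # length-ne vectors recycle down columns, i.e. per eQTL row
  noiseless <- ((2 - geno) + geno * 2^s_true) * e0
  eps <- 10^matrix(stats::rnorm(ne * ni, 0, config$noise_sigma_log10), ne, ni)
  expr <- noiseless * eps

  structure(
    list(genotypes = geno, expression = expr,
         truth = data.frame(f0 = f0, e0 = e0, s_true = s_true),
         config = config),
    class = "sim_eqtl_dataset"
  )
}

#' Simulate haplotypic ASE counts for one eVariant
#'
#' Per heterozygous individual, the alternative-haplotype count is
#' `c1 ~ Binomial(depth, delta / (1 + delta))` with `delta = 2^s_true`, and
#' `c0 = depth - c1`.
#'
#' @param s_true True log2 aFC.
#' @param n_individuals Number of heterozygous individuals.
#' @param depth Total haplotypic coverage per individual: a scalar, a vector
#'   of length `n_individuals`, or a function `(n) -> integer vector`.
#' @param seed Optional integer seed.
#'
#' @return A data frame with columns `individual_id`, `c0`, `c1`.
#' @export
simulate_ase_counts <- function(s_true, n_individuals, depth = 100,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dp <- if (is.function(depth)) depth(n_individuals) else
    rep_len(as.integer(depth), n_individuals)
  if (any(dp < 1)) stop_domain("depth must be >= 1")
  delta <- 2^s_true
  p <- delta / (1 + delta)
  c1 <- stats::rbinom(n_individuals, dp, p)
  data.frame(individual_id = paste0("ind", seq_len(n_individuals)),
             c0 = dp - c1, c1 = c1, stringsAsFactors = FALSE)
}

#' Simulate a two-eQTL data set
#'
#' Haplotypes are drawn independently per chromosome copy (alternative
#' allele frequencies `allele_freqs`, no linkage disequilibrium). Haplotype
#' expression is `e0 * 2^s_hap` with `s_00 = 0`, `s_10 = s_v1`,
#' `s_01 = s_v2` and `s_11 = s_v1 + s_v2 + interaction_offset`; an offset of
#' zero reproduces the regulatory-independence model. Total expression is
#' the sum over the two haplotypes, with multiplicative log-normal noise.
#'
#' @param n_individuals Cohort size.
#' @param s_v1,s_v2 True log2 aFC of the two eVariants.
#' @param interaction_offset Departure of `s_11` from additivity (log2
#'   units).
#' @param allele_freqs Alternative-allele frequencies of the two eVariants.
#' @param noise_sigma_log10 Log10-scale noise standard deviation.
#' @param e0 Basal (all-reference) haplotype expression.
#' @param seed Optional integer seed.
#'
#' @return A list with `expression` (linear scale), `diplotypes`
#'   (a [phased_diplotypes] matrix) and `truth`.
#' @export
simulate_two_eqtl_dataset <- function(n_individuals, s_v1, s_v2,
                                      interaction_offset = 0,
                                      allele_freqs = c(0.5, 0.5),
                                      noise_sigma_log10 = 0.17,
                                      e0 = 100, seed = NULL) {
  if (any(allele_freqs <= 0) || any(allele_freqs >= 1))
    stop_domain("allele frequencies must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- n_individuals
  hap_a <- cbind(stats::rbinom(n, 1, allele_freqs[1]),
                 stats::rbinom(n, 1, allele_freqs[2]))
  hap_b <- cbind(stats::rbinom(n, 1, allele_freqs[1]),
                 stats::rbinom(n, 1, allele_freqs[2]))
  diplos <- phased_diplotypes(hap_a, hap_b)
  s4 <- c(0, s_v1, s_v2, s_v1 + s_v2 + interaction_offset)
  ka <- .hap_index(hap_a[, 1], hap_a[, 2])
  kb <- .hap_index(hap_b[, 1], hap_b[, 2])
  mu <- e0 * (2^s4[ka] + 2^s4[kb])
  expr <- mu * 10^stats::rnorm(n, 0, noise_sigma_log10)
  list(expression = expr, diplotypes = diplos,
       truth = list(s_v1 = s_v1, s_v2 = s_v2,
                    interaction_offset = interaction_offset, e0 = e0,
                    noise_sigma_log10 = noise_sigma_log10))
}

#' Root mean squared deviation between estimated and true log2 aFC
#'
#' @param true_s,est_s Paired numeric vectors of equal length.
#'
#' @return `sqrt(mean((est_s - true_s)^2))`.
#' @export
evaluate_rmsd <- function(true_s, est_s) {
  if (length(true_s) != length(est_s))
    stop_domain("true_s and est_s must have equal length")
  sqrt(mean((est_s - true_s)^2))
}

#' Run the three eQTL estimators over a simulated data set
#'
#' Applies M1 (linear), M2 (nonlinear) and M3 (approximate) to every
#' simulated eQTL, caps estimates at `+/- log2(100)`, and evaluates the RMSD
#' of each method against the generating truth. eQTLs with fewer than two
#' genotype classes are excluded (counted in `n_monomorphic`); eQTLs on
#' which an estimator fails (e.g. a non-positive M1 baseline) are excluded
#' from all three methods so the comparison stays paired (counted in
#' `n_failed`).
#'
#' @param dataset A [simulate_eqtl_dataset()] result.
#' @param methods Subset of `c("M1", "M2", "M3")` to run.
#'
#' @return A list of class `afc_benchmark`: `estimates` (data frame with
#'   `s_true` and one column per method), `rmsd` (named vector),
#'   `rmsd_ratio_pct` (percentage excess RMSD of M1 and M3 over M2, when
#'   all three methods are run), `n_used`, `n_monomorphic`, `n_failed`.
#' @export
benchmark_estimators <- function(dataset, methods = c("M1", "M2", "M3")) {
  stopifnot(inherits(dataset, "sim_eqtl_dataset"))
  methods <- match.arg(methods, several.ok = TRUE)
  ne <- nrow(dataset$genotypes)
  est <- matrix(NA_real_, ne, 3L, dimnames = list(NULL, c("M1", "M2", "M3")))
  n_mono <- 0L

  for (i in seq_len(ne)) {
    t <- dataset$genotypes[i, ]
    y <- dataset$expression[i, ]
    if (length(unique(t)) < 2L) {
      n_mono <- n_mono + 1L
      next
    }
    z <- log2(y)
    suppressWarnings({
      m3 <- tryCatch(fit_approx_afc(z, t), afc_error = function(e) NULL)
      if ("M3" %in% methods && !is.null(m3)) est[i, "M3"] <- m3$log2_afc
      if ("M2" %in% methods) {
        init <- if (!is.null(m3)) m3$log2_afc else NULL
        est[i, "M2"] <- tryCatch(fit_nonlinear_afc(z, t, init = init)$log2_afc,
                                 afc_error = function(e) NA_real_)
      }
      if ("M1" %in% methods)
        est[i, "M1"] <- tryCatch(fit_linear_afc(y, t)$estimate$log2_afc,
                                 afc_error = function(e) NA_real_)
    })
  }

  est <- est[, methods, drop = FALSE]
  polymorphic <- rowSums(is.na(dataset$genotypes)) == 0 &
    apply(dataset$genotypes, 1, function(t) length(unique(t)) >= 2L)
  ok <- stats::complete.cases(est) & polymorphic
  n_failed <- sum(polymorphic) - sum(ok)
  s_true <- dataset$truth$s_true

  rmsd <- vapply(methods, function(m) evaluate_rmsd(s_true[ok], est[ok, m]),
                 numeric(1))
  ratios <- NULL
  if (all(c("M1", "M2", "M3") %in% methods)) {
    ratios <- c(M1_vs_M2 = 100 * (rmsd[["M1"]] / rmsd[["M2"]] - 1),
                M3_vs_M2 = 100 * (rmsd[["M3"]] / rmsd[["M2"]] - 1))
  }
  structure(
    list(estimates = data.frame(s_true = s_true, est, row.names = NULL)[ok, ],
         rmsd = rmsd, rmsd_ratio_pct = ratios,
         n_used = sum(ok), n_monomorphic = n_mono, n_failed = n_failed),
    class = "afc_benchmark"
  )
}

#' @export
print.afc_benchmark <- function(x, ...) {
  cat(sprintf("aFC estimator benchmark: %d eQTLs used (%d monomorphic, %d failed fits excluded)\n",
              x$n_used, x$n_monomorphic, x$n_failed))
  for (m in names(x$rmsd)) cat(sprintf("  RMSD %s = %.4f\n", m, x$rmsd[[m]]))
  if (!is.null(x$rmsd_ratio_pct)) {
    cat(sprintf("  RMSD(M1) exceeds RMSD(M2) by %+.1f%%\n", x$rmsd_ratio_pct[["M1_vs_M2"]]))
    cat(sprintf("  RMSD(M3) exceeds RMSD(M2) by %+.1f%%\n", x$rmsd_ratio_pct[["M3_vs_M2"]]))
  }
  invisible(x)
}
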
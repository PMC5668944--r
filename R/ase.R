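# aFC estimation from phased allele-specific expression (ASE).
#
# In individuals heterozygous for an eVariant, reads overlapping heterozygous
# transcribed SNPs (aeSNPs) measure the expression of each haplotype. Phasing
# between each aeSNP and the eVariant assigns every allelic count to the
# haplotype carrying the reference or the alternative eVariant allele; the
# per-individual ratio of those haplotypic counts estimates the allelic fold
# change directly.

#' Aggregate aeSNP-level allelic counts into haplotypic counts
#'
#' Sums allelic read counts over all phased aeSNPs of a gene, per individual:
#' counts whose allele lies on the same haplotype as the alternative
#' eVariant allele accumulate into `c1`, the rest into `c0`.
#'
#' @param records A data frame with columns `individual_id`, `site_id`,
#'   `ref_count`, `alt_count` and `phase_to_evariant` (either
#'   `"cis_with_alt"` — the site's alternative allele shares a haplotype with
#'   the alternative eVariant allele — or `"cis_with_ref"`).
#' @param individuals Optional character vector restricting (and ordering)
#'   the individuals to aggregate; records for unknown individuals are
#'   skipped with a warning.
#'
#' @return A data frame with columns `individual_id`, `c0` (reads on the
#'   reference-allele haplotype) and `c1` (reads on the alternative-allele
#'   haplotype), one row per individual.
#' @export
aggregate_haplotypic_counts <- function(records, individuals = NULL) {
  req <- c("individual_id", "site_id", "ref_count", "alt_count", "phase_to_evariant")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop_domain(paste("records must be a data frame with columns",
                      paste(req, collapse = ", ")))
  if (nrow(records) == 0L) stop_degenerate("no aeSNP records to aggregate")
  phase <- as.character(records$phase_to_evariant)
  if (any(is.na(phase)) || !all(phase %in% c("cis_with_alt", "cis_with_ref")))
    stop(afc_error("missing_phase",
                   "every record needs phase_to_evariant 'cis_with_alt' or 'cis_with_ref'"))
  if (any(records$ref_count < 0) || any(records$alt_count < 0))
    stop_domain("allelic counts must be non-negative")

  if (!is.null(individuals)) {
    unknown <- setdiff(unique(records$individual_id), individuals)
    if (length(unknown)) {
      afc_warning("unknown_individual",
                  sprintf("skipping records for unknown individual(s): %s",
                          paste(unknown, collapse = ", ")))
      records <- records[records$individual_id %in% individuals, , drop = FALSE]
      phase <- as.character(records$phase_to_evariant)
    }
  }

  # counts cis with the alternative eVariant allele
  to_c1 <- ifelse(phase == "cis_with_alt", records$alt_count, records$ref_count)
  to_c0 <- ifelse(phase == "cis_with_alt", records$ref_count, records$alt_count)
  ids <- as.character(records$individual_id)
  lev <- if (is.null(individuals)) unique(ids) else individuals
  f <- factor(ids, levels = lev)
  out <- data.frame(
    individual_id = lev,
    c0 = as.numeric(tapply(to_c0, f, sum, default = 0)),
    c1 = as.numeric(tapply(to_c1, f, sum, default = 0)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

.check_pairs <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("c0", "c1") %in% names(pairs)))
    stop_domain("pairs must be a data frame with columns c0 and c1")
  if (nrow(pairs) == 0L) stop_degenerate("no haplotypic count pairs")
  if (any(pairs$c0 < 0) || any(pairs$c1 < 0))
    stop_domain("haplotypic counts must be non-negative")
  pairs
}

#' aFC from phased haplotypic counts (median allelic ratio)
#'
#' Estimates `delta = median_n(c1_n / c0_n)` over individuals heterozygous
#' for the eVariant and reports the capped `log2` of the median. Pairs with
#' haplotypic coverage `c0 + c1` below `min_coverage` are dropped; if fewer
#' than `min_individuals` pairs survive, the estimate is not attempted and an
#' `afc_estimate` with `log2_afc = NA` is returned.
#'
#' Ratios with `c0 = 0` enter the median as `+Inf`; the median is robust to a
#' minority of such ratios, and an infinite median caps at `+log2(100)`.
#' For an even number of individuals the median is the midpoint of the two
#' central ratios, taken on the ratio scale before the log.
#'
#' @param pairs Data frame with columns `c0` and `c1` (haplotypic read
#'   counts per individual; see [aggregate_haplotypic_counts()]).
#' @param min_coverage Minimum haplotypic coverage `c0 + c1` per individual.
#' @param min_individuals Minimum number of individuals passing coverage.
#' @param n_boot If > 0, number of bootstrap replicates for a BCa confidence
#'   interval over individuals.
#' @param seed Optional seed for the bootstrap.
#'
#' @return An [afc_estimate] with method `"ASE"` (extra field `estimable`).
#' @export
afc_from_phased_counts <- function(pairs, min_coverage = 10, min_individuals = 5,
                                   n_boot = 0, seed = NULL) {
  pairs <- .check_pairs(pairs)
  keep <- (pairs$c0 + pairs$c1) >= max(min_coverage, 1)
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < min_individuals)
    return(afc_estimate(NA_real_, "ASE", n_used = nrow(pairs), estimable = FALSE))

  point_fun <- function(p) {
    delta <- stats::median(p$c1 / p$c0)
    cap_log_afc(log2(delta))
  }
  cl <- point_fun(pairs)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    bs <- bca_interval(pairs, function(p) point_fun(p)$value,
                       n_boot = n_boot, seed = seed)
    ci <- c(bs$ci_low, bs$ci_high)
  }
  afc_estimate(cl$value, "ASE", ci_low = ci[1], ci_high = ci[2],
               capped = cl$capped, n_used = nrow(pairs), estimable = TRUE)
}

#' Magnitude of aFC from unphased allelic counts
#'
#' Without phase information only the magnitude of the regulatory effect can
#' be recovered: the median over individuals of `|log2(c1_n / c0_n)|`
#' (assignment of counts to `c0`/`c1` is arbitrary per individual).
#'
#' Note this magnitude systematically overestimates small true effects: when
#' the allelic counts are dominated by measurement noise, `|log2 ratio|` is
#' positive in every individual even at a true aFC of zero.
#'
#' @inheritParams afc_from_phased_counts
#'
#' @return The median absolute log2 allelic ratio (numeric scalar).
#' @export
afc_magnitude_unphased <- function(pairs) {
  pairs <- .check_pairs(pairs)
  keep <- (pairs$c0 + pairs$c1) > 0
  if (!any(keep)) stop_degenerate("all pairs have zero total coverage")
  stats::median(abs(log2(pairs$c1[keep] / pairs$c0[keep])))
}
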
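# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

# Noiseless expression under the cis-regulatory model, linear scale.
noiseless_expr <- function(t, s, e0 = 1) {
  ((2 - t) + t * 2^s) * e0
}

# One simulated eQTL: genotypes from two Bernoulli draws, multiplicative
# log-normal noise (log10 eps ~ N(0, sigma)).
sim_one_eqtl <- function(n = 200, s = 1, f0 = 0.5, e0 = 100, sigma = 0.17) {
  t <- stats::rbinom(n, 2, 1 - f0)
  y <- noiseless_expr(t, s, e0) * 10^stats::rnorm(n, 0, sigma)
  list(t = t, y = y, z = log2(y), s = s)
}

# Independent grid-search oracle for the nonlinear (M2) estimator: profile
# log2 e0 in closed form and scan s on a regular grid.
grid_oracle_m2 <- function(z, t, s_grid = seq(-log2(100), log2(100), by = 0.01)) {
  rss <- vapply(s_grid, function(s) {
    g <- log2((2 - t) + t * 2^s)
    r <- z - g
    sum((r - mean(r))^2)
  }, numeric(1))
  s_grid[which.min(rss)]
}

# Write a small plain-text VCF for IO tests; gts is a variants x samples
# character matrix of GT strings.
write_test_vcf <- function(path, gts, ids = NULL, alts = NULL) {
  nv <- nrow(gts); ns <- ncol(gts)
  if (is.null(ids)) ids <- paste0("v", seq_len(nv))
  if (is.null(alts)) alts <- rep("G", nv)
  samples <- colnames(gts)
  if (is.null(samples)) samples <- paste0("s", seq_len(ns))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  writeLines(paste("chr1", seq_len(nv) * 100L, ids, "A", alts, ".", "PASS",
                   ".", "GT", apply(gts, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

expect_afc_error <- function(expr, subclass) {
  expect_error(expr, class = paste0("afc_", subclass, "_error"))
}
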
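# Readers and writers for the standard eQTL-pipeline formats:
# VCF genotypes (1-based, read via vcfR), FastQTL-style phenotype BED
# (0-based half-open start), and TSV covariate / pair / ASE-count / result
# tables. Sample alignment is always by ID, never by column position.

#' Read genotypes (and phased haplotypes) from a VCF
#'
#' Extracts per-sample alternative-allele counts from the GT field of a VCF.
#' Phase is preserved when GT uses `|` (the first allele is haplotype A).
#' Missing genotypes (`.`) become `NA`. Multiallelic records are rejected:
#' the biallelic aFC estimators are not defined for them.
#'
#' @param vcf_path Path to a VCF file (plain or bgzipped).
#' @param variant_ids Optional character vector of variant IDs to extract
#'   (an error if any is absent).
#' @param samples Optional character vector restricting/ordering samples.
#'
#' @return A named list (by variant ID) of lists with elements `variant_id`,
#'   `genotype` (named integer vector of alt-allele counts), `phased`
#'   (logical: all non-missing GTs phased), `hap_a`, `hap_b` (named integer
#'   allele vectors, `NA` where unphased or missing).
#' @export
read_genotypes <- function(vcf_path, variant_ids = NULL, samples = NULL) {
  if (!file.exists(vcf_path)) stop_domain(sprintf("VCF not found: %s", vcf_path))
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))                  # single-record VCFs drop to a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"], "_",
                       fix[no_id, "REF"], "_", fix[no_id, "ALT"])
  if (anyDuplicated(ids))
    stop_domain("duplicate variant IDs in VCF")

  if (!is.null(variant_ids)) {
    absent <- setdiff(variant_ids, ids)
    if (length(absent))
      stop(afc_error("variant_not_found",
                     sprintf("variant(s) not in VCF: %s", paste(absent, collapse = ", "))))
    sel <- match(variant_ids, ids)
  } else {
    sel <- seq_along(ids)
  }

  gt <- vcfR::extract.gt(v, element = "GT")
  vcf_samples <- colnames(gt)
  if (!is.null(samples)) {
    absent <- setdiff(samples, vcf_samples)
    if (length(absent))
      stop(afc_error("sample_mismatch",
                     sprintf("sample(s) not in VCF: %s", paste(absent, collapse = ", "))))
  } else {
    samples <- vcf_samples
  }

  out <- lapply(sel, function(i) {
    if (grepl(",", fix[i, "ALT"], fixed = TRUE))
      stop(afc_error("multiallelic",
                     sprintf("variant %s is multiallelic; biallelic aFC estimators require a single ALT allele",
                             ids[i])))
    g <- gt[i, samples]
    g[is.na(g)] <- "."                    # vcfR reads missing GT as NA
    phased_gt <- grepl("|", g, fixed = TRUE)
    parts <- strsplit(g, "[|/]")
    a1 <- vapply(parts, function(p) if (length(p) < 1 || is.na(p[1]) || p[1] == ".")
      NA_integer_ else as.integer(p[1]), integer(1))
    a2 <- vapply(parts, function(p) if (length(p) < 2 || is.na(p[2]) || p[2] == ".")
      NA_integer_ else as.integer(p[2]), integer(1))
    cnt <- a1 + a2
    hap_a <- ifelse(phased_gt, a1, NA_integer_)
    hap_b <- ifelse(phased_gt, a2, NA_integer_)
    names(cnt) <- names(hap_a) <- names(hap_b) <- samples
    list(variant_id = ids[i], genotype = cnt,
         phased = all(phased_gt[!is.na(cnt)]),
         hap_a = hap_a, hap_b = hap_b)
  })
  names(out) <- ids[sel]
  out
}

#' Read a FastQTL-style phenotype BED
#'
#' Expects a header line `#chr start end gene_id` (tab-separated; the gene
#' column may also be named `ID`, `id`, `pid` or `phenotype_id`) followed by
#' one sample column per individual. Starts are 0-based half-open per the
#' BED convention.
#'
#' @param bed_path Path to the phenotype BED file.
#'
#' @return A list with `genes` (data frame: `chr`, `start`, `end`,
#'   `gene_id`) and `expr` (numeric matrix, genes x samples, gene IDs as row
#'   names and sample IDs as column names).
#' @export
read_phenotypes <- function(bed_path) {
  if (!file.exists(bed_path)) stop_domain(sprintf("BED not found: %s", bed_path))
  header <- strsplit(readLines(bed_path, n = 1L), "\t", fixed = TRUE)[[1]]
  header[1] <- sub("^#", "", header[1])
  if (length(header) < 5L ||
      tolower(header[1]) != "chr" || tolower(header[2]) != "start" ||
      tolower(header[3]) != "end" ||
      !(header[4] %in% c("gene_id", "ID", "id", "pid", "phenotype_id")))
    stop_domain("phenotype BED header must be '#chr start end gene_id' plus sample columns")
  tab <- utils::read.delim(bed_path, comment.char = "", skip = 1L,
                           header = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- header
  genes <- data.frame(chr = as.character(tab[[1]]), start = as.integer(tab[[2]]),
                      end = as.integer(tab[[3]]), gene_id = as.character(tab[[4]]),
                      stringsAsFactors = FALSE)
  expr <- as.matrix(tab[, -(1:4), drop = FALSE])
  rownames(expr) <- genes$gene_id
  list(genes = genes, expr = expr)
}

#' Reconcile phenotype and genotype samples by ID
#'
#' @param pheno_samples,geno_samples Character vectors of sample IDs.
#'
#' @return The common samples, in the genotype order.
#' @export
align_samples <- function(pheno_samples, geno_samples) {
  common <- intersect(geno_samples, pheno_samples)
  if (length(common) == 0L) {
    stop(afc_error("sample_mismatch",
                   sprintf("no overlap between phenotype samples (%s...) and genotype samples (%s...)",
                           paste(utils::head(pheno_samples, 3), collapse = ","),
                           paste(utils::head(geno_samples, 3), collapse = ","))))
  }
  common
}

#' Library-size normalization and log2 transform of raw counts
#'
#' Scales each sample's counts by `mean(library sizes) / library size`, adds
#' one pseudocount to smooth the normalized counts, and log2-transforms.
#'
#' @param raw_counts Non-negative matrix, genes x samples.
#' @param library_sizes Optional per-sample library sizes; defaults to the
#'   column sums of `raw_counts`.
#'
#' @return Log2-scale expression matrix of the same shape.
#' @export
normalize_counts <- function(raw_counts, library_sizes = NULL) {
  raw_counts <- as.matrix(raw_counts)
  if (any(raw_counts < 0)) stop_domain("counts must be non-negative")
  if (is.null(library_sizes)) library_sizes <- colSums(raw_counts)
  if (length(library_sizes) != ncol(raw_counts))
    stop_domain("one library size per sample is required")
  if (any(library_sizes <= 0)) stop_domain("library sizes must be positive")
  scaled <- sweep(raw_counts, 2, mean(library_sizes) / library_sizes, `*`)
  log2(scaled + 1)
}

#' Read a covariate TSV (covariates x samples)
#'
#' First column holds covariate names, the header row holds sample IDs.
#'
#' @param path Path to the covariate file.
#' @return Numeric matrix with covariate row names and sample column names.
#' @export
read_covariates <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read an eGene–eVariant pair list
#'
#' A TSV with columns `gene_id` and `variant_id` (plus `variant2_id` for
#' two-eQTL analyses).
#'
#' @param path Path to the pair TSV.
#' @return A data frame.
#' @export
read_eqtl_pairs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "variant_id") %in% names(tab)))
    stop_domain("pair file needs columns gene_id and variant_id")
  if (any(tab$gene_id == "") || any(tab$variant_id == ""))
    stop_domain("gene and variant IDs must be non-empty")
  tab
}

#' Read ASE counts (site-level or pre-aggregated)
#'
#' Two schemas are accepted: site-level records with columns
#' `individual_id, site_id, ref_count, alt_count, phase_to_evariant`
#' (see [aggregate_haplotypic_counts()]) or pre-aggregated haplotypic counts
#' with columns `individual_id, hap_ref_count, hap_alt_count`. Input is
#' assumed to be pre-filtered for site-level ASE quality (minimum reads per
#' SNP, mappability, genotyping error); no such filters are applied here.
#'
#' @param path Path to the TSV.
#' @return A list with `type` (`"sites"` or `"haplotypic"`) and `data`.
#' @export
read_ase_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  site_cols <- c("individual_id", "site_id", "ref_count", "alt_count",
                 "phase_to_evariant")
  agg_cols <- c("individual_id", "hap_ref_count", "hap_alt_count")
  if (all(site_cols %in% names(tab))) {
    list(type = "sites", data = tab)
  } else if (all(agg_cols %in% names(tab))) {
    list(type = "haplotypic",
         data = data.frame(individual_id = tab$individual_id,
                           c0 = tab$hap_ref_count, c1 = tab$hap_alt_count,
                           stringsAsFactors = FALSE))
  } else {
    stop_domain(paste("ASE count file must have columns",
                      paste(site_cols, collapse = ","), "or",
                      paste(agg_cols, collapse = ",")))
  }
}

RESULTS_SCHEMA_HEADER <- "# allelicfc results schema v1"

#' Write (and read back) an aFC results table
#'
#' One row per eGene–eVariant pair: `gene_id`, `variant_id`, `log2_afc`,
#' `ci_low`, `ci_high`, `method`, `n_used`, `capped`, `warnings`. The file
#' starts with a versioned schema comment line.
#'
#' @param results Data frame of result rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(RESULTS_SCHEMA_HEADER, con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a simulated data set as VCF + phenotype BED + truth TSV
#'
#' Serializes a [simulate_eqtl_dataset()] result in the formats the CLI
#' consumes, so the full pipeline can be exercised without external data.
#' Genotypes are written phased (heterozygotes as `0|1`); variants are
#' placed on a synthetic chromosome at 1-based kilobase positions with the
#' matching gene's BED interval (0-based half-open) beside them.
#'
#' @param dataset A `sim_eqtl_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_eqtl_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ne <- nrow(dataset$genotypes)
  samples <- paste0("ind", seq_len(ncol(dataset$genotypes)))
  vid <- paste0("var", seq_len(ne))
  gid <- paste0("gene", seq_len(ne))
  pos <- seq_len(ne) * 1000L

  gt_str <- matrix(c("0|0", "0|1", "1|1")[dataset$genotypes + 1L],
                   nrow = ne)
  vcf_path <- file.path(dir, "genotypes.vcf")
  con <- file(vcf_path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chrS>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  body <- paste("chrS", pos, vid, "A", "G", ".", "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  close(con)

  bed_path <- file.path(dir, "phenotypes.bed")
  con <- file(bed_path, "w")
  writeLines(paste(c("#chr", "start", "end", "gene_id", samples),
                   collapse = "\t"), con)
  # %.17g guarantees exact double round trip through the text file
  expr <- matrix(sprintf("%.17g", dataset$expression),
                 nrow = nrow(dataset$expression))
  writeLines(paste("chrS", pos - 1L, pos, gid,
                   apply(expr, 1, paste, collapse = "\t"), sep = "\t"), con)
  close(con)

  truth_path <- file.path(dir, "truth.tsv")
  truth <- cbind(data.frame(gene_id = gid, variant_id = vid,
                            stringsAsFactors = FALSE), dataset$truth)
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  c(vcf = vcf_path, bed = bed_path, truth = truth_path)
}
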
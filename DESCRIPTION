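Package: allelicfc
Title: Allelic Fold Change Estimation for cis-eQTLs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of log allelic fold change (aFC), the log2 ratio of
    expression between the haplotypes carrying the alternative and the
    reference allele of a cis-regulatory variant. Provides three estimators
    from eQTL data (a closed-form linear estimator, a nonlinear least-squares
    estimator on log-transformed expression, and a linear-time four-candidate
    approximation), estimators from phased allele-specific expression counts,
    two-step covariate correction, bias-corrected and accelerated (BCa)
    bootstrap confidence intervals, a joint two-eQTL model with a test of
    regulatory independence via BIC, a simulator of eQTL, allele-specific
    expression and two-eQTL data sets, and a command-line interface over
    VCF, FastQTL-style phenotype BED and TSV inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    boot,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
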
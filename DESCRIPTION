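Package: hlapredict
Title: HLA Allele Prediction from MHC SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds predictive models for classical HLA alleles from unphased
    SNP genotypes in the extended MHC region. A joint (HLA allele, SNP
    haplotype) frequency model is fitted by expectation-maximization under
    Hardy-Weinberg random pairing; predictor SNPs are chosen by a
    forward-and-backward search over an expanding flanking window, scored by
    the conditional negative log-likelihood of the HLA genotype penalized by
    the number of haplotype parameters. Includes confidence-threshold
    genotype calling, SNP quality-control filters for observed and imputed
    (posterior-probability) genotypes, accuracy and Cohen's kappa concordance
    metrics, and a seedable multi-population synthetic MHC cohort simulator
    for evaluating model transfer across platforms, populations and
    ethnicities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse, yaml
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
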
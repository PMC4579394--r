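Package: hapimpute
Title: Haplotype-Copying Genotype Imputation, Reference Panel Merging and
    Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genotype imputation from phased haplotype reference panels with
    a Li-Stephens haplotype-copying hidden Markov model, including selection
    of the conditioning haplotypes by region-wide Hamming distance or by
    local shared-tract length, reciprocal-imputation merging of two phased
    panels into a union-variant panel with full site-filtering accounting,
    and accuracy-evaluation harnesses (IMPUTE-style info score, true r2
    against masked genotypes, minor-allele-frequency stratification,
    leave-one-out and pseudo-GWAS designs).  A seeded synthetic-panel
    generator provides reference, study and array-like typed-site inputs
    for end-to-end experiments.  Panels are read and written as phased VCF
    or IMPUTE-style hap/legend/sample text files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
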
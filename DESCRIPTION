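Package: mrsexdiff
Title: Sex-Stratified Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale pipeline for sex-stratified two-sample Mendelian
    randomization from GWAS summary statistics: instrument selection by
    p-value, minor-allele-frequency filtering and greedy LD clumping;
    allele harmonization with palindrome and strand-flip handling;
    inverse-variance-weighted, MR-Egger, simple- and weighted-median
    causal estimation; MR-PRESSO global, outlier and distortion tests;
    and a between-sex Cochran's Q test, including back-conversion from
    published odds ratios with confidence intervals. A synthetic
    summary-statistics generator with known ground truth (configurable
    per-sex causal effects, pleiotropy, LD block structure and allele
    corruption) makes every stage testable without consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, metafor, withr
Config/testthat/edition: 3
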
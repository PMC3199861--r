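Package: isopop
Title: Population-Genetic Comparison of Isolate and Outbred Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing a genetic isolate with an outbred reference
    cohort from genome-wide SNP array data: pairwise relatedness estimation
    and greedy unrelated-subset selection, SNP quality control (combined call
    rate, stratified Hardy-Weinberg test, between-platform allele-frequency
    test), exact-confidence-interval rare-SNP classification, Weir-Cockerham
    F-statistics with delete-one-individual jackknife standard errors,
    sliding-window runs-of-homozygosity detection, linkage-disequilibrium
    profiles including the allele-frequency-free measure eta1, and power of
    proxy-SNP association testing with and without cryptic relatedness.
    Includes a synthetic two-cohort generator (Balding-Nichols divergence,
    haplotype-copying LD, pedigreed families, platform artifacts) with
    recorded ground truth, and PLINK bed/bim/fam and VCF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
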
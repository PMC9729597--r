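Package: pedseg
Title: Pedigree-Based Rare-Variant Segregation and Kinship-Adjusted
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of whole-exome sequencing data from multiplex
    families with serious mental illness and unrelated controls.
    Classifies rare predicted-deleterious (RPD) variants from annotated
    VCFs (gnomAD frequencies plus a five-tool deleteriousness consensus),
    prioritizes variants segregating among three or more affected
    relatives within a pedigree (shared-broad and shared-stringent
    tiers), tests gene-set overrepresentation with Fisher's exact test
    and a Bonferroni-corrected specificity scan, and performs a
    kinship- and structure-adjusted sequence kernel association test
    (SKAT) with an EMMAX-style restricted-maximum-likelihood null model,
    Davies characteristic-function p-values and residual-permutation
    p-values. Includes a Mendelian gene-dropping pedigree simulator with
    a liability-threshold phenotype model so the whole pipeline can be
    exercised and calibrated on synthetic cohorts with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
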
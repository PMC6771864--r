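Package: prsdissect
Title: Dissecting APOE and Polygenic Background in Alzheimer Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs LD-clumped polygenic risk scores (PRS) for Alzheimer
    disease from GWAS summary statistics and genotype dosages, with direct
    APOE epsilon2/epsilon4 haplotype terms, principal-component adjustment,
    pathway-partitioned scores, and a nested logistic-model AUC battery that
    separates APOE-driven amyloid deposition from polygenic-background-driven
    conversion from mild cognitive impairment to AD. Includes a two-stage
    liability simulator for synthetic discovery and target cohorts, and a
    resampling correction for discovery-target sample overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
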
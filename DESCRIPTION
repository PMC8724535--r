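Package: prodromalPRS
Title: Polygenic Risk Scores and the Probability of Prodromal Parkinson's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying the relationship between common-variant
    polygenic risk and the prodromal stage of Parkinson's disease in elderly
    population cohorts. Provides genotype quality control (sample missingness,
    heterozygosity outliers, method-of-moments kinship, principal components,
    Hardy-Weinberg and differential-missingness variant filters), clumping-and-
    thresholding polygenic risk score construction from discovery GWAS summary
    statistics, a likelihood-ratio calculator for the MDS research-criteria
    probability of prodromal Parkinson's disease, multi-adjusted linear and
    logistic association models with quartile contrasts and sensitivity
    analyses, and a synthetic-cohort generator so that every stage is testable
    without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
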
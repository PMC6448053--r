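Package: vaherit
Title: Heritability of Value-Added Measures of Educational Progress on Synthetic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates school cohorts with genotyped pupils and key-stage attainment,
    builds raw, contextual (multilevel) and teacher-assessed value-added measures, and
    estimates their SNP heritability by GREML (average-information REML on a genetic
    relatedness matrix) with principal-component control for population stratification.
    Includes genotype quality control, GCTA-dialect GRM and PLINK bed/bim/fam input and
    output, polygenic scoring with allele harmonisation, and a measurement-error
    simulation study quantifying how error in the baseline score inflates the apparent
    heritability of value-added measures, more so for contextual than raw value-added.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
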
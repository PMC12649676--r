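Package: resilio
Title: Resilience Phenotyping and Genetic Analysis from Automated Feeder Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives longitudinal resilience indicators for growing pigs from
    electronic feeder (FIRE-type) visit records and analyses their genetic
    basis. Provides visit-to-day aggregation with outlier masking and
    rolling-average imputation, six deviation-based resilience traits (RMSE of
    daily and cumulative feed intake and feeding duration, and the proportion
    of fasting days below a population 5th-percentile quantile-regression
    line), production traits (ADG, adjusted 100-kg age and backfat, ADFI,
    ADFD, FCR, RFI), pedigree and genomic relationship matrices, AI-REML
    variance components under an animal model with a litter effect,
    bivariate genetic correlations, and a univariate linear mixed-model GWAS
    with kinship eigendecomposition, genomic-control diagnostics and an
    FDR-proportional significance threshold. A synthetic-data generator with
    known ground truth emulates feeder records, pedigree, covariates and
    genotypes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
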
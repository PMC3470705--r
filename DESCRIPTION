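Package: llarrma
Title: Local Automatic Regularization Resample Model Averaging for
    GWAS Hit Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reprioritizes SNPs within a genome-wide association study
    (GWAS) hit region under strong linkage disequilibrium by subsample
    model averaging of L1-penalized logistic regressions with a locally
    (per-subsample) and automatically chosen penalty.  Each SNP receives
    a resample model inclusion probability (RMIP): the fraction of
    case-control subsamples in which the LASSO selects it at a penalty
    calibrated either by response permutation or by out-of-sample
    (complement) deviance.  Includes the benchmark competitors
    (single-locus logistic regression, Stability Selection with oracle
    penalty calibration), hard/dosage/multiple imputation of missing
    genotypes from genotype posteriors, synthetic hit-region data
    generators with LD-block structure and an empirical missingness
    model, and windowed ROC/AUC evaluation with threshold averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
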
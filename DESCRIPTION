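Package: pyroclock
Title: Single-Locus DNA-Methylation Age Prediction from ELOVL2 Pyrosequencing
Version: 0.1.0
Authors@R:
    person("Pyroclock", "Developers", email = "pyroclock@example.org",
           role = c("aut", "cre"))
Description: Development, evaluation and inter-laboratory optimization of
    blood-based single-locus age-prediction models from bisulfite
    pyrosequencing of seven CpG sites in the ELOVL2 promoter. Implements
    cohort pooling and quality control, exhaustive CpG-combination search
    across six model families (a two-CpG multiple linear regression baseline,
    multiple quadratic regression over 14 variables, epsilon-insensitive
    support-vector regression with linear, polynomial and radial kernels,
    gradient-boosted regression trees, and age imputation by regularized
    iterative principal-component reconstruction), MAD/RMSE/Pearson
    evaluation, multi-model averaging, technical-replicate scheme evaluation
    on a 3-PCR x 2-pyrosequencing grid, variance-inflation diagnostics, and a
    synthetic-cohort generator emulating the pooled study design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
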
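Package: liporank
Title: Consensus Ranking and Retention Modeling of Lipophilicity Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing chromatographic and computational
    lipophilicity estimates of small drug-like molecules. Computes
    reversed-phase TLC indices (Soczewinski-Wachtmeister intercepts and
    slopes, C0, mean RM, and the first principal component of the retention
    matrix), extrapolated log kw from two linear-gradient HPLC runs via the
    linear-solvent-strength model, micellar electrokinetic chromatography
    retention factors, and logP from DFT solvation free energies. Ranks a
    panel of lipophilicity measures against a consensus reference by the
    Sum of Ranking Differences (SRD), validates the ranking against a
    permutation null (CRRN) and by sevenfold cross-validation with
    nonparametric pairwise grouping, and decomposes cross-validated SRD
    scores by factorial ANOVA. Builds consensus QSRR retention models by
    genetic-algorithm variable selection coupled with partial least squares,
    with descriptor pre-selection, Kennard-Stone splitting, and CV-ANOVA
    significance testing. Ships the published data tables for a series of 26
    isoxazolo[3,4-b]pyridin-3(1H)-one derivatives, and seeded generators for
    every input type so the full pipeline is testable offline.
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
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
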
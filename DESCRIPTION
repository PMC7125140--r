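Package: oscidesign
Title: Design-Space Screening for Autonomous Oscillations in Power-Law Kinetic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discover autonomous limit-cycle oscillations in biochemical
    networks written in Generalized Mass Action (GMA) form. The package enumerates
    dominance phenotypes (S-systems) of a kinetic model, decides their validity by
    linear-programming feasibility in log-parameter space, samples valid phenotypes
    log-uniformly within their boundaries, screens sampled steady states for
    complex-conjugate eigenvalues with non-negative real part (Hopf-type oscillatory
    potential), and verifies limit cycles by windowed integration of the full model
    with period, amplitude and peak-order measurement. Eleven minimal budding-yeast
    Clb/Cdk1 cell-cycle network designs ship as built-in models, together with
    downstream analyses: dominant-parameter counts, parameter correlations, PCA
    projections, period sensitivity, 1D bifurcation scans, 2D robustness heatmaps and
    phenotype phase planes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    boot,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
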
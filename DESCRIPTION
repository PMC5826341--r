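Package: lingclim
Title: Robustness Analyses for Climatic Adaptation in Language
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether properties of languages (lexical tone,
    vowel use) adapt to ambient climate, with an emphasis on robustness to the
    non-independence of languages (Galton's problem). Implements an
    independence-constrained percentile resampling test for clustered
    cross-linguistic data, measurement-agreement diagnostics (Cohen's weighted
    kappa and a grouped bias test), mixed-effects comparative regressions with
    random-effect ablation and optimizer-stability sweeps, convex-hull
    vowel-space areas from F1/F2 formants, tone-category contingency and
    seasonal corpus statistics, Brownian-motion ancestral state reconstruction
    with phylomorphospace coordinates, and d-separation queries on causal
    graphs. A seeded synthetic-world generator emulates the statistical
    structure of cross-linguistic databases (languages nested in families and
    areas, spatially autocorrelated humidity, areal borrowing) so that every
    analysis can be validated by simulation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    Matrix,
    lme4,
    mgcv,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
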
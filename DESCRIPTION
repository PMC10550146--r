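Package: oscitumor
Title: Oscillatory Unperturbed Tumor Growth Dynamics: Screening, Modeling and Exploration
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize oscillatory (non-monotonic) patterns in
    unperturbed tumor volume profiles from xenograft experiments. Implements an
    empirical oscillation screen (per-animal classical growth-model fits, a
    smoothing-spline reference, half-period extraction from the difference
    signal, a simulated white-noise null with Kolmogorov-Smirnov uniformity
    testing), a semi-mechanistic tumor-angiogenesis-resources ODE model,
    nonlinear mixed-effects estimation by SAEM with importance-sampling
    log-likelihood and AIC, goodness-of-fit diagnostics (weighted residuals,
    lag-plot autocorrelation, visual predictive checks with ethical-limit
    dropout), dynamical systems analysis (equilibria, perturbation ensembles),
    local and global (Sobol/Saltelli, Latin hypercube) sensitivity analysis,
    and a study-shaped synthetic data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
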
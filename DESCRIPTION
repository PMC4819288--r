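Package: virtualstroke
Title: Individualized Whole-Brain Network Modelling of Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates regional BOLD signals from individual structural
    connectomes with a delay-coupled network of Stefanescu-Jirsa 3D
    (reduced Hindmarsh-Rose) neural-mass models, integrated with a
    stochastic Heun scheme and passed through a gamma-kernel hemodynamic
    forward model.  Provides parameter-space exploration over global
    coupling and conduction velocity (global-variance heat maps with
    bifurcation-flanked range selection), amplitude/frequency/phase
    fitting of local and global parameters against target BOLD series,
    group contrasts (Wilcoxon rank-sum with Bonferroni correction,
    Kolmogorov-Smirnov weight-distribution tests) and linear regression
    of model parameters on clinical motor outcomes.  A synthetic-data
    module generates control-like and virtually lesioned connectomes,
    ground-truth BOLD at known parameters, and clinical tables with
    planted effects, so the complete analysis runs without any
    neuroimaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
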
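Package: myoratchet
Title: Single-Molecule Trajectory Inference for Myosin Weak and Strong
    Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference tools for microsecond gold-nanoparticle
    tracking of muscle myosin heads on actin. Generates synthetic
    trajectories, diffraction-limited spot stacks and fluorescent-ATP
    intensity traces with hidden weak-binding states; localizes spots by
    radial symmetry and Gaussian refinement and projects tracks onto their
    major axis; estimates the detached-to-strong-binding step with a fixed-SD
    two-state Gaussian hidden Markov model; detects transient weak-binding
    states with a constrained beam-sampled hierarchical-Dirichlet-process HMM
    (one detached state, unbounded binding states, binding-to-binding
    transitions forbidden); pools repeated inferences into binding-position
    peaks, access ratios and left-truncated exponential dwell times; and fits
    ATP-binding kinetics (spike detection, double-exponential waiting times,
    Cy3 correction, rate-versus-concentration line).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    tiff
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
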
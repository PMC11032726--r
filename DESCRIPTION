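Package: trackfeat
Title: Feature Engineering and Diffusion-Mode Classification for
    Particle Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies arbitrary trajectories (single-particle tracks,
    cell paths, molecular-dynamics output) with seventeen physics-based
    and statistical descriptors: anomalous diffusion exponent from the
    mean squared displacement, gyration-tensor shape measures
    (radius of gyration, asymmetry, anisotropy, projection kurtosis),
    Katz fractal dimension, straightness, efficiency, trappedness,
    gaussianity, velocity statistics, Green-Kubo diffusivity from the
    velocity autocorrelation function, and the dominant Fourier
    frequency.  Simulates the four canonical diffusion modes (normal,
    anomalous via fractional Brownian motion, confined with reflecting
    spherical boundary, and directed) and supports the full
    classification workflow: synthetic labelled training data, feature
    extraction, classifier training with cross-validation, principal
    component projection, and two-sample feature comparison.  Reads
    trajectory tables from CSV and minimal LAMMPS-style YAML dumps; a
    command-line interface exposes the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
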
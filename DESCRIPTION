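Package: pinnelast
Title: Physics-Informed Neural Networks for Inverse Identification of
    Elastic Material Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inverse identification of elastic material parameters from
    reference displacement fields using physics-informed neural networks
    (PINNs). Two parallel feedforward networks map coordinates to
    displacements and stresses; strong-form momentum, constitutive and
    traction residuals are evaluated by exact derivative (Taylor-jet)
    propagation through the networks and co-optimized with bounded
    material parameters by Adam. Ships closed-form pressurized
    thick-walled cylinder and clamped circular plate benchmarks, a
    hexahedral finite-element forward solver (linear elastic and
    Neo-Hookean, quasi-static and transient) for verification of
    recovered parameters, Lee-Sacks and Neo-Hookean constitutive models
    for soft-tissue membranes, surface-mesh input/output, and shape
    agreement metrics (mean symmetric distance, 95th-percentile
    Hausdorff distance, relative L2 error).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
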
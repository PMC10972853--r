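Package: sphmicro
Title: Rotationally Invariant Spherical Convolutional Networks for
    Diffusion MRI Microstructure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates Gaussian compartment-model parameters and fibre
    orientation distribution functions (ODFs) from diffusion MRI signals
    using a rotationally equivariant spherical convolutional neural
    network trained on efficiently simulated data. Provides real
    even-degree spherical-harmonic transforms with least-squares fitting,
    zonal spherical convolution, Wigner-D rotations, HEALPix sampling
    grids, linear and planar b-tensor acquisition schemes, closed-form
    spherical-mean-technique (SMT) signal equations for constrained two-
    and three-compartment models, a frequency-domain signal simulator
    with Rician noise, a multi-layer perceptron baseline, an SMT plus
    constrained spherical deconvolution baseline, and benchmarks for
    test-set accuracy and rotational variance.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
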
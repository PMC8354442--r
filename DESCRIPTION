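Package: toothdisp
Title: Geometric Morphometric Disparity Analysis of Tooth Outlines
Version: 0.1.0
Authors@R:
    person("Repro", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics for 2D tooth outlines
    sampled across geological time bins. Provides TPS landmark file input
    and output, equidistant curve resampling, generalized Procrustes
    superimposition with bending-energy sliding of semilandmarks,
    principal component ordination with backtransform and modal shape
    reconstruction, thin-plate-spline deformation grids and expansion
    heat maps, Procrustes-variance disparity with partial disparity,
    residual-randomization permutation inference, bootstrap and
    rarefaction uncertainty, distributional diagnostics (skewness,
    kurtosis, Hartigan dip, Henze-Zirkler), two-block partial least
    squares, measurement-error analysis, and a parametric generator of
    synthetic tooth assemblages with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
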
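Package: lcstrain
Title: Lamina Cribrosa Strain from Radial OCT by Fast-Iterative Digital
    Volume Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates optic nerve head deformation from pairs of radial
    optical coherence tomography (OCT) scan sets using fast-iterative
    digital volume correlation (FI-DVC). Provides contrast enhancement
    (CLAHE and gamma correction), landmark-driven segmentation of the
    lamina cribrosa analysis region, subset-based windowed
    cross-correlation with subpixel refinement and iterative subset
    halving, displacement-field validity filtering, cylindrical
    Green-Lagrange strain fields with in-plane principal and maximum
    shear strains, anterior lamina depth change relative to the Bruch's
    membrane opening, and per-eye strain compliance (strain per mm Hg of
    intraocular pressure increase). A synthetic-phantom module generates
    radial speckle volumes with analytically known deformations and
    synthetic cohorts so every stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
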
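Package: DewetDynamics
Title: Physical Modeling of Smooth Muscle Cell Cluster Self-Organization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the self-organization of contractile
    (smooth muscle) cell sheets into three-dimensional clusters: hole
    opening in the sheet modeled as viscoelastic fracture with an
    exponential-saturation width law, cluster rounding modeled as active
    dewetting of a viscous droplet, cluster fusion modeled as Frenkel
    viscous sintering, cluster population dynamics with a ramped fusion
    rate, the nematic order parameter of actin stress fibers, mask-based
    morphometry (area, perimeter, ellipse axes, circularity, anisotropy),
    and a minimal multi-pass cross-correlation PIV. A synthetic-data
    generator emits every input modality with known ground truth so the
    whole pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    tiff,
    minpack.lm,
    pracma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Software, TimeCourse
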
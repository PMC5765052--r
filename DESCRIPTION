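Package: skelemorph
Title: 3D Skeletal Morphometry for Micro-CT and MRI Mouse Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative 3D morphometry of the mouse skeleton from
    micro-CT and MRI volumes: curved bone lengths from seed points or
    automatically extracted centerlines, trabecular microarchitecture
    (BV/TV, Tb.Th by maximal inscribed spheres, Tb.N) inside a
    growth-plate-referenced volume of interest, growth-plate volume and
    two-surface thickness mapping, skull and brain volumes, foramen
    magnum rim circumference and elliptical area, spinal kyphosis index
    and vertebral lengths, and the accompanying group statistics (Welch
    t-tests, Holm-Sidak step-down correction, chi-square goodness of
    fit). Includes analytic phantom generators with closed-form ground
    truth for validating every measurement, and a config-driven pipeline
    for batch studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
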
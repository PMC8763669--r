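Package: osteotexture
Title: Dual-Modality Vertebral Texture Analysis on CT and Water-Fat MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantitative and texture analysis of vertebral bodies
    from CT and chemical shift encoding-based water-fat MRI. Implements
    three-dimensional gray-level co-occurrence (GLCM) and run-length (GLRLM)
    texture features over the 13 direction classes of the 26-neighborhood,
    proton density fat fraction (PDFF) map computation, HU-to-vBMD
    calibration, mask-wise aggregation of quantitative maps, and stepwise
    linear regression with forced adjustment covariates for differentiating
    fracture status. Includes a synthetic vertebral cohort generator
    (Gaussian-random-field phantoms with group-structured density and
    heterogeneity) so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
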
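Package: redose
Title: Reirradiation Dose Accumulation and EQD2 Planning Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Vendor-agnostic tools for evaluating reirradiation cases:
    maps prior-course dose grids onto the current planning geometry through
    user-supplied rigid or deformable transforms, converts physical dose to
    equieffective dose in 2 Gy fractions (EQD2) under the linear-quadratic
    model with per-structure alpha/beta ratios and tissue-recovery scaling
    factors, sums courses voxel-wise, evaluates cumulative organ-at-risk
    constraints (Dmax, D0.01cc, Dmean, Dx%, VxGy), performs point-dose
    feasibility analysis, generates nested isodose optimization structures
    with EQD2 and physical dose limits for the new plan, and renders
    cumulative DVH and scorecard reports.  Reads and writes DICOM RT Dose,
    RT Structure Set and RT Plan objects (axis-aligned dialect) as well as
    NIfTI volumes, and includes a deterministic synthetic-case generator so
    every pipeline stage is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
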
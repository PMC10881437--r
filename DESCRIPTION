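Package: dartplan
Title: Dose-Accumulation-Based Automated Re-Irradiation Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated stereotactic re-irradiation planning for paraspinal
    targets. Maps a prior radiotherapy dose distribution onto the current
    anatomy through a displacement vector field with conservative
    maximum-in-neighborhood dose smearing, converts it to equivalent dose
    in 2 Gy fractions (EQD2), derives spatially resolved per-organ
    maximum-dose constraints from cumulative tissue-tolerance budgets,
    optimizes a new fluence-based plan under those hard constraints, and
    evaluates cumulative radiobiological dose and plan quality (DVH
    metrics, Paddick conformity, ICRU homogeneity and gradient indices).
    Includes a deterministic synthetic vertebral-column phantom generator
    so the full workflow runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
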
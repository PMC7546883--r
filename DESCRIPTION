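Package: contourdose
Title: Geometric and Dosimetric Evaluation of Auto-Segmented Radiotherapy Contours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how contour (segmentation) differences propagate
    into radiotherapy plan quality. Generates seeded synthetic phantom cohorts of
    paired manually-segmented (MS) and auto-segmented (AS) structure sets with
    controllable geometric discrepancy, computes the standard geometric agreement
    metrics (Dice similarity coefficient and symmetric Hausdorff distance in
    physical units), synthesizes prescription-conformal dose distributions with a
    closed-form parametric surrogate for inverse planning, extracts cumulative
    dose-volume histograms and clinical dosimetric endpoints (VxGy, Max, Mean)
    against constraint tables, and orchestrates the three-mode plan/contour
    cross-evaluation (PlanAEvalA, PlanMEvalM, PlanAEvalM) with paired t-tests,
    exceedance accounting and a geometric-versus-dosimetric discordance sweep.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
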
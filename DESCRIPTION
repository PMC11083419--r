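Package: lamorph
Title: Quantitative 3D Morphometry of the Levator Ani Muscle in the
    Pelvic Inclination Correction System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative three-dimensional morphometry of the
    levator ani muscle (LAM) from landmark-annotated pelvic MRI points.
    Builds the subject-specific 3D Pelvic Inclination Correction System
    (3D-PICS) coordinate frame from four bony landmarks (inferior pubic
    point, sacrococcygeal articulation, bilateral ischial spines) and
    rigidly transforms annotations between scanner and PICS space;
    computes per-muscle origin-insertion lengths, signed angles to the
    sagittal, transversal and coronal PICS planes, and the pubovisceral
    quarter-point subdivision; summarizes cohorts (coordinate means and
    SDs, length and angle tables, SD-threshold point counts); and
    quantifies inter-rater reliability via ICC(2,k) with 95% confidence
    intervals and Bland-Altman limits of agreement with Wald intervals.
    Includes a synthetic-cohort generator (Gaussian muscle-point
    variation, random rigid pelvic embeddings, two-rater annotation
    noise) so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
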
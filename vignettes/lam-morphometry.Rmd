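---
title: "Quantitative 3D morphometry of the levator ani in the PICS frame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative 3D morphometry of the levator ani in the PICS frame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamorph)
library(dplyr)
```

## The measurement problem

The levator ani muscle (LAM) is the principal supportive muscle of the
female pelvic floor; its subdivisions — pubovisceral (PVM), iliococcygeal
(ICM), coccygeal (COC) and puborectal (PRM) — attach between bony and
soft-tissue landmarks that can be annotated on static pelvic MRI. Raw
scanner coordinates of such annotations are not comparable across subjects
or visits, because pelvic inclination and scanner positioning differ every
time. The 3D Pelvic Inclination Correction System (3D-PICS) solves this by
re-expressing every point in a pelvis-fixed frame built from four bony
landmarks:

* the **inferior pubic point** (IPP) — the frame origin (0/0/0);
* the **sacrococcygeal articulation** (SCJ) — fixes the antero-posterior
  direction;
* the **left and right ischial spines** — fix the lateral axis.

Axis conventions: `x` antero-posterior (+ posterior), `y` cranio-caudal
(+ caudal), `z` lateral (+ right). The PICS xz-plane is the near-horizontal
pelvic plane; in an upright posture it is perpendicular to the body axis and
aligned with the direction of gravity and prolapse.

## Frame construction

The four landmarks name the frame but do not by themselves fix its algebra.
`build_pics_frame()` uses the construction

1. `z_hat = unit(is_right − is_left)`,
2. `x_hat = unit((scj − ipp) − ((scj − ipp)·z_hat) z_hat)` (Gram–Schmidt
   against the lateral axis),
3. `y_hat = z_hat × x_hat`,

with the origin at the IPP. This is the unique orthonormal frame in which
the IPP is at the origin, the xz-plane contains both the IPP and the SCJ
and is parallel to the interspinous axis, and the sign conventions above
hold. We document it as this package's convention: any construction
satisfying those constraints is rigidly equivalent.

Two numerical choices matter here:

* **Degeneracy threshold.** If the SCJ–IPP direction is within 1° of the
  interspinous axis (or either pair nearly coincides, at 10⁻⁶ mm), the
  frame is refused with an error naming the offending landmark pair.
  Real pelvic geometry is nowhere near this limit; the guard exists for
  corrupt input.
* **Handedness.** `y_hat = z_hat × x_hat` points *caudally* only if the
  scanner frame is right-handed (e.g. RAS or LPS). The point-file dialect
  therefore carries a handedness code in its metadata line; it is declared,
  never guessed from data.

Transforms are exact rigid maps: `to_pics()` computes
`p′ = Bᵀ(p − origin)`, `from_pics()` its inverse, and a round trip
reproduces coordinates to well below the 10⁻⁹ mm tolerance asserted in the
tests.

## Morphometry

Each muscle course is a straight origin-to-insertion segment in PICS space.
Its **length** is the Euclidean distance in mm. Its **direction** is
insertion minus origin, and the **angle to each PICS plane** is

$$\theta_P = \arcsin\!\left(\frac{\mathbf{d}\cdot\hat{n}_P}{\lVert\mathbf{d}\rVert}\right),$$

with the plane normals: posterior unit vector for the coronal (yz) plane,
inferior for the transversal (xz) plane, right for the sagittal (xy) plane.
Angles lie in [−90°, 90°]; courses pointing posterior / caudal / right get
positive angles. Because the three normals are orthonormal, every course
satisfies $\sin^2\theta_{sag} + \sin^2\theta_{trans} + \sin^2\theta_{cor} = 1$
— an identity the test-suite checks to 10⁻⁹ on random directions. Note the
identity holds per course, not after averaging angles across courses.

### Pairing points into courses

The annotation roster has 29 points; turning them into courses requires
pairing rules, which the reference publication states only partially. The
defaults, all configurable via `course_pairing()`:

* **COC**: one origin per side, two insertion subpoints; both courses are
  built and reported as their mean.
* **ICM / PRM**: lateral origin subpoint *k* pairs with midline insertion
  subpoint *k* (k↔k). We chose this over cross-pairing because lengths
  reconstructed from the reference mean coordinates then land close to the
  published per-muscle means (e.g. PRM left 57.6 mm vs the published
  58.1 ± 5.7 mm), while cross-pairing diverges.
* **PVM**: its fan-like origin is annotated by a first (cranio-lateral) and
  last (caudo-medial) point. `pvm_quarter_points()` divides the straight
  line between them into four equal parts; the three interior points are
  the course origins for the PVM's three insertion targets. The default
  assignment q1→PAM, q2→PPM, q3→PVaM reproduces the published ordering
  (PAM longest, PVaM shortest). The PAM and PVaM insertions are side-specific;
  the PPM insertion is midline and is reached from both sides' q2 points.
* Degenerate (zero-length) and missing courses are flagged, not fatal;
  cohort summaries are computed cell-wise over what is available.

The published length table carries a "PVM (average)" row identical to its
PPM row; we treat that as a labeling artifact and report the three PVM
components individually.

## Cohort summaries

`summarize_coordinates()` gives per-point, per-axis means and sample SDs
(n−1). `sd_threshold_count()` counts SD cells at or below a threshold —
the homogeneity statistic quoted for annotation precision (on the packaged
reference table: 80/87 cells ≤ 8 mm, 28/87 ≤ 4 mm). The threshold is
inclusive; 4.0 mm occurs in the table, so inclusiveness matters there.
`summarize_morphometry()` reports length mean/SD and angle median with
quartiles; quartiles use linear interpolation between order statistics
(R's default type 7), a choice we document because the reference does not
state one. Display rounding (one decimal in the printed tables) never
feeds back into computation.

## Inter-rater reliability

`icc2k()` implements ICC(2,k) in the Shrout–Fleiss convention: two-way
model, absolute agreement, mean of k = 2 raters,

$$\mathrm{ICC}(2,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n},$$

with 95% confidence bounds from the McGraw–Wong F-based procedure for
absolute-agreement average measures (single-measure bounds with
Satterthwaite degrees of freedom, stepped up by Spearman–Brown). The
"two-way mixed" wording sometimes attached to ICC(2,k) does not change the
point estimate; we follow the ICC(2,k) algebra. Two numerical details:

* when MSE = 0 with rater offset present, the Satterthwaite degrees of
  freedom are taken at their analytic limit (k − 1), where the textbook
  formula is 0/0;
* estimates and bounds are floored at 0 in the reported fields (the usual
  table convention), with unclamped values retained in `$raw`.

`limits_of_agreement()` is Bland–Altman with fixed z = 1.96 Wald
intervals: `sd/√n` for the bias, `sd·√(3/n)` for each limit. We use z
rather than t because the intervals are declared as Wald intervals;
proportional-bias regression and heteroscedasticity checks are out of
scope (they were assumed away at the n = 10 study size this emulates).
`reliability_report()` assembles per-point, per-axis ICCs (87 cells on the
full roster), unweighted per-axis mean/SD of the estimates, and an LoA
table in which mirrored left/right points are pooled by default.

## The synthetic cohort generator

No per-subject annotation data are published, so the generator *is* the
study-conditions stand-in for every downstream test:

* **Coordinates** are drawn independently per point and axis from
  `Normal(mean, sd)` with the packaged reference means/SDs (29 points × 3
  axes). Only marginal moments are published, so independence is an
  explicit stand-in, not the study's truth; an optional `lr_correlation`
  parameter (default 0) couples mirrored left/right points with a z-sign
  flip for sensitivity experiments.
* **Embeddings**: each subject gets one random rigid motion — inclination
  about the lateral axis uniform in ±30°, the other two rotations ±10°,
  translations ±100 mm per axis. These ranges exercise the frame
  correction well beyond clinical positioning variation without creating
  degenerate geometry. The landmark geometry (IPP at the origin, SCJ at
  (110, 0, 0), spines at (10, −5, ∓45) mm) is plausible pelvic plumbing,
  configurable, and not itself an estimand.
* **Raters**: two copies of the cohort with independent per-axis Gaussian
  noise (default SD 2 mm, the order of slice thickness) on muscle points;
  bony landmarks stay exact by default since they are easy to identify.
* **Determinism**: one global seed; per-subject streams are derived
  counter-style, so any subject subset reproduces exactly and identical
  parameters give byte-identical pipelines.

What passing tests on this generator do show: the frame construction
inverts arbitrary rigid embeddings to 10⁻⁹ mm; morphometry is
rigid-invariant; summaries recover generator means at the expected
√n rate; ICC intervals cover a closed-form truth at their nominal rate.
What they cannot show: anything about real annotation error structure
(correlated, heteroscedastic, rater-specific bias), anatomical covariance
between points, or image-related effects — none of which are published at
subject level.

## Problem sizes

The shipped tests and the acceptance script use: 100 subjects for the
round-trip property, 10⁴ random directions for the angle identity, 1000
subjects for mean recovery (≥ 95% of the 87 cells within 3 SE), 500
simulated two-rater studies of n = 200 for interval coverage, and the
35-subject cohort size of the reference study for the end-to-end report.
These sizes put Monte-Carlo error comfortably below the asserted margins.

## A worked example

```{r example}
ref <- lam_coordinate_reference()
subject <- tibble::tibble(
  subject_id = "MEAN", structure = ref$structure, role = ref$role,
  side = ref$side, subpoint = ref$subpoint,
  x_mm = ref$mean_x, y_mm = ref$mean_y, z_mm = ref$mean_z, frame = "pics")
subject_morphometry(subject) |>
  filter(side == "left") |>
  select(structure, length_mm, angle_sagittal_deg, angle_transversal_deg)
```

A subject placed at the reference mean coordinates reproduces the
published length scale (COC ≈ 50.8 mm, PRM ≈ 57.6 mm, PVaM ≈ 19.6 mm) and
angle signs (posterior muscles nearly in-plane, PVM components elevated by
35–40° to the transversal plane). Cohort *medians* of per-subject values
are not identical to morphometry of the mean coordinates, so agreement is
expected at table precision, not exactly.

## Known limitations

* Straight-line courses only: no curvature, thickness, cross-section or
  volume measures.
* No pelvic-size normalization; coordinates are absolute mm.
* The frame algebra matches every property stated for the original
  system, but the original derivation is published elsewhere and could
  differ by an equivalent construction.
* The generator's independence assumptions make it a calibration and
  correctness harness, not a biomechanical model.
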
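---
title: "Methods: vertebral morphometry and acute-fracture screening evaluation"
author: "SpineScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vertebral morphometry and acute-fracture screening evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpineScreen)
```

## The problem

A vertebral compression fracture (VCF) is a collapse of a vertebral body.
Classical screening quantifies it with the height loss ratio (HLR): the
anterior, middle and posterior heights of each body are read on a sagittal
image and

$$\mathrm{HLR} = \left(1 - \frac{\min(h_a, h_m)}{h_p}\right) \times 100\,[\%],$$

followed by Genant semiquantitative grading: normal (HLR < 20%), mild
(20--25%), moderate (25--40%), severe (>= 40%). Mild compression is displayed
like normal and never counts as a VCF.

Acute fractures (roughly the first 6--8 weeks) matter most clinically, and
they are exactly where pure height measurement struggles: their hallmarks on
CT are cortical step-offs, cortical breakage and sharp fissures — horizontal,
contour-level deformations that may come with little vertical height loss.
Conversely, physiological wedging (a normal anterior/posterior height
asymmetry, typical at the lowest lumbar levels) and small vertebral size can
push HLR past a fixed threshold without any fracture. `SpineScreen`
implements this screening analysis end to end so the behavior of
height-based, contour-based and fused detectors can be studied
quantitatively on synthetic spines with known ground truth.

## The spine phantom generator

Clinical CT cohorts with vertebra-level acute/chronic truth are not publicly
distributable, so the package generates parametric sagittal phantoms
(`phantomSpec()`, `buildPhantom()`, `rasterizePhantom()`):

* **Geometry.** 0-based image coordinates, y down, anterior left. Each body
  is an isosceles trapezoid with a flat inferior endplate; level $k$ is
  scaled by `sizeGradient`$^{k-1}$ (default 1.06 per level, lumbar larger
  than thoracic), default base 60 x 36 px with a 6 px inter-body gap. A
  signed per-level `wedgingProfile` sets the anterior/posterior asymmetry;
  negative values make the posterior side lower, the physiological pattern
  of the lowest lumbar levels (the cohort sampler uses -0.08 and -0.04 at
  the two lowest levels).
* **Deformities.** `wedge`, `biconcave` and `crush` subtract an absolute
  `heightLoss` from the anterior, middle, or all three generative heights;
  `step_off` displaces a stretch of the superior endplate downward by
  `offset` pixels; `cortical_break` carves a 2 px wide fissure of depth
  `gapLen` into the superior cortex. The two latter are acute markers.
* **Generative heights are exact by construction.** Heights are anchored at
  10/50/90% of the AP chord. The wedge/biconcave depression profiles are
  piecewise linear with plateaus spanning [0, 0.15], [0.45, 0.55] and
  [0.85, 1] of the chord, so the anchored heights equal base-minus-loss to
  machine precision and a band-averaged raster measurement sees a constant
  depression across each measurement band. The step-off spans chord
  fractions 0.16--0.44 and the fissure sits at 0.68 — both strictly between
  the anchor bands, so acute markers perturb the cortex without changing
  the generative heights. This is a deliberate design choice: it makes the
  generative heights a usable oracle for the measurement code.
* **Class balance.** The cohort sampler draws acute vertebrae at rate
  148/1030 (~14%), matching the evaluated screening cohort (882 normal, 148
  acute vertebrae), plus chronic (non-acute) wedges/biconcavities at rate
  0.08 whose height loss alone can cross the Genant thresholds — the
  substrate for height-based false positives. Acute height losses are drawn
  uniformly from 10--45% of the posterior height, step offsets from 3--6 px,
  fissure depths from 4--8 px; these ranges are the generator's definition
  of "clinically visible" acute morphology, chosen once to straddle the
  Genant boundaries rather than tuned to any detector.

What the phantoms deliberately do **not** model: HU texture (trabecular
density, sclerosis), 3D partial-volume effects, segmentation errors, ribs
and soft tissue. Tests passing on phantoms therefore validate the
*arithmetic and geometry* of the pipeline — measurement recovery, grading,
fusion algebra, interval estimates — not clinical performance on CT.

## Height measurement

`measureHeights()` reads one body from a label mask:

1. **Axis alignment** (`axisMethod = "principal_axis"`, default): the pixel
   set is rotated to its long (anterior--posterior) axis. The orientation is
   estimated as the minimal-area bounding-rectangle direction (rotating
   calipers on the convex hull) rather than a raw pixel PCA: a superior
   endplate deformity tilts the principal axis of the pixel mass and would
   bias the measurement by several HLR percentage points, while the
   minimal-area rectangle locks onto the intact inferior cortex. For
   symmetric bodies the two coincide. `"bounding_box"` skips rotation.
2. **Band reading**: heights are whole-band vertical extents
   (max - min + 1 of pixel-center y) in 5%-wide bands centered at the
   10/50/90% sampling fractions of the AP extent. Whole-band extents are
   used instead of per-column averages because columns of a rotated raster
   are corner-clipped and individually noisy (> 1 px), while the band
   extent recovers rotated rectangles within 1 px.

Bodies with fewer than 20 pixels or an extent under 3 px raise a typed
`unmeasurableVertebra` condition; `measureSpine()` converts it to a warning
and reports the body with `NA` heights, grade `normal` and
`vcf_flag = FALSE`.

Two HLR variants are provided. The default `printed` variant is the formula
above; it can be *negative* when the posterior height is the lowest, as in
physiological lumbar wedging. The commercial screening behavior it mirrors
flags such bodies, which is irreconcilable with the printed formula; the
`min_over_max` variant, $(1 - \min/\max) \times 100$ over all three heights,
treats any asymmetry as loss and is offered for that reading. The package
default stays with the printed formula; HLR is kept at full precision
internally and rounded half-up to 2 decimals only at the I/O layer.

## Preprocessing stages

* `applyWindow()` — linear HU windowing onto [0,1] with clamping; default
  level 300 / width 850 HU (a bone-type display window).
* `extractContour()` — boundary pixels of a label under 8-connectivity
  (4-connectivity would break diagonal cortices); deterministic and
  idempotent on contour-only masks.
* `cropAndStandardize()` — half-open 0-based bounding-box crop, then a
  mean-anchored linear contrast stretch
  ($\mathrm{out} = m + f\,(\mathrm{in} - m)$, clamped to [0,1], default
  $f = 2$), then bicubic resize (Keys kernel, $a = -0.5$) to 224 x 224.
  "Contrast doubling" is not defined by the libraries that popularized it;
  the mean-anchored stretch is the testable interpretation used here, and it
  is applied to the cropped patch (cropping first keeps the anchor mean
  local to the vertebra).

## The contour-irregularity detector

Trained deep-learning detectors are not reproducible at desk scale (no
weights, no cohort), so the package provides two clearly-labeled stand-ins:

1. `irregularityScore()` — deterministic. A reference quadrilateral is
   fitted to the cortical contour (corners initialized at the extreme points
   along the principal-axis diagonals, refined by Nelder--Mead on the mean
   point-to-edge distance). The score combines the maximum residual $r$ and
   a discontinuity count $d$:
   $\mathrm{score} = 1 - \exp\!\big(-(r/r_0 + d/d_0)\big)$ with $r_0 = 2$ px
   and $d_0 = 1$, chosen so that a 3 px step-off scores above 0.6.
   Discontinuities count traversal steps longer than `jumpThreshold`
   (default 2 px) plus inward excursions — contour runs deeper than the
   threshold inside the quadrilateral. The excursion term exists because a
   closed region cannot produce a literal gap in its own boundary chain: a
   break fissure manifests as the two walls of a narrow notch, which is
   precisely an inward excursion. The traversal starts at the
   topmost-leftmost pixel and proceeds by nearest-unvisited-neighbor with
   clockwise tie-breaking, making the count deterministic.
2. `emulateDetector()` — stochastic. Reproduces a detector *arithmetically*
   by its operating point: truly acute vertebrae are called positive with
   probability `sens`, normal ones with `1 - spec`, independently under a
   fixed seed. The confidence score is derived from the underlying uniform
   draw (score = 1 - u). It emulates one fixed operating point per class —
   not a single global score threshold — which is all the fused-evaluation
   arithmetic requires.

Two properties define the deterministic scorer and are enforced by tests:
*step-off separation* (with no boundary jitter, every step-off body with
offset >= 3 px scores strictly above every undeformed body, so a perfectly
separating threshold exists) and *crush blindness* (uniform height loss with
a clean cortex scores ~0 — the same blindness that defeats HLR screening and
motivates fusing the two signals).

## Fusion and evaluation

`fuseCalls()` implements the two complementary uses of a second detector:

* `complement_negative` (HLR(-) + detector): height-negative vertebrae are
  re-examined; fused positive = primary OR secondary.
* `confirm_positive` (HLR(+) + detector): height-positive vertebrae need
  confirmation; fused positive = primary AND secondary.

These semantics are forced by arithmetic, not assumption: for any call sets,
$TP_{OR} + TP_{AND} = TP_A + TP_B$ and $FP_{OR} + FP_{AND} = FP_A + FP_B$
(inclusion--exclusion), and the published fused confusion matrices satisfy
these identities exactly against the standalone ones. The test suite
verifies both the published counts and the identity on 1000 random cohorts.

`detectionMetric()` computes sensitivity, specificity, accuracy and
precision in percent with 95% confidence intervals. The interval family is
the **Wilson score interval** (`wilsonCI()`): it reproduces the published
intervals — e.g. 102/148 gives 61.06--75.82% and 875/882 gives
98.37--99.62% — to two decimals, which a Wald interval does not; this
identification was verified against `stats::prop.test(correct = FALSE)`
before implementation and is re-checked in the tests. The accuracy CI is
Wilson on $(tp+tn)/n$. Metrics with a zero denominator raise an error from
`detectionMetric()` and are reported as `NA` by `metricTable()`.

`rocCurve()` sweeps all distinct score thresholds (ties grouped), includes
the (0,0) and (1,1) endpoints, and integrates by the trapezoid rule;
`rocFromConfusion()` represents a threshold-free binary detector as its
single operating point joined to the endpoints. How a full ROC should be
assigned to a *fused binary* method is not well defined; the package
supports sweeping either component's scores but does not designate either
as canonical. Published AUROC values of the trained models are out of
scope for the same reason the models are.

## Numerical choices and degenerate inputs

* Rasterization is by strict pixel-center-in-polygon membership (no
  anti-aliasing); areas agree with the analytic polygon area within 2% for
  default-size bodies, and overlapping polygons are an error.
* Boundary jitter (`noiseSigma`) is Gaussian on polygon vertices, seeded;
  the default is 0 so geometric tests are exact.
* All randomness (jitter, cohort sampling, detector emulation) flows from
  integer seeds; `runExperiment()` derives every stage's seed from the one
  config seed and logs it, so identical configs give byte-identical tables.
* Half-open, 0-based bounding boxes throughout; grade boundaries are
  half-open intervals with 20/25/40 belonging to the upper band.
* Rounding: half-up to 2 decimals, applied only when writing tables.

## Problem sizes

The shipped tests run single bodies up to ~90 x 60 px (supersampled x4
for the scale-crossover check), cohorts of 5--8 spines for the experiment
runner, $10^5$ vertebrae for emulator calibration, and 1000 random cohorts
for the fusion identities; these sizes give stable statistics while keeping
the whole suite under a minute of compute. The same code paths accept
arbitrarily larger cohorts via `runExperiment()`.

## Known limitations

* Phantoms are 2D polygons; no HU texture, no segmentation noise unless
  `noiseSigma` is set, no anatomical level naming (T11/L2).
* The contour scorer is a geometric stand-in: it shares the *premise* of
  contour-based detection (acute = cortical irregularity), not the learned
  behavior of any trained model.
* The fissure realization is an open notch; a displaced-fragment
  realization would need multiple polygons per level and is not modeled.
* `min_over_max` HLR is provided but unvalidated against any reference
  measurements; it exists to make the physiological-wedging false-positive
  mechanism expressible.
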
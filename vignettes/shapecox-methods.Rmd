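---
title: "Tumor shape features and survival prognosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor shape features and survival prognosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapecox)
```

## The problem

Whole-slide H&E images of lung adenocarcinoma record tumor morphology at
high resolution, but outlining tumor regions by hand is slow and
subjective. The pipeline implemented here automates the path from slide to
prognosis:

1. the slide is cut into non-overlapping square patches;
2. each patch is classified into *tumor*, *non-malignant* or *white*
   (empty glass), giving a per-patch class-probability heatmap in which
   one heatmap cell corresponds to one patch;
3. tumor regions are segmented from the argmax label map at heatmap-cell
   resolution, and 22 shape and boundary descriptors are computed per
   tissue sample, then averaged per patient;
4. a univariate Cox screen followed by an elastic-net penalized Cox model
   turns the features into a risk score, which is validated on an
   independent cohort by median dichotomization, Kaplan–Meier curves, a
   log-rank test, and a multivariate Cox model adjusting for age, sex,
   smoking and stage.

Because real cohorts of this kind (hundreds of gigapixel slides plus
survival follow-up) are not shippable, the package includes a synthetic
cohort generator whose ground truth is exact at the heatmap-cell level.
Every stage is therefore testable against known answers, and the whole
pipeline runs on a laptop.

## Patch classification

The deep network used on real slides is deliberately represented by a
*contract*, not a fixed implementation: `predict_proba()` must return one
row of non-negative probabilities per patch, summing to 1, deterministic
and batch-order independent. All downstream computation touches only the
probability map, so any backend honoring the contract can be substituted.

The default backend, `fit_reference_classifier()`, is a multinomial
logistic model (with a small ridge penalty for stability on separable
classes) on five patch summary statistics: mean intensity, the three
channel means, and the fraction of dark pixels (intensity < 0.5 after the
[0, 1] rescaling by 1/255), a proxy for nuclear blob density. On the
synthetic textures these statistics separate the classes nearly
perfectly; the reference backend is a stand-in for the full network's
*role*, and no claim is made about deep-network accuracies on real
tissue. Patches flagged non-tissue by the Otsu mask are folded into the
white class with probability row (0, 0, 1), since white is the
empty-region category and only tissue patches are predicted. Argmax ties
are broken by the fixed priority tumor > non-malignant > white, so a
pathological 50/50 cell errs toward sensitivity.

Tissue masking uses Otsu's threshold over the 256 integer candidates on
the channel-mean grayscale; tissue is the *dark* side of the split (H&E
tissue is darker than glass), followed by a binary closing then opening
with a disk of radius 1 pixel (configurable). Patch windows are half-open,
trailing remainder pixels are dropped, and a cell is tissue when more than
a configurable fraction (default 0, i.e. any) of its pixels are tissue.
The white-patch rule uses a strict mean-intensity inequality with a
default threshold of 200/255; on real slides this constant is calibrated
from sample images, so it is exposed as a parameter.

Dataset splitting is stratified per class with the rounding convention
round-half-up for the training count, floor for the test count, remainder
to validation. This convention conserves class totals exactly; with class
counts 2139/2475/730 and fractions 0.72/0.08/0.20 it yields totals
3848/428/1068, which the acceptance suite checks.

## Region segmentation and the 22 features

All geometry is computed on the heatmap grid (1 cell = one patch), using
8-connectivity for both tumor regions and holes. Dual-8 connectivity
admits the classical checkerboard paradox — a pocket enclosed only
diagonally leaks to the outside and is not a hole — which the test suite
documents rather than hides, because the alternative (4-connected holes)
would change hole counts relative to the stated method.

Tissue samples are 8-connected components of non-white cells after a
radius-1 closing (bridging 1-cell classification gaps); samples with area
strictly smaller than half of the largest are discarded; areas are
measured after the closing. Within a tissue sample the largest tumor
component is the *main tumor region* (ties: earlier first cell in
row-major order).

Per tissue sample, the 22-feature vector comprises the region count; sums
over all tumor regions of area, crack perimeter, convex area, filled
area, hole count, and major/minor axis lengths; the ratio
(Σ perimeter)²/(Σ area); and, for the main region, area, convex area,
eccentricity, hole count, extent, filled area, major/minor axis,
orientation angle, perimeter, solidity, mean predicted tumor probability,
and perimeter²/area. Conventions:

* **Perimeter** is crack length: the number of unit cell edges adjacent
  to exactly one region cell. It is exactly computable, rotation-
  consistent, and gives the discrete isoperimetric bound P²/A ≥ 16 with
  equality precisely for filled squares. Since every feature is used
  relatively (within one model), any consistent perimeter convention is
  valid; chain-code-weighted alternatives would scale all perimeters
  without changing the science.
* **Convex area** counts cell centers inside or on the convex hull of
  the 4 corner points of every region cell.
* **The moment ellipse** uses central second moments of cell centers;
  axis lengths are 4·√eigenvalue, eccentricity √(1 − (minor/major)²)
  (defined 0 for a single cell), and orientation is the major-axis angle
  to the column axis in (−π/2, π/2], ties toward 0.
* **Holes** are 8-connected background components inside the padded
  bounding box not connected to the frame; filled area = area + total
  hole area, an identity tested exactly against a flood-fill oracle.

Feature vectors are averaged *unweighted* across all tissue samples of
all of a patient's slides. Reporting scales (per 1000 cells for sizes,
per 100 for hole counts, per 100 for main-region axes, per 0.10 for the
mean tumor probability, per 1000 for P²/A; shape indices and the angle
unscaled) are applied only at the Cox layer, so hazard ratios are
reported per interpretable unit; the angle's reporting unit is not
standardized anywhere, so it is exported unscaled.

## Survival modelling

`cox_fit()` wraps `survival::coxph` (Newton–Raphson, Efron ties by
default), with Wald CIs computed as exp(β ± 1.96·SE). The univariate
screen fits each rescaled feature alone and selects at two-sided
p ≤ 0.05 — inclusive, so borderline features stay in. The penalized model
is elastic-net Cox via `glmnet` (cyclic coordinate descent with warm
starts, Breslow ties, internal standardization, coefficients returned on
the analysis scale). The mixing parameter defaults to 0.5 — a genuinely
open choice, since pure lasso discards correlated size features
arbitrarily while pure ridge never produces a sparse, reportable model —
and is configurable. The λ path holds 100 log-spaced values from
λ_max down to 0.01·λ_max (0.05·λ_max when n < p). λ* minimizes the mean
held-out partial-likelihood deviance over 10 seeded folds stratified by
event status, so every fold retains events whenever the event count
allows.

Risk scores are linear predictors; each cohort is dichotomized at its
*own* median (scores strictly above go high), matching how validation
cohorts are grouped in practice and avoiding any training-cohort
leakage into the validation grouping. Degenerate cases (all scores
equal) assign everyone to the low group with a warning rather than
splitting arbitrarily. The multivariate model codes sex against female,
smoking against never, and stage II/III/IV against stage I, dropping
empty levels with a warning.

When the screen selects fewer than two features the model falls back to
an unpenalized Cox fit (coordinate-descent software requires at least
two columns, and penalization of a single pre-screened covariate serves
no purpose); when it selects none, fitting stops with an error rather
than silently producing a null model.

## The synthetic cohort generator

The generator defines the study conditions; it is *not* tuned per test.
A tumor body is a star-convex region with boundary radius
r(θ) = R·(1 + Σₖ aₖ cos(kθ + φₖ)), k = 2 … n_harmonics + 1, rasterized on
the cell grid with the column axis stretched by the aspect factor.
Harmonic amplitudes scale linearly with the roughness parameter, so the
crack-perimeter²/area of generated masks increases with roughness in
expectation — the property that makes boundary roughness a usable
prognostic signal. Holes are 1-cell pockets punched strictly in the
interior (full 8-neighborhood inside the body, pairwise Chebyshev
spacing ≥ 2 so they stay disconnected); removing such a cell can never
disconnect the body, because its 8-neighbor ring is itself connected.
Satellites — the analog of tumor spread through air spaces, which
typically occupies a single patch — are 1-cell specks at Chebyshev
distance 2–4 from the body: disjoint from it under 8-connectivity, yet
close enough that the non-malignant rim (Chebyshev dilation by 2)
connects them into the same tissue sample. Samples are laid out on a
white canvas with a 3-cell gap so tissue regions stay disconnected even
after the radius-1 closing.

Rendering maps each cell to a patch-sized texture: white cells draw from
a near-saturated background (mean intensity ≈ 247, above any sensible
white threshold by construction); tumor cells dense dark-purple blobs
(blue > red); non-malignant cells sparse pink blobs (red > blue). The
default render size is 32 px per cell for desk-scale speed; 300 px
mirrors full-scale slides and remains configurable. The generator
emulates the *statistical* structure the pipeline relies on —
multi-sample slides on white glass, three separable patch classes,
controllable boundary roughness, holes, satellites — and deliberately
not nucleus-level histology; passing tests therefore demonstrate the
correctness of the measurement and modelling machinery, not
deep-network performance on real stains.

Survival times follow T = −ln(U)/(h₀·exp(x'β)). Censoring is
exponential; its rate is solved numerically (mean of c/(c + hᵢ) equals
the target censored fraction) because no closed-form inversion exists
under covariate heterogeneity. Cohort-level effect sizes are specified
per standard deviation of the Table-scaled driver features (default
β = 0.8 per SD on main-region P²/A and 0.5 per SD on total tumor area,
with h₀ = 10⁻³/day and 35 % censoring — a strong but realistic
prognostic signal with a median survival around two years). Clinical
covariates are drawn independently of the hazard (age ≈ N(65, 8²), stage
probabilities 0.60/0.20/0.13/0.07), so they act as adjustment noise.
Default shape ranges are radius 6–14 cells, aspect 1–2, roughness
0–0.6, Poisson(1.5) holes and Poisson(1) satellites (capped at 4 and 3).

## Problem sizes and numerical choices

The test suite and the acceptance script use: 200 random masks for the
geometry oracles; 20 seeds at n = 500 for coefficient recovery; 20 × 22
null features at n = 150 for the screen's type-I error; 20 seeds of
train n = 150 / validation n = 389 for end-to-end discrimination
(mirroring the cohort sizes the design targets); and 20 seeds at
n = 400 with a true risk-group hazard ratio of 2.25 for the multivariate
recovery bracket. Penalized/unpenalized equivalence is asserted at
λ = 0 within 10⁻⁴ per coefficient (glmnet run with threshold 10⁻¹² and a
path extended to 0); brute-force partial-likelihood maximization agrees
with the Newton fits within 10⁻⁴; Otsu equals an exhaustive
between-class-variance scan exactly, with the smallest maximizer taken
on plateaus.

Degenerate inputs are defined, not crashed on: constant images yield an
empty tissue mask with a warning; a patch grid larger than the image is
empty with a warning; tissue samples without tumor regions are skipped
with a warning and contribute nothing to the patient average; patients
with no usable tissue are excluded with a warning; single-cell regions
have axis lengths 0, eccentricity 0 and orientation 0 by convention.

## A worked example

```{r example, eval = FALSE}
train <- simulate_cohort(cohort_spec(n_patients = 150, seed = 1))
valid <- simulate_cohort(cohort_spec(n_patients = 389, seed = 2))
fit <- shapecox(train$features, train$clinical$time_days,
                train$clinical$event, seed = 1)
print(fit)
val <- validate_risk_groups(fit, valid$features,
                            valid$clinical$time_days,
                            valid$clinical$event, valid$clinical)
val$logrank
plot(fit, type = "km")
```

The full image-level path (render → mask → tile → classify → heatmap →
regions → features → model) is orchestrated by `run_pipeline()`, which
writes clinical tables, feature matrices, the univariate screen, the
serialized model, risk scores and Kaplan–Meier data as plain text with a
JSON manifest; `report_run()` adds a Markdown summary with the
validation KM plot and an example heatmap rendering. The package's
functions and this vignette are the pipeline's interface; all stages
are plain R calls, so partial reruns are ordinary function calls on
saved artifacts.

## Known limitations

* The reference classifier sees summary statistics, not texture; it is
  adequate for the synthetic classes and for exercising the contract,
  but is not a histology model.
* Geometry is measured at heatmap-cell resolution; sub-patch boundary
  detail and 3-D structure are out of scope by design.
* The dual-8 connectivity convention, the crack-perimeter definition and
  the tie-break rules are choices a different implementation might make
  differently; they are documented and pinned by tests so that results
  are reproducible rather than universal.
* Ground-truth label maps make the mean-tumor-probability feature
  constant (1 on tumor cells), so it drops out of the screen in
  feature-level simulations; it varies, and participates, in the
  image-level pipeline.
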
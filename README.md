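# shapecox

Tumor shape and boundary features from pathology-style images, turned into
a validated survival risk model.

## The problem

Lung adenocarcinoma is morphologically heterogeneous, and features of the
tumor *shape* — overall size, boundary roughness, holes, satellite tumor
specks — carry prognostic information that is tedious and subjective to
quantify by eye. This package implements an automated path from RGB slide
images to prognosis, for researchers who want a fully testable,
desk-scale version of that pipeline:

1. **Tiling & masking** — Otsu tissue masking, non-overlapping square
   patch grids, the mean-intensity white-patch rule, stratified dataset
   splits and flip augmentation.
2. **Patch classification** — a 3-class (tumor / non-malignant / white)
   probability contract with a dependency-light multinomial reference
   classifier; predictions assemble into class-probability heatmaps where
   1 heatmap cell = 1 patch.
3. **Region morphology** — 8-connected tissue samples and tumor regions
   from the argmax label map, half-of-largest tissue filtering, main
   tumor region and hole detection.
4. **Shape features** — 22 descriptors per tissue sample (region count;
   sums of area, crack perimeter, convex area, filled area, holes, axis
   lengths; P²/A; plus the main-region block with eccentricity, extent,
   solidity, orientation and mean tumor probability), averaged to patient
   level.
5. **Survival modelling** — univariate Cox screening (p ≤ 0.05), an
   elastic-net penalized Cox model with 10-fold cross-validated penalty,
   median-cutoff risk groups, Kaplan–Meier / log-rank validation and
   multivariate adjustment for age, sex, smoking and stage.

At the core is the proportional-hazards risk model
h(t | x) = h₀(t)·exp(xᵀβ), with β estimated under the elastic-net penalty
λ·(α‖β‖₁ + (1−α)/2·‖β‖₂²) on the univariately screened, unit-scaled
shape features; patients are dichotomized at the median risk score
xᵀβ̂ of their own cohort.

A synthetic cohort generator (`simulate_cohort()`) produces slides, label
maps and survival outcomes with exact ground truth — tumor masks with
controllable boundary roughness (radial harmonic perturbations), interior
holes, 1-cell satellite specks, and survival times driven by the true
shape features — so every stage is tested against known answers without
any clinical data.

## A worked example

```r
library(shapecox)

train <- simulate_cohort(cohort_spec(n_patients = 150, seed = 1))
valid <- simulate_cohort(cohort_spec(n_patients = 389, seed = 2))

fit <- shapecox(train$features, train$clinical$time_days,
                train$clinical$event, seed = 1)
print(fit)
#> Tumor-shape prognostic Cox model
#>   training cohort: n = 150 , events = 95
#>   screen: 17/22 features selected at p <= 0.05
#>   elastic net: alpha_mix = 0.5, lambda* = 0.02848 (10-fold CV)
#>   nonzero coefficients (per reporting unit):
#>          area_sum   convex_area_sum   filled_area_sum       n_holes_sum
#>            0.2578            0.1929            0.2360           -4.0650
#>      pa_ratio_all         area_main  convex_area_main eccentricity_main
#>           68.4500            0.2669            0.2007            0.2564
#>      n_holes_main  filled_area_main     solidity_main     pa_ratio_main
#>           -4.0730            0.2450           -2.2160          135.0000

val <- validate_risk_groups(fit, valid$features,
                            valid$clinical$time_days,
                            valid$clinical$event, valid$clinical)
val$logrank
#> chi2 = 72.93, df = 1, p = 1.35e-17
print(val$multivariate)
#> Cox proportional hazards fit (n = 389, events = 272)
#>             term      beta       se     hr  ci_lo ci_hi         p
#>      high_vs_low  1.079000 0.129700 2.9430 2.2820 3.794 8.808e-17
#>              age -0.007984 0.007858 0.9920 0.9769 1.007 3.096e-01
#>   male_vs_female -0.126300 0.125000 0.8813 0.6899 1.126 3.122e-01
#>  smoker_vs_never -0.180200 0.124700 0.8351 0.6540 1.066 1.483e-01
#>         stage_II  0.380700 0.152000 1.4630 1.0860 1.971 1.228e-02
#>        stage_III  0.025690 0.196400 1.0260 0.6982 1.508 8.959e-01
#>         stage_IV  0.182800 0.245100 1.2010 0.7426 1.941 4.558e-01
```

Reading the output: the screen keeps the size- and roughness-related
features (coefficients are per reporting unit, e.g. per 1000 heatmap
cells of tumor area, per 1000 units of P²/A); the penalized model keeps
a sparse subset; on the independent validation cohort the high-risk
group has significantly worse survival (log-rank), and the risk group
remains prognostic with hazard ratio ≈ 2.9 after adjusting for age, sex,
smoking and stage — in this simulated cohort the clinical covariates are
noise by construction, and their hazard ratios sit near 1 accordingly.

The full image-level path (render slides → tissue mask → tile → classify
→ heatmap → segment → features → model) is run by:

```r
out <- run_pipeline(pipeline_config(n_train = 30, n_valid = 50, seed = 1),
                    out_dir = "artifacts")
report_run(out, "artifacts")
```

which writes clinical tables, feature matrices, the univariate screen,
the serialized model (JSON), risk scores, Kaplan–Meier data, an example
probability heatmap (plain-text matrices + JSON sidecar), a manifest,
and a Markdown report with the validation KM plot.

## Documentation

The methods vignette (`vignettes/shapecox-methods.Rmd`) describes the
models, the conventions (crack perimeter, dual-8 connectivity, tie
breaks, rounding), the synthetic generator's design and its limits, and
the numerical choices, in detail.
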
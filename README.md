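# scarmap

Per-pixel Bayesian probability maps of scarred myocardium in
late-gadolinium-enhanced cardiac MR (LGE-CMR) short-axis slices.

After myocardial infarction, the infarct core is fully necrotic while the
peri-infarct *gray zone* interweaves dead and viable fibers — tissue that is
arrhythmogenic but invisible to a crisp scar/no-scar segmentation.  Instead
of a binary mask, `scarmap` assigns every myocardial pixel the posterior

P(scar | v) = P(scar) p(v|scar) / [ P(scar) p(v|scar) + P(myo) p(v|myo) ],

with class-conditional Gaussian densities fitted by maximum likelihood on
labeled training pixels and the prior estimated as the pooled scar-to-
myocardium pixel ratio.  The feature v is either

* **DC** — the local 3×3 mean intensity (tracks what the cardiologist sees;
  maps have sharp 0/1 transitions), or
* **texture** — the residual-ratio R_p = R_m / (R_s + R_m), where R_s and
  R_m are ORMP sparse-coding residuals of each 3×3 patch against a scar and
  a healthy dictionary (9×90 atoms, sparsity 2) learned with RLS-DLA
  (recursive least squares with a forgetting factor ramping from 0.995
  toward 1), Gaussian-smoothed (9×9, σ = 5) before the ratio.  Texture maps
  have broad transitions that expose intermediate, gray-zone-like tissue.

Downstream, probability-interval ("LU") cardiac segments are enumerated on a
0.025 grid (703 candidates with U − L ≥ 0.1), per-patient relative segment
sizes are compared between patient groups with a Mann-Whitney test, and maps
are scored pixel-wise against reference masks with per-patient ROC curves
and a vertically averaged curve with a 95% band.  A synthetic textured
cardiac phantom generator (annular myocardium, angular scar sector,
blended gray-zone band, known ground truth) makes the whole pipeline
testable without patient data.

## Worked example

```r
library(scarmap)

# two annotated training slices and one held-out test slice
train <- lapply(1:2, function(i) generate_phantom(phantom_spec(seed = 100 + i)))
test  <- generate_phantom(phantom_spec(seed = 1))

fit <- scar_model(train, feature = "texture")
print(fit)
#> Myocardial scar probability-mapping model
#>   feature: texture (patch 3x3)
#>   dictionaries: 9 x 90 atoms, sparsity 2, lambda0 0.995, 40 epochs
#>   trained on 2 slice(s); prior P(scar) = 0.3333

map <- predict(fit, test)[[1]]                    # posterior per myocardial pixel
seg <- minimum_error_segmentation(map)            # P(scar|v) > 0.5

core_ann <- region_annotation(test$annotation$myocardium, test$truth_core)
map_roc(map, core_ann, exclude = test$truth_border)
#> ROC: AUC = 0.9999  (332 positive, 808 negative)
dice_coefficient(seg, test$truth_core)
#> [1] 0.9005848
```

The AUC scores the map against the phantom's ground-truth scar core
(the blended gray-zone band is excluded — its binary label would be
arbitrary), and the Dice coefficient compares the minimum-error
segmentation with the core.  `render_map(map, test$image)` produces the
blue-to-dark-red rendering (dark red = probability 1, blue = 0,
non-myocardium in light pink).

For a cohort study, `generate_cohort()` + `run_pipeline()` wire training,
mapping, LU-segment testing and ROC evaluation end to end with a
patient-level train/test split and a JSON manifest of every parameter and
seed.

## Documentation

The methods vignette (`vignettes/probability-mapping.Rmd`) documents the
model and its assumptions, the dictionary-learning design choices, what the
phantom emulates and what passing tests do and do not show about real CMR
data, and all numerical conventions.
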
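---
title: "Probability mapping of scarred myocardium: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability mapping of scarred myocardium: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarmap)
```

## The problem

After a myocardial infarction, the heart wall is not simply "scar" or
"healthy".  The infarct core is fully necrotic and electrically inert, but at
its edges lies a *gray zone* (peri-infarct border) where dead and viable
muscle fibers are interwoven — tissue that disturbs electrical propagation
and is a recognized arrhythmogenic substrate.  Late-gadolinium-enhanced
cardiac MR (LGE-CMR) makes scar hyperintense, and clinical practice segments
it with crisp manual contours; but a binary scar/no-scar delineation throws
away exactly the intermediate tissue states that matter for risk assessment.

`scarmap` replaces the crisp decision with a per-pixel posterior probability.
Every myocardial pixel receives

$$P(\mathrm{scar}\mid v) \;=\;
\frac{P(\mathrm{scar})\,p(v\mid \mathrm{scar})}
     {P(\mathrm{scar})\,p(v\mid\mathrm{scar}) +
      P(\mathrm{myo})\,p(v\mid\mathrm{myo})},$$

where $v$ is a scalar feature computed from the pixel's neighborhood.  High
and low probabilities indicate scar and healthy tissue; *intermediate* values
flag tissue where the two are mixed — the gray zone.

## The model and its estimation

The class-conditional densities $p(v\mid\cdot)$ are univariate Gaussians
fitted by maximum likelihood on labeled training pixels (mean = sample mean,
sd with divisor $n$, not $n-1$).  The prior $P(\mathrm{scar})$ is the pooled
ratio of scar to myocardium pixels over the training slices — the mean
relative scar size.  The posterior is evaluated in the log domain (it is the
logistic of the log-odds), so feature values deep in both tails stay finite.
The minimum-error segmentation classifies a pixel as scar when
$P(\mathrm{scar}\mid v) > 1/2$, with ties going to healthy.

A single Gaussian per class is deliberately simple: it is the
lowest-complexity parametric family consistent with ML estimation, it is
monotone-calibrated for the DC feature (equal sds give a logistic posterior,
monotone in $v$), and it behaves sensibly for the texture feature once the
values are clipped away from the exact endpoints of $[0,1]$ by $10^{-9}$
before fitting.  The residual-ratio feature is bounded, so a logit-normal
family would also be defensible; we keep the Gaussian as the default for
comparability between the two features.

Two features are implemented.

### The DC (local mean) feature

`dc_image()` assigns each pixel the arithmetic mean of its $N \times N$
neighborhood ($N = 3$ by default); "DC" is the electronics name for the
mean.  Because LGE makes scar bright, this feature tracks what the
cardiologist sees, and its probability maps have a *narrow* transition: the
posterior is almost always near 0 or 1.  DC training values are standardized
to zero mean and unit variance (scaler fitted on the pooled values of both
classes — pooling preserves the class separation that per-class scaling
would destroy; the ML convention, divisor $n$, is used for the scaler sd as
well) and the scaler is stored in the model for test-time reuse.

### The dictionary-based texture feature

Texture is modeled through sparse representation.  A dictionary $D$ is an
$N^2 \times K$ matrix of unit-norm atoms with $K > N^2$ (default
$9 \times 90$); a vectorized patch $x$ is approximated as $x \approx Dw$
with at most $s$ nonzero coefficients.  Coding uses order recursive matching
pursuit (ORMP): at each step the atom whose component orthogonal to the
already-selected span carries the largest residual projection is added, and
the coefficients are re-solved by least squares on the support, so the final
residual is orthogonal to the selected span.  Ties break to the lowest atom
index for determinism; atoms numerically dependent on the selected span are
skipped.

One dictionary is learned per tissue class with the recursive least squares
dictionary learning algorithm (RLS-DLA).  With forgetting factor
$\lambda_t$, each training vector $x_t$ with code $w_t$ updates

$$u = (\lambda_t^{-1} C_{t-1})\,w_t,\quad
\alpha = \frac{1}{1 + w_t^\top u},\quad
r_t = x_t - D_{t-1} w_t,$$
$$C_t = \lambda_t^{-1} C_{t-1} - \alpha u u^\top,\qquad
D_t = D_{t-1} + \alpha\, r_t u^\top .$$

With $\lambda \equiv 1$ this recursion maintains the exact least-squares
normal equations for the codes used, *including* the identity-initialized
$C_0$, which acts as a set of virtual prior observations (signals $D_0$ with
identity codes): $D_T (I + WW^\top) = D_0 + XW^\top$.  The test suite
asserts this identity to relative $10^{-6}$.

Design choices that the recursion itself does not fix:

* **Forgetting-factor ramp.**  $\lambda_t = 1 - (1-\lambda_0)e^{-t/\tau}$
  with $\lambda_0 = 0.995$ and $\tau = (\text{epochs}\cdot L)/5$: the ramp
  discounts the random initialization early and converges to plain least
  squares.  The exponential form is standard for this learner; the time
  constant is configurable.
* **Epochs.**  40 passes by default; the learner is online, and on the
  phantom training sets the dictionaries are stable well before that.
* **Normalization.**  Atoms are renormalized and $C$ reset at epoch
  boundaries only, keeping the rank-one updates exact within a pass.
* **Initialization.**  $K$ distinct training vectors drawn with the given
  seed (normalized); $C_0 = I$, the standard recursive-least-squares start.
  Training is bit-reproducible given (training set, seed).

**Training-vector purity.**  Training vectors are collected only from pixels
whose *entire* $N \times N$ neighborhood lies inside one class region
(`collect_training_vectors()`); windows that straddle the scar/healthy
boundary, the myocardial border or the image edge contribute nothing, so the
dictionaries never learn mixed textures.  The same rule is applied to both
classes.  Patches are vectorized in fixed row-major order; the order itself
is arbitrary, but its consistency between training and testing is asserted
by tests.

**The feature.**  For a test image, every full-window pixel is coded against
both dictionaries, giving residual images $R_s$ and $R_m$.  Texture is not a
pixel-local property, so both residual images are smoothed with a separable
$a \times a$ Gaussian ($a = 9$, $\sigma = 5$ by default, replicate edges,
kernel normalized to sum 1) *before* forming the ratio

$$R_p = \frac{R_m}{R_s + R_m} \in [0, 1],$$

with the non-informative value $1/2$ when both residuals are exactly zero.
$R_p$ near 1 means the scar dictionary explains the local texture much
better.  Smoothing is applied at test time only by default
(`smooth_training = FALSE`): training features are raw ratios, read at
labeled myocardium pixels.  Both modes exist because the alternative reading
(smoothing training residuals too) is defensible; the default keeps training
features maximally local to their labels.  Residuals are computed over the
whole valid image field rather than only the myocardium, so the Gaussian
needs no mask-boundary renormalization; a mask of `NA`s is re-imposed after
smoothing.

**With or without the patch mean.**  Dictionaries can be trained on raw
patches (default) or mean-subtracted ones (`remove_dc = TRUE`).  With the
mean retained, the bright homogeneous scar dominates the atoms and the
scar dictionary's atoms are smooth; the *atom derivative statistic*
(`atom_derivative_statistic()` — mean absolute first difference of the
atoms reshaped to patches, pooled over rows and columns) quantifies this:
it is near zero for intensity-dominated dictionaries and rises when only
texture is left.  The package asserts the direction of this contrast, not
any particular value.

## Contours and masks

Manual segmentations arrive either as label masks or as ordered control
points marked on the image.  Control points are interpolated with a
*periodic* cubic spline (uniform parameterization — the chord-length
alternative is not used; the choice matters little for roughly equispaced
clinical landmarks) and rasterized with the even-odd rule on pixel centers,
which is deterministic and orientation-independent; the myocardium is the
region inside the outer contour minus the region inside the inner one.
Coordinates are 1-based `(row, col)` with pixel centers at integer
positions; `read_contours(offset = 1)` converts files written 0-based.
`validate_annotation()` enforces scar-inside-myocardium nesting, clipping up
to 1% stray scar pixels (rasterization slack) with a warning and refusing
larger violations.

## The synthetic phantom and what it does (not) show

No public LGE-CMR dataset with cardiologist contours accompanies this
method, so every claim the package tests is exercised on synthetic phantoms
(`generate_phantom()`): a 64×64 slice with an annular myocardium (radii
10/22 px) containing a 120° scar sector, defaults chosen to match a
short-axis left ventricle cropped to the field of view at typical CMR
resolution, with scar occupying a third of the myocardium as in a
substantial infarct.  The two tissues differ in

* mean intensity (0.35 vs 0.65, about 15 noise standard deviations apart,
  emulating strong late-gadolinium enhancement),
* spatial texture: separable sinusoidal gratings with class-specific period
  (4 px healthy, 7 px scar) and a 45° orientation offset, amplitude 0.12 —
  a genuine "tiled floor" texture, so patch dictionaries can represent each
  class sparsely and discriminate between them,
* a gray-zone band (default 3 px of arc length) at the scar's angular edges
  where intensity offset and texture are blended *linearly*, producing true
  intermediate tissue with known ground truth (`truth_border` vs
  `truth_core`).

i.i.d. Gaussian noise (sd 0.02) is added everywhere, and identical spec +
seed gives bit-identical slices.  `generate_cohort()` derives per-slice
seeds deterministically from a master seed to build two-group cohorts.

What passing tests on these phantoms demonstrate: the estimators, the
coding/learning algebra, the feature pipelines, the segment statistics and
the evaluation machinery are correct, and the *directional* claims (texture
maps have broader transitions than DC maps; gray-zone width separates
cohorts in intermediate-probability segments) follow from the model when its
assumptions hold.  What they do not demonstrate: performance on real CMR,
where texture is not stationary or periodic, enhancement varies with
acquisition, contours carry observer variability, and slices are correlated
in 3-D.  The published performance figures for this method were obtained on
a private hospital dataset and are not reproducible here; no number computed
on phantoms should be read as a clinical claim.

## LU cardiac segments

A candidate cardiac segment is the set of myocardial pixels with posterior
in $[L, U)$.  Candidates enumerate all $L, U$ on a 0.025 grid with
$U - L \ge 0.1$ — 703 intervals.  Per patient, the relative size of each
segment is accumulated over all slices before dividing by the accumulated
myocardium size.  Because maps rarely span the full $[0,1]$ range, each map
is first passed through an order-preserving logistic rescale
(`sigmoid_extend()`) whose center is the midpoint of the observed range and
whose gain sends the observed extremes to 0.01 and 0.99; the anchor values
are an implementation choice (the transform's purpose is comparability
across patients, and any fixed pair of symmetric anchors serves it).

Group differences per segment are tested with a Mann-Whitney test:
$U$ counts pairs with $a > b$ plus half the ties (computed from average
ranks); the two-sided p-value is exact when the smaller group has at most 8
observations and there are no ties (via the null $U$ distribution, identical
to enumerating label assignments), and otherwise uses the normal
approximation with tie-corrected variance and no continuity correction.  The
interval membership rule is half-open with $U = 1$ inclusive, so adjacent
segments partition the probability scale.  No multiplicity correction is
applied by default — the analysis is a descriptive map of raw $p < \alpha$
over the grid — but Benjamini-Hochberg is available behind a flag.  An
intensity-threshold baseline (`intensity_baseline_segment()`, thresholds
relative to the maximum scar intensity over all the patient's slices)
provides the comparison that skips probability mapping.

Because the 703 tests are strongly correlated (nested intervals share
pixels), the *fraction* of significant segments in a null cohort has large
Monte-Carlo spread around $\alpha$, and tie-induced discreteness can push it
below $\alpha$; the acceptance test therefore averages several null cohorts
and checks a band, not a point.

## ROC evaluation

`map_roc()` pools all of a patient's slices into one ROC curve (threshold
sweep over unique scores; trapezoidal AUC, which with the half-tie
convention equals $U/(n_{\text{pos}} n_{\text{neg}})$ exactly — a
cross-module identity the tests assert).  `average_roc()` averages patients
*vertically*: each TPR curve is interpolated onto a common FPR grid and the
95% band is the pointwise normal interval across patients, clipped to
$[0,1]$.  Vertical averaging and pointwise-across-patients intervals are one
of several conventions; they are chosen for simplicity and documented rather
than asserted as canonical.  On phantoms, ROC against the ground-truth core
excludes the blended border band, whose binary label would be arbitrary.

## Numerical choices and degenerate inputs

* ORMP: zero signals return the all-zero code; selection stops early if no
  atom has a numerically independent component (tolerance $10^{-10}$).
* RLS-DLA: a non-finite step gain ($w^\top u = -1$) raises an error with the
  step index.
* Posterior: non-finite features map to `NA`; log-domain evaluation avoids
  Gaussian tail underflow.
* `rp_image`: both-zero residuals give 0.5; negative residuals are an error.
* `sigmoid_extend`: constant maps are returned unchanged with a warning.
* `mann_whitney`: all-identical pooled values give $p = 1$.
* Probability maps are stored as 32-bit integer-scaled TIFF (quantization
  step $2^{-32}$), with exact 0 marking non-myocardium; masks as 8-bit
  label PNG (0/1/2), which round-trips bit-exactly.

## Problem sizes used in the tests

The shipped tests and the acceptance script train on 2 phantom slices
(about 1500 class-pure training vectors), evaluate on 10 held-out phantoms,
and use cohorts of 10 + 10 patients with 2 slices each — sizes at which
every stage's behavior is already asymptotic enough for the directional
claims while a full run stays comfortably interactive.

## Known limitations

* Univariate features only; the combined (DC, texture) feature is out of
  scope.
* The phantom's textures are stationary gratings — the easiest honest case
  for dictionary discrimination; real myocardial texture is less regular.
* DICOM input is not supported (PNG/TIFF only).
* The Gaussian class model can assign nonzero density outside $[0,1]$ for
  the texture feature; in practice the posterior only ever evaluates inside.
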
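---
title: "From facial kinematics to decision-making style: the facestyle pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From facial kinematics to decision-making style: the facestyle pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facestyle)
```

## The problem

Decision-making style — the habitual way a person approaches decisions —
is conventionally measured with the General Decision-Making Style
questionnaire (GDMS): 25 Likert items scored 1–5, summed in blocks of
five into the dimensions *spontaneous*, *avoidant*, *rational*,
*dependent* and *intuition* (each in 5–25). `facestyle` implements an
instrument-free alternative: regress those five scores on spectral
summaries of a subject's facial micro-movements, captured as a 3D
landmark mesh (1347 points at full resolution) tracked at 30 Hz while
the subject speaks for about a minute.

The pipeline is deliberately linear and auditable: translation
normalization, smoothing, length standardization, mobility-based
landmark selection, windowed Fourier features, PCA, and one of four
linear regression variants.

## Preprocessing

**Coordinate shift.** Camera-frame coordinates depend on where the
subject sat. A designated reference landmark (the face "vertex") is
subtracted from every landmark. Two readings are implementable: subtract
the reference *per frame* (also removes whole-head translation) or its
*first-frame* position only. Per-frame is the default
(`shift_mode = "per_frame"`): it is the stricter normalization, is
idempotent, and makes the pipeline invariant to arbitrary head drift,
which the simulator deliberately injects. The reference index is
configurable (`reference_point`, default 0) since no anatomical labeling
of the mesh is assumed.

**Mean filtering.** Each scalar series is replaced by a centered moving
average of width `W` (3 or 5 frames). A forward-window reading of the
same filter would shift every series by `(W-1)/2` frames; the centered
reading is phase-preserving and is what "replace the central value"
describes. At the series ends the window is clipped to the available
frames (width 2 at the boundary for `W = 3`); since 150 frames are
trimmed from each end immediately afterwards, end handling is
immaterial in practice.

**Trim and length standardization.** Subjects need a few seconds to
settle and the capture tail is contaminated by the operator stopping the
recording, so `round(trim_seconds * rate)` frames (150 at defaults) are
dropped from each end. The remainder is cut to exactly
`retained_frames = 2112` frames — a constant chosen so the sliding-window
layout below is uniform across subjects (2112 = 64 · 33 = the 128-frame
window plus 31 hops of 64). Captures that come up short are *flagged
discarded*, never padded; the per-capture report keeps the accounting
visible (a 240-subject corpus discarding 4 captures is typical at these
settings).

## Landmark screening

Most of the 1347 mesh points barely move during speech. For each capture
the inter-frame Euclidean displacement matrix
`d[i, j] = ‖p[i+1, j] − p[i, j]‖` (shape `(N−1) × P`) is reduced to
per-landmark sample variances, and landmarks are ranked by the mean
variance across the corpus; the `top_points = 100` most variable are
kept. Ties are broken by ascending landmark index so the selection is
deterministic. Screening uses the whole preprocessed corpus by default —
the selection statistic involves no score information, so this is not
target leakage, and it matches how a fixed landmark panel would be
chosen in practice.

Two invariants pin the implementation down: scaling all coordinates by
`c` scales every variance by `c²` without changing the ranking, and the
selection is invariant to sample order.

## Spectral features

For each selected landmark and axis, a 128-frame window slides by 64
frames (50% overlap), giving `(2112 − 128)/64 + 1 = 32` windows. Each
window is transformed with the unnormalized forward DFT (no `1/L`
factor) and summarized by the **mean** and **sample variance** of its
128 coefficient moduli `|Z_k| = sqrt(Re² + Im²)`. No taper is applied:
the design uses raw rectangular windows. The feature vector is laid out
deterministically — landmark-major, axes x/y/z, windows in time order,
mean before variance — for 2 × 32 = 64 features per axis, 192 per
landmark, 19200 per subject at full scale.

Two normalization questions are ambiguous in this design's lineage and
are resolved explicitly here: the variance of the 128 moduli uses the
*sample* normalization (denominator 127), consistent with the screening
variance; and the DFT is unnormalized, so a constant series `c` has
modulus `128·|c|` at bin 0 — whence the closed forms used in the tests
(window mean `|c|`, window variance `128·c²`).

## Dimensionality reduction and regression

With 19200 features and ~192 training subjects, regression without
reduction would interpolate noise. PCA is fitted **on training rows
only** (the permissive fit-on-everything variant is available but not
default, to avoid leaking validation structure) and the first
`pca_components = 80` components are kept; at full scale this retains
more than 98% of feature variance, and the fit warns whenever it
retains less.

Four regressors are provided on the component scores:

* `lr` — ordinary least squares (`stats::lm.fit`);
* `svr` — linear-kernel ε-SVR (`e1071::svm`) with `C = 1` and
  `ε = 0.1 · sd(y)`. Component scores are standardized inside the SVR
  (the library default): the components are meter-scaled and tiny, and
  with unscaled inputs a fixed `C = 1` clamps the fit so severely that
  results become erratic across dimensions;
* `ridgecv` — ridge regression with the penalty chosen by generalized
  cross-validation over 13 log-spaced penalties `1e−3 … 1e3`, computed
  from one SVD of the centered design. The unit test cross-checks the
  GCV profile against an independent implementation (`MASS::lm.ridge`);
* `br` — Bayesian linear regression with conjugate Gamma hyperpriors
  (shape/rate `1e−6`) on the noise and weight precisions, estimated by
  iterative evidence maximization on the SVD basis, to a coefficient
  tolerance of `1e−6` within 300 iterations.

## Splitting and evaluation

Scores are not uniform, so a plain random split can starve the
validation set of extreme scorers. The split orders subjects by one
dimension's score (descending, ties by subject id), cuts four contiguous
strata (any remainder goes to the highest strata), and samples
`round(0.8 · size)` training subjects per stratum with the run seed: at
n = 240, four strata of 60 with 48/12 each, 192/48 overall. Each
dimension gets its own split and model by default (`--shared-split`
style reuse is a one-flag change since the plan is a first-class
object).

Validation performance is the Pearson correlation between predicted and
observed scores plus RMSE; a constant validation target makes r
undefined and is reported as `NA` with a warning rather than silently.
10-fold cross-validation (seeded shuffle, near-equal folds, PCA refitted
per fold) is available for every dimension × algorithm cell.

**Split-half reliability.** Each preprocessed capture is split into its
odd-frame and even-frame halves. A half-length series cannot be pushed
through the full-length model — the feature dimensionality would change —
so two *parallel pipelines* with identical hyperparameters, window and
hop halved (preserving the 32-windows-per-axis layout), are trained on
the training half-sets, and their validation predictions are correlated.
The Spearman–Brown step-up `2r/(1+r)` is implemented but off by
default: the halves are interleaved frames of the same capture, not
independent test halves, so the uncorrected r is the honest statistic.

## The synthetic cohort generator

The generator stands in for unreleased capture corpora and defines the
package's study conditions:

* **Scores.** Latent traits `z ~ N(0, I₅)` per subject;
  dimension scores are `round(mean_d + sd_d · z_d)` clipped to 5–25.
  Default means and SDs pool published young-adult gender-specific GDMS
  norms (130 women / 110 men) via the law of total variance
  (`gdms_score_norms()`); gender-specific overrides are supported.
* **Motion.** Every landmark sits at a template position (a fixed,
  point-count-determined face-sized cloud) plus per-subject shape jitter
  (SD 0.5 mm), and rides a shared two-sinusoid head drift (2–8 mm,
  0.02–0.2 Hz) that the coordinate-shift stage must remove. Signal
  landmarks additionally oscillate as sums of 2–4 sinusoids with fixed
  per-point frequencies in (0.5, 8) Hz — below the 15 Hz Nyquist limit
  and resolvable in 128-frame windows — with common amplitude
  `base_amplitude · max(0, 1 + coupling · ⟨w_j, z⟩)` and i.i.d. Gaussian
  sensor noise (default 0.3 mm) on every coordinate.
* **Trait weights.** Each signal landmark carries exactly one trait
  dimension, assigned in balanced rotation with random sign and weight
  norm 0.25. Balance makes the five dimensions exchangeable by
  construction, so differences in how well dimensions are predicted
  reflect properties of the *scores* (e.g. their dispersion), not luck
  in the weight draw; the 0.25 norm keeps the amplitude factor positive
  for all but ~0.4% of draws, preserving the linear coupling.
* **Determinism.** Template, signal-point set, frequencies and weights
  are cohort-level constants derived from the seed; each subject gets an
  independent sub-seed for phases, jitter, drift and noise. The same
  configuration reproduces bit-identical cohorts.

What the generator does **not** emulate: facial anatomy and mesh
topology, expression semantics, speech-correlated articulation,
autocorrelated or heteroscedastic sensor noise, and any nonlinear or
time-varying trait coupling. Passing the planted-signal tests therefore
demonstrates that the pipeline's machinery is correct and sensitive, not
that real faces carry this much linearly decodable signal.

## Problem sizes used in tests and the acceptance script

Full-scale cohorts (240 × 1347 × 2500 frames) occupy ~19 GB as dense
arrays, so validation studies run at proportionally scaled geometries,
keeping every count derived from configuration rather than hard-coded:

* **Planted-signal recovery / reliability / score-dispersion studies:**
  240 subjects, 60 landmarks (30 signal), 600 frames; pipeline 288
  retained frames, 64-frame windows with 32-frame hop (8 windows per
  axis), top 30 landmarks, PCA to 80.
* **Null-versus-planted comparison:** 100 subjects at the same capture
  geometry, PCA to 40 (80 training rows), 20 zero-coupling null cohorts
  against one planted cohort, both arms at the same scale.
* **Toy preset (`toy_config()`):** 20 subjects, used for smoke tests and
  the CLI example.

With coupling 1.5 and zero noise the linear-regression pipeline recovers
validation r ≈ 0.98 on every dimension and split-half reliability
≈ 0.999; with 0.3 mm noise, recovery stays far above the zero-coupling
null's 95th percentile. When one dimension's score SD is shrunk to 1,
its scores quantize to a handful of levels and the rounding error
becomes a fixed fraction of the score variance; that dimension becomes
the worst-predicted on average across the four algorithms — the
dispersion-sensitivity one expects from correlation-based evaluation.
(That comparison is run on zero-noise cohorts: the effect is a few
hundredths of r, and sensor noise at desk scale adds per-dimension
estimation scatter of the same order.)

## Known limitations

* Landmark corpora are held in memory as dense arrays; full-resolution
  corpora should be processed per subject via the CLI stages rather
  than `simulate_cohort()`.
* The regressors are linear by design; no interaction or nonlinear
  effects are modeled.
* Screening on the full corpus is the default to match the panel-style
  design; `screen_points()` accepts any subset of sequences when a
  training-only screen is wanted.
* The GDMS item-to-dimension key is not standardized across
  translations; `score_gdms_items()` takes the key as an argument and
  defaults to consecutive blocks of five.
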
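# facestyle

Automatic recognition of decision-making style from 3D facial kinematics.

`facestyle` implements a complete, tested pipeline from depth-camera
facial-landmark time series to predicted scores on the five dimensions of
the General Decision-Making Style questionnaire (GDMS): *spontaneous*,
*avoidant*, *rational*, *dependent* and *intuition*, each the sum of five
1–5 Likert items (range 5–25). The target setting is a capture of 1347
facial mesh points tracked in 3D at 30 Hz while a subject speaks, paired
with that subject's questionnaire scores.

Because raw capture corpora of this kind are rarely shareable, the package
also ships a first-class synthetic-cohort generator that plants a known,
recoverable linear coupling between latent decision-style traits and the
oscillation amplitudes of facial landmarks. Every downstream claim the
package makes about itself is demonstrated by recovering that planted
signal.

## The method

For each subject, with landmark positions `p[i, j] ∈ R³` at frame `i`,
point `j`:

1. **Coordinate shift** — subtract a reference landmark (the face
   "vertex") per frame: `p'[i, j] = p[i, j] − p[i, ref]`, removing
   camera-relative placement and head translation.
2. **Mean filtering** — centered moving average of width `W ∈ {3, 5}` on
   every scalar series, suppressing sensor noise.
3. **Trim and standardize** — drop the first and last 5 s (150 frames at
   30 Hz), keep the first 2112 frames; shorter captures are discarded.
4. **Landmark screening** — inter-frame Euclidean displacements
   `d[i, j] = ‖p'[i+1, j] − p'[i, j]‖` give per-landmark sample variances
   `σ²_j`; landmarks are ranked by the corpus mean of `σ²_j` and the top
   100 retained.
5. **Spectral features** — per selected landmark and axis, a 128-frame
   window slides by 64 frames (32 windows over 2112 frames); each window
   contributes the mean and sample variance of its unnormalized DFT
   coefficient moduli `|Z_k|`. Total: 2 × 32 × 3 × 100 = **19200
   features** per subject.
6. **PCA** — fitted on training rows only, 19200 → 80 components
   (retaining > 98% of feature variance at full scale).
7. **Regression** — per dimension, one of: ordinary least squares
   (`lr`), linear-kernel ε-SVR (`svr`), ridge with GCV-selected penalty
   (`ridgecv`), or evidence-maximization Bayesian ridge (`br`), trained
   on a score-stratified 8:2 split (four score-ordered strata of 60,
   48/12 each at n = 240).
8. **Evaluation** — validation Pearson r and RMSE, optional 10-fold CV,
   and odd/even-frame split-half reliability via two parallel
   half-length pipelines.

## Worked example

Simulate a 60-subject cohort whose landmark oscillation amplitudes are
coupled to the latent traits (coupling 1.5, 0.3 mm sensor noise), then
run the full pipeline at a proportionally scaled-down geometry:

```r
library(facestyle)

sim <- simulation_config(n_subjects = 60, n_points = 60, n_frames = 600,
                         n_signal_points = 30, coupling_strength = 1.5,
                         noise_sd_m = 3e-4, seed = 42)
cfg <- pipeline_config(retained_frames = 288, fft_window = 64, fft_hop = 32,
                       top_points = 30, pca_components = 40, seed = 42)

cohort <- simulate_cohort(sim)
report <- run_style_pipeline(cohort, cfg, algorithms = "lr",
                             filter_windows = c(3, 5), reliability = TRUE)
tidy(report)
#> # A tibble: 10 × 9
#>    dimension   algorithm filter_window pearson_r  rmse n_train n_val
#>  1 spontaneous lr                    3     0.982 0.883      48    12
#>  2 avoidant    lr                    3     0.760 2.11       48    12
#>  3 rational    lr                    3     0.913 1.74       48    12
#>  4 dependent   lr                    3     0.645 4.17       48    12
#>  5 intuition   lr                    3     0.628 3.63       48    12
#>  6 spontaneous lr                    5     0.982 0.875      48    12
#>  ...          (explained_variance and split_half_r columns follow)

glance(report)
#> # A tibble: 2 × 5
#>   algorithm filter_window r_mean  r_sd rmse_mean
#> 1 lr                    3  0.786 0.158      2.51
#> 2 lr                    5  0.614 0.276      3.26
```

`pearson_r` is the correlation between predicted and observed GDMS scores
on the held-out validation subjects — the planted trait signal is
recovered well above chance on every dimension. `split_half_r` near 1
says the two half-capture pipelines agree almost perfectly. The wider
`W = 5` filter attenuates the faster oscillations and costs accuracy, a
trade-off the report makes visible. `autoplot(report)` and
`plot_predictions(report)` draw the corresponding figures.

Individual stages are exported (`shift_to_reference()`, `mean_filter()`,
`trim_and_standardize()`, `screen_points()`, `extract_features()`,
`stratified_split()`, `fit_pipeline()`, `crossvalidate()`,
`split_half_reliability()`), and a thin command-line front end in
`inst/cli/facestyle` chains them over on-disk CSVs (`simulate`,
`preprocess`, `screen`, `extract`, `run-all`).

See `vignettes/facial-kinematics-pipeline.Rmd` for the full model
description, the simulator's assumptions, and every numerical design
choice.

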
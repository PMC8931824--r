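test_that("an amplitude-free, noise-free capture is constant over time", {
  cfg <- simulation_config(n_subjects = 1, n_points = 8, n_frames = 50,
                           n_signal_points = 4, base_amplitude_m = 0,
                           coupling_strength = 0, noise_sd_m = 0, seed = 2)
  # kill the head drift by comparing after per-frame shift
  traits <- simulate_traits(1, cfg$seed)
  seq <- shift_to_reference(simulate_sample(traits[1, ], cfg, 99L), 0)
  rng <- apply(seq$coords, c(2, 3), function(v) diff(range(v)))
  expect_true(all(rng < 1e-12))
})

test_that("simulation is bit-identical under the same seed", {
  cfg <- tiny_sim(n_subjects = 2, noise = 0.0003, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$sequences[[1]]$coords, b$sequences[[1]]$coords)
  expect_identical(a$scores, b$scores)
  expect_identical(a$traits, b$traits)
  c <- simulate_cohort(tiny_sim(n_subjects = 2, noise = 0.0003, seed = 10))
  expect_false(identical(a$sequences[[1]]$coords, c$sequences[[1]]$coords))
})

test_that("stronger coupling raises signal-point displacement variance", {
  base <- tiny_sim(n_subjects = 1, coupling = 0.5, seed = 4)
  strong <- tiny_sim(n_subjects = 1, coupling = 1.0, seed = 4)
  traits <- simulate_traits(1, base$seed)
  # put the subject at z = +1 on every dimension so <w, z> has a known sign
  traits[1, paste0("z_", gdms_dimensions())] <-
    as.list(rep(1, 5))
  design <- facestyle:::simulation_design(base)
  # restrict to landmarks whose summed weight is positive: for these,
  # amplitude must increase with coupling
  wsum <- rowSums(design$weights)
  pos <- design$signal_points[wsum > 0.05] + 1L
  sv <- function(cfg) {
    seq <- shift_to_reference(simulate_sample(traits[1, ], cfg, 77L), 0)
    point_variance(frame_displacements(seq))
  }
  v_base <- sv(base)
  v_strong <- sv(strong)
  expect_true(all(v_strong[pos] > v_base[pos]))
})

test_that("cohorts deliver matched captures, scores and traits", {
  cfg <- simulation_config(n_subjects = 240, n_points = 4, n_frames = 40,
                           n_signal_points = 2, seed = 6)
  coh <- simulate_cohort(cfg)
  expect_length(coh$sequences, 240L)
  expect_equal(nrow(coh$scores), 240L)
  expect_equal(nrow(coh$traits), 240L)
  expect_equal(vapply(coh$sequences, `[[`, "", "subject_id"),
               coh$scores$subject_id)
  expect_true(all(as.matrix(coh$scores[, gdms_dimensions()]) >= 5))
  expect_true(all(as.matrix(coh$scores[, gdms_dimensions()]) <= 25))
})

test_that("generated scores are calibrated to the configured distribution", {
  cfg <- simulation_config(n_subjects = 10000, n_points = 1, n_frames = 2,
                           n_signal_points = 0, seed = 12)
  traits <- simulate_traits(cfg$n_subjects, cfg$seed)
  scores <- simulate_scores(traits, cfg)
  for (d in c("spontaneous", "avoidant")) {
    se <- cfg$score_sds[[d]] / sqrt(cfg$n_subjects)
    expect_lt(abs(mean(scores[[d]]) - cfg$score_means[[d]]), 3 * se + 0.1)
    # 0.1 allowance for the rounding/clipping of the discrete scale
    expect_equal(sd(scores[[d]]), cfg$score_sds[[d]], tolerance = 0.05)
  }
})

test_that("with zero coupling no single feature correlates with scores", {
  cfg <- simulation_config(n_subjects = 500, n_points = 6, n_frames = 80,
                           n_signal_points = 4, coupling_strength = 0,
                           noise_sd_m = 0.0003, seed = 13)
  pipe <- pipeline_config(trim_seconds = 0.5, retained_frames = 48,
                          fft_window = 16, fft_hop = 8, top_points = 4,
                          pca_components = 2, seed = 13)
  coh <- simulate_cohort(cfg)
  pre <- preprocess_cohort(coh$sequences, pipe)
  fm <- extract_features(pre$sequences, screen_points(pre$sequences, 4), pipe)
  y <- coh$scores$spontaneous[match(fm$subject_ids, coh$scores$subject_id)]
  rs <- abs(apply(fm$values, 2, function(col) {
    if (sd(col) == 0) 0 else cor(col, y)
  }))
  # null correlations at n = 500: |r| < 0.1 is ~2.2 sigma, so the vast
  # majority of features must satisfy it
  expect_gte(mean(rs < 0.1), 0.95)
})

test_that("cohorts write to disk in the documented layout", {
  cfg <- simulation_config(n_subjects = 3, n_points = 4, n_frames = 20,
                           n_signal_points = 2, seed = 14)
  coh <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "scores.csv")))
  expect_true(file.exists(file.path(dir, "traits.csv")))
  back <- read_landmark_table(file.path(dir, "S002.csv"))
  expect_equal(back$coords, coh$sequences[[2]]$coords, tolerance = 1e-9)
  scores <- read_gdms_scores(file.path(dir, "scores.csv"))
  expect_equal(scores[, c("subject_id", gdms_dimensions())],
               coh$scores[, c("subject_id", gdms_dimensions())])
})
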
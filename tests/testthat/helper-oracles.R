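# Independent oracles, coded directly from definitions so they share no
# code path with the package implementations they check.

# O(L^2) discrete Fourier transform by direct summation
brute_dft <- function(x) {
  L <- length(x)
  vapply(0:(L - 1L), function(k) {
    sum(x * exp(-2i * pi * k * (0:(L - 1L)) / L))
  }, complex(1))
}

# two-pass sample variance, denominator n - 1
brute_variance <- function(v) {
  m <- sum(v) / length(v)
  sum((v - m)^2) / (length(v) - 1)
}

# Pearson r from raw deviation sums
brute_pearson <- function(a, b) {
  da <- a - sum(a) / length(a)
  db <- b - sum(b) / length(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

brute_rmse <- function(pred, actual) {
  sqrt(sum((pred - actual)^2) / length(pred))
}

# build a landmark_sequence from a function of (frame, point, axis)
make_seq <- function(n_frames, n_points, f, subject_id = "T01",
                     sample_rate_hz = 30) {
  coords <- array(0, c(n_frames, n_points, 3))
  for (j in seq_len(n_points)) {
    for (m in 1:3) {
      coords[, j, m] <- f(seq_len(n_frames) - 1L, j - 1L, m)
    }
  }
  landmark_sequence(coords, subject_id, sample_rate_hz)
}

# small matched configs used across test files
tiny_pipeline <- function(...) {
  args <- list(retained_frames = 160, fft_window = 32, fft_hop = 16,
               top_points = 12, pca_components = 8)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(pipeline_config, args)
}

tiny_sim <- function(n_subjects = 60, coupling = 1.5, noise = 0, seed = 1L) {
  simulation_config(
    n_subjects = n_subjects, n_points = 24, n_frames = 480,
    n_signal_points = 12, coupling_strength = coupling,
    noise_sd_m = noise, seed = seed
  )
}
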
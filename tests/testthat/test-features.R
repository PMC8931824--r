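test_that("window DFT matches closed forms for constant and zero input", {
  L <- 128
  spec <- window_fft(rep(3, L))
  expect_equal(spec$moduli[1], 128 * 3)
  expect_equal(spec$moduli[-1], rep(0, L - 1), tolerance = 1e-9)
  expect_equal(window_fft(rep(0, L))$moduli, rep(0, L))
  expect_error(window_fft(rep(0, 64), L = 128), "length")
})

test_that("a pure on-bin cosine concentrates at its two mirror bins", {
  L <- 128
  k0 <- 4
  x <- cos(2 * pi * k0 * (0:(L - 1)) / L)
  m <- window_fft(x)$moduli
  expect_equal(m[k0 + 1], L / 2, tolerance = 1e-9)
  expect_equal(m[L - k0 + 1], L / 2, tolerance = 1e-9)
  expect_equal(m[-c(k0 + 1, L - k0 + 1)], rep(0, L - 2), tolerance = 1e-9)
  # and agrees with the O(L^2) direct-summation oracle
  expect_equal(m, Mod(brute_dft(x)), tolerance = 1e-8)
})

test_that("window DFT agrees with the brute-force oracle on random input", {
  set.seed(41)
  for (rep_i in 1:5) {
    x <- rnorm(128)
    got <- window_fft(x)$moduli
    want <- Mod(brute_dft(x))
    expect_lt(max(abs(got - want)) / max(want), 1e-8)
  }
})

test_that("moduli of real input are conjugate-symmetric", {
  set.seed(42)
  for (rep_i in 1:10) {
    m <- window_fft(rnorm(64))$moduli
    k <- 1:63
    expect_equal(m[k + 1], m[64 - k + 1], tolerance = 1e-9)
  }
})

test_that("window statistics use mean and sample variance of the moduli", {
  L <- 128
  c0 <- 0.7
  st <- window_stats(window_fft(rep(c0, L)))
  # moduli are (L*c, 0, ..., 0): mean c, variance ((Lc-c)^2+(L-1)c^2)/(L-1)
  expect_equal(unname(st["mean"]), c0)
  expect_equal(unname(st["variance"]), 128 * c0^2)
  expect_equal(unname(window_stats(window_fft(rep(0, L)))), c(0, 0))
  set.seed(43)
  m <- abs(rnorm(128))
  expect_equal(unname(window_stats(m)["variance"]), brute_variance(m),
               tolerance = 1e-12)
})

test_that("feature layout enumerates (point, axis, window, statistic)", {
  cfg <- pipeline_config()
  layout <- feature_layout(0:99, cfg)
  expect_length(layout, 19200L)
  expect_false(anyDuplicated(layout) > 0)
  # point-major: first landmark's features first, mean before variance
  expect_equal(layout[1], "p0_x_w0_mean")
  expect_equal(layout[2], "p0_x_w0_var")
  expect_equal(layout[193], "p1_x_w0_mean")
  # per-axis and per-landmark block sizes
  expect_equal(sum(startsWith(layout, "p0_x_")), 64L)
  expect_equal(sum(startsWith(layout, "p0_")), 192L)
})

test_that("sample features follow the layout and are deterministic", {
  cfg <- tiny_pipeline()
  set.seed(44)
  seq <- make_seq(cfg$retained_frames, 6, function(i, j, m) rnorm(length(i)))
  sel <- c(0L, 3L, 5L)
  row <- extract_sample_features(seq, sel, cfg)
  expect_length(row, length(sel) * 3 * n_fft_windows(cfg) * 2)
  expect_identical(row, extract_sample_features(seq, sel, cfg))

  # permuting `selected` permutes whole landmark blocks correspondingly
  row_perm <- extract_sample_features(seq, c(5L, 0L, 3L), cfg)
  block <- 3 * n_fft_windows(cfg) * 2
  expect_equal(unname(row_perm[1:block]),
               unname(row[(2 * block + 1):(3 * block)]))

  # first feature is the mean modulus of the first window of p0's x series,
  # computed independently via the single-window operations
  w1 <- window_stats(window_fft(seq$coords[1:cfg$fft_window, 1, 1]))
  expect_equal(unname(row[1]), unname(w1["mean"]), tolerance = 1e-12)
  expect_equal(unname(row[2]), unname(w1["variance"]), tolerance = 1e-12)

  expect_error(extract_sample_features(seq, integer(0), cfg), "empty")
  expect_error(extract_sample_features(seq, 99L, cfg), "range")
  short <- make_seq(cfg$retained_frames - 1, 6, function(i, j, m) 0 * i)
  expect_error(extract_sample_features(short, sel, cfg), "retained_frames")
})

test_that("non-DC moduli are invariant to adding a constant offset", {
  cfg <- tiny_pipeline()
  set.seed(45)
  x <- rnorm(cfg$fft_window)
  m0 <- window_fft(x)$moduli
  m1 <- window_fft(x + 10)$moduli
  expect_equal(m1[-1], m0[-1], tolerance = 1e-9)
  expect_equal(m1[1], abs(sum(x) + 10 * cfg$fft_window), tolerance = 1e-9)
})

test_that("corpus feature matrices stack rows and round-trip via CSV", {
  cfg <- tiny_pipeline()
  set.seed(46)
  seqs <- lapply(1:3, function(s) {
    make_seq(cfg$retained_frames, 5, function(i, j, m) rnorm(length(i)),
             sprintf("S%02d", s))
  })
  fm <- extract_features(seqs, c(0L, 2L), cfg)
  expect_equal(dim(fm$values), c(3L, 2L * 3L * n_fft_windows(cfg) * 2L))
  expect_equal(fm$subject_ids, c("S01", "S02", "S03"))
  expect_equal(unname(fm$values[2, ]),
               unname(extract_sample_features(seqs[[2]], c(0L, 2L), cfg)))

  path <- withr::local_tempfile(fileext = ".csv")
  write_features(fm, path)
  back <- read_features(path)
  expect_equal(back$subject_ids, fm$subject_ids)
  expect_equal(unname(back$values), unname(fm$values), tolerance = 1e-12)
  expect_equal(as.character(back$layout), as.character(fm$layout))
})
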
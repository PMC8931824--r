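#' Discrete Fourier transform of one analysis window
#'
#' Unnormalized forward DFT (no 1/L factor) of a real series of exactly
#' the configured window length, plus the coefficient moduli
#' `|Z_k| = sqrt(Re^2 + Im^2)`. For real input the moduli satisfy the
#' conjugate symmetry `|Z_k| = |Z_(L-k)|`.
#'
#' @param x Numeric vector of length `L` (the FFT window; 128 at
#'   defaults).
#' @param L Expected window length; defaults to `length(x)` but is
#'   checked when supplied so layout mismatches fail loudly.
#' @return A `window_spectrum`: list with `coefficients` (complex length
#'   L) and `moduli` (numeric length L).
#' @export
window_fft <- function(x, L = length(x)) {
  if (length(x) != L) {
    stop("window has length ", length(x), ", expected ", L, call. = FALSE)
  }
  if (!is.numeric(x) || anyNA(x)) stop("window must be numeric", call. = FALSE)
  co <- stats::fft(x)
  structure(list(coefficients = co, moduli = Mod(co)),
            class = "window_spectrum")
}

#' Mean and variance of window-spectrum moduli
#'
#' The two per-window features: the arithmetic mean and the sample
#' variance (denominator L - 1) of the L coefficient moduli.
#'
#' @param spec A `window_spectrum` from [window_fft()], or a bare numeric
#'   vector of moduli.
#' @return Named numeric vector `c(mean = , variance = )`.
#' @export
window_stats <- function(spec) {
  m <- if (inherits(spec, "window_spectrum")) spec$moduli else spec
  c(mean = mean(m), variance = stats::var(m))
}

#' Deterministic feature layout
#'
#' Names and orders every spectral feature as the tuple
#' (landmark rank, axis, window, statistic), point-major: all features of
#' the first selected landmark first, within a landmark the axes x, y, z,
#' within an axis the windows in time order, within a window mean before
#' variance. Length is `top_points * 3 * n_windows * 2` — 19200 at the
#' full-scale defaults (100 landmarks, 32 windows).
#'
#' @param selected Integer vector of selected 0-based landmark indices
#'   (screening order).
#' @param cfg A [pipeline_config()].
#' @return Character vector of feature names
#'   `p<point>_<axis>_w<window>_<mean|var>` with attributes `point`,
#'   `axis`, `window`, `statistic` giving the tuple columns.
#' @export
feature_layout <- function(selected, cfg) {
  nw <- n_fft_windows(cfg)
  grid <- expand.grid(
    statistic = c("mean", "var"),
    window = seq_len(nw) - 1L,
    axis = c("x", "y", "z"),
    point = as.integer(selected),
    stringsAsFactors = FALSE
  )[, 4:1]
  nm <- sprintf("p%d_%s_w%d_%s", grid$point, grid$axis, grid$window,
                grid$statistic)
  structure(nm, point = grid$point, axis = grid$axis,
            window = grid$window, statistic = grid$statistic)
}

#' Spectral feature row for one preprocessed capture
#'
#' Slides an `fft_window`-frame window by `fft_hop` frames along each
#' axis series of each selected landmark (windows start at frames 0,
#' hop, 2*hop, ...), takes the unnormalized DFT of each window, and
#' records the mean and sample variance of the coefficient moduli. At
#' the full-scale defaults this yields 32 windows x 2 statistics = 64
#' features per axis, 192 per landmark, 19200 per sample.
#'
#' @param seq A preprocessed [landmark_sequence()] with exactly
#'   `cfg$retained_frames` frames.
#' @param selected Integer vector of selected 0-based landmark indices.
#' @param cfg A [pipeline_config()].
#' @return Named numeric vector in [feature_layout()] order.
#' @export
extract_sample_features <- function(seq, selected, cfg) {
  stopifnot(inherits(seq, "landmark_sequence"))
  N <- n_frames(seq)
  if (N != cfg$retained_frames) {
    stop("sequence has ", N, " frames; expected retained_frames = ",
         cfg$retained_frames, call. = FALSE)
  }
  if (length(selected) == 0L) stop("`selected` is empty", call. = FALSE)
  if (any(selected < 0L | selected >= n_points(seq))) {
    stop("selected landmark index out of range", call. = FALSE)
  }
  L <- cfg$fft_window
  nw <- n_fft_windows(cfg)
  starts <- (seq_len(nw) - 1L) * cfg$fft_hop
  # series matrix: frames x (selected points * 3 axes), point-major
  series <- matrix(
    seq$coords[, selected + 1L, , drop = FALSE],
    nrow = N
  )[, rep(seq_along(selected), each = 3L) +
      length(selected) * rep(0:2, times = length(selected)), drop = FALSE]
  ns <- ncol(series)
  # window matrix: L x (n_series * n_windows), windows fastest
  win_idx <- outer(seq_len(L), starts, `+`)   # L x nw frame indices
  wm <- matrix(series[as.vector(win_idx), , drop = FALSE], nrow = L)
  moduli <- Mod(stats::mvfft(wm))             # L x (nw * ns)
  mu <- colMeans(moduli)
  va <- colSums((moduli - rep(mu, each = L))^2) / (L - 1)
  feats <- rbind(mu, va)                      # statistic fastest
  layout <- feature_layout(selected, cfg)
  stats::setNames(as.vector(feats), layout)
}

#' Feature matrix for a corpus
#'
#' Applies [extract_sample_features()] to every capture and stacks the
#' rows into a samples x features matrix with a shared layout.
#'
#' @param sequences List of preprocessed [landmark_sequence()] objects.
#' @param selected Selected 0-based landmark indices (typically
#'   `screening$selected`), or a `screening_result`.
#' @param cfg A [pipeline_config()].
#' @return A `feature_matrix`: list with `values` (numeric matrix,
#'   rownames = subject ids), `subject_ids`, and `layout`.
#' @export
extract_features <- function(sequences, selected, cfg) {
  if (inherits(selected, "screening_result")) selected <- selected$selected
  rows <- lapply(sequences, extract_sample_features,
                 selected = selected, cfg = cfg)
  values <- do.call(rbind, rows)
  ids <- vapply(sequences, `[[`, "", "subject_id")
  rownames(values) <- ids
  structure(
    list(values = values, subject_ids = ids,
         layout = feature_layout(selected, cfg)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d spectral features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname extract_features
#' @param x A `feature_matrix`.
#' @param ... Unused.
#' @method as_tibble feature_matrix
#' @export
as_tibble.feature_matrix <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(subject_id = x$subject_ids),
    tibble::as_tibble(x$values, .name_repair = "minimal")
  )
}

#' Write / read a feature matrix as CSV with layout-named columns
#'
#' @param x A `feature_matrix`.
#' @param path Output path.
#' @export
write_features <- function(x, path) {
  readr::write_csv(as_tibble.feature_matrix(x), path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab$subject_id
  layout <- colnames(values)
  structure(
    list(values = values, subject_ids = tab$subject_id, layout = layout),
    class = "feature_matrix"
  )
}
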
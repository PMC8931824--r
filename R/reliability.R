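#' Odd/even frame halves of a preprocessed capture
#'
#' Splits a standardized capture into its odd-frame and even-frame
#' subsequences (frames 0, 2, 4, ... and 1, 3, 5, ... in 0-based
#' indexing), each half the length of the input. The halves retain the
#' original subject id; their effective sampling rate is halved but the
#' stored rate is kept so window arithmetic stays in frames.
#'
#' @param seq A [landmark_sequence()] with an even number of frames.
#' @return List with elements `odd` and `even`, both
#'   [landmark_sequence()] objects of `n_frames(seq) / 2` frames.
#' @export
split_half_sequences <- function(seq) {
  stopifnot(inherits(seq, "landmark_sequence"))
  N <- n_frames(seq)
  if (N %% 2L != 0L) {
    stop("frame count must be even to split into halves", call. = FALSE)
  }
  odd_idx <- seq(1L, N, by = 2L)   # 0-based frames 0, 2, 4, ...
  even_idx <- seq(2L, N, by = 2L)  # 0-based frames 1, 3, 5, ...
  list(
    odd = landmark_sequence(seq$coords[odd_idx, , , drop = FALSE],
                            seq$subject_id, seq$sample_rate_hz),
    even = landmark_sequence(seq$coords[even_idx, , , drop = FALSE],
                             seq$subject_id, seq$sample_rate_hz)
  )
}

# Pipeline configuration for half-length sequences: window and hop are
# halved so the windows-per-axis count — and hence the feature layout
# shape — matches the full-length run.
halve_config <- function(cfg) {
  if (cfg$retained_frames %% 2L != 0L || cfg$fft_window %% 2L != 0L ||
      cfg$fft_hop %% 2L != 0L) {
    stop("retained_frames, fft_window and fft_hop must be even for ",
         "split-half analysis", call. = FALSE)
  }
  cfg$retained_frames <- cfg$retained_frames %/% 2L
  cfg$fft_window <- cfg$fft_window %/% 2L
  cfg$fft_hop <- cfg$fft_hop %/% 2L
  validate_pipeline_config(cfg)
  cfg
}

#' Split-half reliability of the score-prediction pipeline
#'
#' Internal-consistency estimate: each preprocessed capture is split
#' into odd-frame and even-frame halves, and two parallel pipelines with
#' identical hyperparameters (FFT window and hop halved, so each axis
#' still yields the same number of windows and the feature layout is
#' shape-identical) are trained on the training half-sets. The Pearson
#' correlation between the two pipelines' validation-set predictions is
#' the per-dimension reliability; the Spearman-Brown step-up
#' `2r / (1 + r)` is available but off by default.
#'
#' @param sequences List of preprocessed [landmark_sequence()] objects
#'   (all `cfg$retained_frames` frames).
#' @param scores Score tibble covering the sequences' subjects.
#' @param screening A `screening_result` (or bare selected-index vector)
#'   from the full-length corpus.
#' @param cfg A [pipeline_config()].
#' @param spearman_brown Apply the step-up correction (default `FALSE`).
#' @return Tibble with one row per dimension: `dimension`, `algorithm`,
#'   `split_half_r`, `n_val`.
#' @export
split_half_reliability <- function(sequences, scores, screening, cfg,
                                   spearman_brown = FALSE) {
  selected <- if (inherits(screening, "screening_result")) {
    screening$selected
  } else {
    as.integer(screening)
  }
  halves <- lapply(sequences, split_half_sequences)
  cfg_half <- halve_config(cfg)
  feats <- list(
    odd = extract_features(lapply(halves, `[[`, "odd"), selected, cfg_half),
    even = extract_features(lapply(halves, `[[`, "even"), selected, cfg_half)
  )
  ids <- feats$odd$subject_ids
  scores <- scores[match(ids, scores$subject_id), , drop = FALSE]
  purrr::map_dfr(gdms_dimensions(), function(dim) {
    plan <- stratified_split(scores, dim, cfg$n_strata, cfg$train_fraction,
                             cfg$seed)
    tr <- ids %in% plan$train_ids
    y <- scores[[dim]]
    preds <- lapply(feats, function(fm) {
      sub <- function(keep) structure(
        list(values = fm$values[keep, , drop = FALSE],
             subject_ids = fm$subject_ids[keep], layout = fm$layout),
        class = "feature_matrix"
      )
      m <- fit_pipeline(sub(tr), y[tr], cfg_half)
      predict(m, sub(!tr))
    })
    r <- stats::cor(preds$odd, preds$even)
    if (spearman_brown) r <- 2 * r / (1 + r)
    tibble::tibble(dimension = dim, algorithm = cfg$algorithm,
                   split_half_r = r, n_val = sum(!tr))
  })
}
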
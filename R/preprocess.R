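#' Shift a capture to face-local coordinates
#'
#' Raw captures are expressed in the camera frame, so absolute positions
#' depend on where the subject sat. Shifting subtracts a reference
#' landmark (the "vertex" of the face) from every other landmark so that
#' all subjects share a face-local origin. In `"per_frame"` mode
#' (default) the reference is subtracted frame by frame, which also
#' removes whole-head translation; `"first_frame"` subtracts only the
#' reference's first-frame position, preserving head motion.
#'
#' @param seq A [landmark_sequence()].
#' @param reference_point 0-based landmark index used as origin.
#' @param mode `"per_frame"` or `"first_frame"`.
#' @return A shifted [landmark_sequence()]; in per-frame mode the
#'   reference landmark's trajectory is identically (0, 0, 0).
#' @export
shift_to_reference <- function(seq, reference_point = 0,
                               mode = c("per_frame", "first_frame")) {
  stopifnot(inherits(seq, "landmark_sequence"))
  mode <- match.arg(mode)
  P <- n_points(seq)
  ref <- as.integer(reference_point)
  if (ref < 0L || ref >= P) {
    stop("`reference_point` must be in 0..", P - 1L, call. = FALSE)
  }
  coords <- seq$coords
  for (m in 1:3) {
    ref_series <- if (mode == "per_frame") {
      coords[, ref + 1L, m]
    } else {
      rep(coords[1L, ref + 1L, m], dim(coords)[1])
    }
    coords[, , m] <- coords[, , m] - ref_series
  }
  landmark_sequence(coords, seq$subject_id, seq$sample_rate_hz)
}

#' Mean-filter a capture
#'
#' Replaces each scalar coordinate series with its centered moving
#' average of width `W` (3 or 5), suppressing sensor noise and
#' micro-vibration. At the series ends the centered window is clipped to
#' the available frames, so the frame count is unchanged. The trim stage
#' downstream removes far more than the affected edge frames.
#'
#' @param seq A [landmark_sequence()].
#' @param W Odd window width, 3 or 5.
#' @return A filtered [landmark_sequence()] with the same dimensions.
#' @export
mean_filter <- function(seq, W = 3) {
  stopifnot(inherits(seq, "landmark_sequence"))
  W <- as.integer(W)
  if (W %% 2L == 0L) stop("`W` must be odd", call. = FALSE)
  if (!W %in% c(3L, 5L)) stop("`W` must be 3 or 5", call. = FALSE)
  N <- n_frames(seq)
  if (W > N) stop("`W` exceeds the number of frames", call. = FALSE)
  d <- dim(seq$coords)
  mat <- matrix(seq$coords, nrow = d[1])  # frames x (points*3)
  landmark_sequence(
    array(moving_average_clipped(mat, W), d),
    seq$subject_id, seq$sample_rate_hz
  )
}

# Centered moving average of each column, window clipped at the ends.
# Implemented with cumulative sums: O(N) per column.
moving_average_clipped <- function(mat, W) {
  n <- nrow(mat)
  h <- (W - 1L) %/% 2L
  cs <- rbind(0, apply(mat, 2L, cumsum))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

#' Trim warm-up/wind-down frames and standardize sample length
#'
#' Removes `round(trim_seconds * sample_rate_hz)` frames from each end
#' (the subject settling in and the capture being stopped), then keeps
#' the first `retained_frames` frames so every sample has identical
#' length and the sliding-window layout is uniform. A sample whose
#' post-trim length falls short of `retained_frames` is flagged as
#' discarded rather than raising an error, mirroring how short captures
#' are dropped from a corpus.
#'
#' @param seq A [landmark_sequence()].
#' @param trim_seconds Seconds removed per end (default 5).
#' @param retained_frames Target length (default 2112).
#' @return A list with elements `sequence` (the standardized
#'   [landmark_sequence()], or `NULL` when discarded) and `report` (a
#'   one-row tibble: `subject_id`, `frames_in`, `frames_trimmed_each_end`,
#'   `frames_out`, `discarded`).
#' @export
trim_and_standardize <- function(seq, trim_seconds = 5,
                                 retained_frames = 2112) {
  stopifnot(inherits(seq, "landmark_sequence"))
  N <- n_frames(seq)
  trim <- as.integer(round(trim_seconds * seq$sample_rate_hz))
  retained_frames <- as.integer(retained_frames)
  kept <- N - 2L * trim
  discarded <- kept < retained_frames
  out <- NULL
  if (!discarded) {
    idx <- (trim + 1L):(trim + retained_frames)
    out <- landmark_sequence(
      seq$coords[idx, , , drop = FALSE], seq$subject_id, seq$sample_rate_hz
    )
  }
  list(
    sequence = out,
    report = tibble::tibble(
      subject_id = seq$subject_id,
      frames_in = N,
      frames_trimmed_each_end = trim,
      frames_out = if (discarded) 0L else retained_frames,
      discarded = discarded
    )
  )
}

#' Preprocess one capture: shift, filter, trim
#'
#' Applies the fixed preprocessing order — coordinate shift to the
#' face-local origin, mean filtering, then trimming/length
#' standardization — under a single [pipeline_config()].
#'
#' @param seq A [landmark_sequence()].
#' @param cfg A [pipeline_config()].
#' @return As [trim_and_standardize()], with `filter_window_used` added
#'   to the report.
#' @export
preprocess_sequence <- function(seq, cfg) {
  shifted <- shift_to_reference(seq, cfg$reference_point, cfg$shift_mode)
  filtered <- mean_filter(shifted, cfg$filter_window)
  res <- trim_and_standardize(filtered, cfg$trim_seconds, cfg$retained_frames)
  res$report$filter_window_used <- cfg$filter_window
  res
}

#' Preprocess a corpus of captures
#'
#' @param sequences List of [landmark_sequence()] objects.
#' @param cfg A [pipeline_config()].
#' @return List with `sequences` (the retained, standardized captures)
#'   and `report` (one tibble row per input capture, including the
#'   discarded ones).
#' @export
preprocess_cohort <- function(sequences, cfg) {
  res <- lapply(sequences, preprocess_sequence, cfg = cfg)
  report <- dplyr::bind_rows(lapply(res, `[[`, "report"))
  kept <- !report$discarded
  list(
    sequences = lapply(res[kept], `[[`, "sequence"),
    report = report
  )
}
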
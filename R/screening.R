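#' Inter-frame Euclidean displacements of every landmark
#'
#' For each landmark j and consecutive frame pair (i, i+1), the Euclidean
#' distance between the landmark's 3D positions, giving an
#' `(N - 1) x P` displacement matrix. This is the raw material for
#' mobility-based landmark screening.
#'
#' @param seq A [landmark_sequence()] with at least 2 frames.
#' @return Numeric matrix of dimension `(n_frames - 1) x n_points`, all
#'   entries >= 0, with the subject id attached as attribute
#'   `subject_id`.
#' @export
frame_displacements <- function(seq) {
  stopifnot(inherits(seq, "landmark_sequence"))
  N <- n_frames(seq)
  if (N < 2L) stop("at least 2 frames required", call. = FALSE)
  dx <- seq$coords[-1L, , 1, drop = FALSE] - seq$coords[-N, , 1, drop = FALSE]
  dy <- seq$coords[-1L, , 2, drop = FALSE] - seq$coords[-N, , 2, drop = FALSE]
  dz <- seq$coords[-1L, , 3, drop = FALSE] - seq$coords[-N, , 3, drop = FALSE]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  dim(d) <- c(N - 1L, n_points(seq))
  attr(d, "subject_id") <- seq$subject_id
  d
}

#' Per-landmark variance of inter-frame displacement
#'
#' Sample variance (denominator count - 1) of each column of a
#' displacement matrix: a landmark that moves erratically scores high, a
#' quasi-static one scores near zero.
#'
#' @param d Displacement matrix from [frame_displacements()].
#' @return Numeric vector of length `n_points`.
#' @export
point_variance <- function(d) {
  if (nrow(d) < 2L) {
    stop("at least 2 displacement rows required for a variance",
         call. = FALSE)
  }
  apply(d, 2L, stats::var)
}

#' Rank landmarks by corpus-mean displacement variance and select the top
#'
#' Stacks the per-sample variance vectors into a samples x points matrix,
#' averages each column across the corpus, ranks landmarks by descending
#' mean variance (ties broken by ascending landmark index) and selects
#' the first `top_points`.
#'
#' @param per_sample_sigmas List of per-landmark variance vectors, one
#'   per sample, all of equal length.
#' @param top_points Number of landmarks to retain.
#' @return A `screening_result`: list with `corpus_variance`
#'   (samples x points matrix), `mean_variance`, `ranking` (0-based
#'   landmark indices, descending mean variance) and `selected` (first
#'   `top_points` of `ranking`).
#' @export
rank_and_select <- function(per_sample_sigmas, top_points) {
  lens <- lengths(per_sample_sigmas)
  if (length(per_sample_sigmas) == 0L) {
    stop("no variance vectors supplied", call. = FALSE)
  }
  if (length(unique(lens)) != 1L) {
    stop("ragged input: per-sample variance vectors differ in length",
         call. = FALSE)
  }
  P <- lens[[1]]
  top_points <- as.integer(top_points)
  if (top_points < 1L || top_points > P) {
    stop("`top_points` must be in 1..", P, call. = FALSE)
  }
  Dv <- do.call(rbind, per_sample_sigmas)
  mean_variance <- colMeans(Dv)
  ranking <- order(-mean_variance, seq_len(P)) - 1L
  structure(
    list(
      corpus_variance = Dv,
      mean_variance = mean_variance,
      ranking = ranking,
      selected = ranking[seq_len(top_points)]
    ),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf(
    "<screening_result> %d samples x %d landmarks; %d selected (top mean displacement variance %.3g)\n",
    nrow(x$corpus_variance), ncol(x$corpus_variance), length(x$selected),
    x$mean_variance[x$ranking[1] + 1L]
  ))
  invisible(x)
}

#' Tidy a screening result
#'
#' @param x A `screening_result`.
#' @param ... Unused.
#' @return Tibble with one row per landmark: `point` (0-based),
#'   `mean_variance`, `rank` (1 = most mobile), `selected`.
#' @method tidy screening_result
#' @export
tidy.screening_result <- function(x, ...) {
  P <- length(x$mean_variance)
  rank <- integer(P)
  rank[x$ranking + 1L] <- seq_len(P)
  tibble::tibble(
    point = 0:(P - 1L),
    mean_variance = x$mean_variance,
    rank = rank,
    selected = (0:(P - 1L)) %in% x$selected
  )
}

#' Screen a preprocessed corpus for its most mobile landmarks
#'
#' Convenience wrapper: displacement matrices, per-landmark variances and
#' ranking/selection in one call.
#'
#' @param sequences List of preprocessed [landmark_sequence()] objects.
#' @param top_points Number of landmarks to retain.
#' @return A `screening_result` (see [rank_and_select()]).
#' @export
screen_points <- function(sequences, top_points) {
  sigmas <- lapply(sequences, function(s) point_variance(frame_displacements(s)))
  rank_and_select(sigmas, top_points)
}

#' Write / read a screening result as JSON
#'
#' Persists the ranking, mean variances and selected indices so feature
#' extraction is reproducible across processes. The per-sample variance
#' matrix is not serialized.
#'
#' @param x A `screening_result`.
#' @param path Output path.
#' @return `path` (write) or a `screening_result` without
#'   `corpus_variance` (read).
#' @export
write_screening <- function(x, path) {
  jsonlite::write_json(
    list(mean_variance = x$mean_variance, ranking = x$ranking,
         selected = x$selected),
    path, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' @rdname write_screening
#' @export
read_screening <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(corpus_variance = NULL,
         mean_variance = as.numeric(obj$mean_variance),
         ranking = as.integer(obj$ranking),
         selected = as.integer(obj$selected)),
    class = "screening_result"
  )
}
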
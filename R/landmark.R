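#' Construct a landmark sequence
#'
#' A `landmark_sequence` holds one subject's facial motion capture: an
#' `n_frames x n_points x 3` numeric array of 3D coordinates in meters,
#' sampled at a fixed rate (30 Hz for the depth-camera captures this
#' pipeline targets; a full-resolution capture tracks 1347 mesh points,
#' i.e. 4041 scalar series per subject).
#'
#' @param coords Numeric array of dimension `c(n_frames, n_points, 3)`.
#'   Axis order is fixed as (x, y, z). All entries must be finite.
#' @param subject_id Non-empty subject identifier.
#' @param sample_rate_hz Sampling rate in Hz (default 30).
#'
#' @return An object of class `landmark_sequence`.
#' @export
#' @examples
#' seq <- landmark_sequence(array(rnorm(2 * 4 * 3), c(2, 4, 3)), "s1")
#' n_frames(seq)
landmark_sequence <- function(coords, subject_id, sample_rate_hz = 30) {
  if (!is.character(subject_id) || length(subject_id) != 1L ||
      is.na(subject_id) || !nzchar(subject_id)) {
    stop("`subject_id` must be a single non-empty string", call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a positive number", call. = FALSE)
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("`coords` must be an n_frames x n_points x 3 array", call. = FALSE)
  }
  if (dim(coords)[1] < 1L || dim(coords)[2] < 1L) {
    stop("`coords` must contain at least one frame and one point",
         call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("`coords` must be finite everywhere", call. = FALSE)
  }
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  structure(
    list(subject_id = subject_id, coords = coords,
         sample_rate_hz = as.numeric(sample_rate_hz)),
    class = "landmark_sequence"
  )
}

#' @rdname landmark_sequence
#' @param x A `landmark_sequence`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "landmark_sequence"))
  dim(x$coords)[1]
}

#' @rdname landmark_sequence
#' @export
n_points <- function(x) {
  stopifnot(inherits(x, "landmark_sequence"))
  dim(x$coords)[2]
}

#' @export
print.landmark_sequence <- function(x, ...) {
  cat(sprintf(
    "<landmark_sequence> subject %s: %d frames x %d points @ %g Hz (%.1f s)\n",
    x$subject_id, n_frames(x), n_points(x), x$sample_rate_hz,
    n_frames(x) / x$sample_rate_hz
  ))
  invisible(x)
}

#' Convert a landmark sequence to a long tibble
#'
#' One row per (frame, point) with x/y/z columns; frame and point indices
#' are 0-based, matching the on-disk interchange format.
#'
#' @param x A `landmark_sequence`.
#' @param ... Unused.
#' @return A tibble with columns `frame`, `point`, `x`, `y`, `z`.
#' @method as_tibble landmark_sequence
#' @export
as_tibble.landmark_sequence <- function(x, ...) {
  d <- dim(x$coords)
  xs <- as.vector(x$coords[, , 1])
  ys <- as.vector(x$coords[, , 2])
  zs <- as.vector(x$coords[, , 3])
  tibble::tibble(
    frame = rep(0:(d[1] - 1L), times = d[2]),
    point = rep(0:(d[2] - 1L), each = d[1]),
    x = xs, y = ys, z = zs
  )
}

#' Read a landmark sequence from a long-format CSV
#'
#' The interchange format is a plain CSV with header `frame,point,x,y,z`,
#' 0-based frame and point indices, coordinates in meters. Every
#' (frame, point) pair in the full grid `0..N-1 x 0..P-1` must be present
#' exactly once; missing or duplicated pairs are an error, never imputed.
#'
#' @param path Path to the CSV file.
#' @param subject_id Subject identifier to attach; defaults to the file
#'   name without extension.
#' @param sample_rate_hz Sampling rate in Hz (default 30).
#' @return A [landmark_sequence()].
#' @export
read_landmark_table <- function(path, subject_id = NULL, sample_rate_hz = 30) {
  if (!file.exists(path)) {
    stop("landmark file not found: ", path, call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  tab <- utils::read.csv(path, colClasses = "numeric")
  required <- c("frame", "point", "x", "y", "z")
  if (!identical(names(tab)[seq_along(required)], required) ||
      ncol(tab) != 5L) {
    stop("malformed landmark header in ", path,
         " (expected frame,point,x,y,z)", call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("empty landmark table: ", path, call. = FALSE)
  if (anyNA(tab)) stop("non-numeric or missing value in ", path, call. = FALSE)
  nf <- max(tab$frame) + 1L
  np <- max(tab$point) + 1L
  if (nrow(tab) != nf * np) {
    stop("ragged frame/point coverage in ", path, ": expected ",
         nf * np, " rows for ", nf, " frames x ", np, " points, got ",
         nrow(tab), call. = FALSE)
  }
  idx <- tab$frame + nf * tab$point
  if (anyDuplicated(idx)) {
    stop("duplicate (frame, point) row in ", path, call. = FALSE)
  }
  if (min(tab$frame) != 0 || min(tab$point) != 0 ||
      any(tab$frame != floor(tab$frame)) || any(tab$point != floor(tab$point))) {
    stop("frame/point indices must be 0-based integers in ", path,
         call. = FALSE)
  }
  ord <- order(idx)
  coords <- array(0, c(nf, np, 3))
  coords[, , 1] <- tab$x[ord]
  coords[, , 2] <- tab$y[ord]
  coords[, , 3] <- tab$z[ord]
  landmark_sequence(coords, subject_id, sample_rate_hz)
}

#' Write a landmark sequence to the long-format CSV
#'
#' Inverse of [read_landmark_table()]: the written file reads back to a
#' sequence with identical coordinates.
#'
#' @param seq A [landmark_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(seq, path) {
  stopifnot(inherits(seq, "landmark_sequence"))
  tab <- as_tibble.landmark_sequence(seq)
  readr::write_csv(tab, path)
  invisible(path)
}
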
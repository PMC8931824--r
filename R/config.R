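#' Pipeline configuration
#'
#' Bundles every tunable of the landmark-to-score pipeline. Defaults
#' reproduce the full-scale design: 5 s (150 frames) trimmed from each
#' end, 2112 retained frames, 128-frame FFT windows sliding by 64 (so 32
#' windows per axis), the 100 most mobile landmarks, PCA to 80
#' components, four score-ordered strata split 8:2, and 10-fold CV.
#'
#' @param filter_window Mean-filter width `W`, 3 or 5.
#' @param trim_seconds Seconds trimmed from each end before length
#'   standardization (default 5, i.e. 150 frames at 30 Hz).
#' @param retained_frames Standardized per-sample frame count (default
#'   2112 = 66 * 32); shorter samples are discarded.
#' @param fft_window FFT window length in frames (default 128).
#' @param fft_hop Window slide in frames (default 64, i.e. 50% overlap).
#' @param top_points Number of landmarks retained by variance screening
#'   (default 100).
#' @param pca_components PCA output dimension (default 80).
#' @param n_strata Number of score-ordered strata for the train/validation
#'   split (default 4).
#' @param train_fraction Per-stratum training fraction (default 0.8).
#' @param cv_folds Folds for cross-validation (default 10).
#' @param algorithm Regression algorithm: `"lr"` (ordinary least squares),
#'   `"svr"` (linear-kernel epsilon-SVR), `"ridgecv"` (ridge with
#'   GCV-selected penalty), or `"br"` (Bayesian ridge).
#' @param reference_point 0-based index of the landmark used as the
#'   face-local origin (default 0).
#' @param shift_mode `"per_frame"` subtracts the reference landmark in
#'   every frame (removes head translation); `"first_frame"` subtracts its
#'   first-frame position only.
#' @param seed Integer seed controlling every stochastic step (splits,
#'   CV shuffles).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(filter_window = 3,
                            trim_seconds = 5,
                            retained_frames = 2112,
                            fft_window = 128,
                            fft_hop = 64,
                            top_points = 100,
                            pca_components = 80,
                            n_strata = 4,
                            train_fraction = 0.8,
                            cv_folds = 10,
                            algorithm = c("lr", "svr", "ridgecv", "br"),
                            reference_point = 0,
                            shift_mode = c("per_frame", "first_frame"),
                            seed = 1L) {
  algorithm <- match.arg(algorithm)
  shift_mode <- match.arg(shift_mode)
  cfg <- list(
    filter_window = as.integer(filter_window),
    trim_seconds = as.numeric(trim_seconds),
    retained_frames = as.integer(retained_frames),
    fft_window = as.integer(fft_window),
    fft_hop = as.integer(fft_hop),
    top_points = as.integer(top_points),
    pca_components = as.integer(pca_components),
    n_strata = as.integer(n_strata),
    train_fraction = as.numeric(train_fraction),
    cv_folds = as.integer(cv_folds),
    algorithm = algorithm,
    reference_point = as.integer(reference_point),
    shift_mode = shift_mode,
    seed = as.integer(seed)
  )
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (!cfg$filter_window %in% c(3L, 5L)) {
    stop("`filter_window` must be 3 or 5", call. = FALSE)
  }
  if (cfg$retained_frames < cfg$fft_window) {
    stop("`retained_frames` must be at least `fft_window`", call. = FALSE)
  }
  if ((cfg$retained_frames - cfg$fft_window) %% cfg$fft_hop != 0L) {
    stop("`fft_hop` must divide (retained_frames - fft_window); got ",
         cfg$retained_frames, " - ", cfg$fft_window, " = ",
         cfg$retained_frames - cfg$fft_window, " with hop ", cfg$fft_hop,
         call. = FALSE)
  }
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (cfg$fft_hop < 1L || cfg$fft_window < 2L || cfg$top_points < 1L ||
      cfg$pca_components < 1L || cfg$n_strata < 1L || cfg$cv_folds < 2L) {
    stop("invalid pipeline configuration value", call. = FALSE)
  }
  invisible(cfg)
}

#' Number of FFT windows per axis series under a configuration
#'
#' `(retained_frames - fft_window) / fft_hop + 1`; 32 at defaults.
#'
#' @param cfg A [pipeline_config()].
#' @return Integer window count.
#' @export
n_fft_windows <- function(cfg) {
  (cfg$retained_frames - cfg$fft_window) %/% cfg$fft_hop + 1L
}

#' Frames trimmed from each end under a configuration
#'
#' `round(trim_seconds * sample_rate_hz)`; 150 at 5 s / 30 Hz.
#'
#' @param cfg A [pipeline_config()].
#' @param sample_rate_hz Sampling rate of the capture.
#' @return Integer frame count trimmed per end.
#' @export
n_trim_frames <- function(cfg, sample_rate_hz = 30) {
  as.integer(round(cfg$trim_seconds * sample_rate_hz))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, x[[nm]]))
  invisible(x)
}

#' Read / write a pipeline configuration as flat key:value text
#'
#' The on-disk format is one `key: value` pair per line, keys matching
#' the [pipeline_config()] argument names; unknown keys are an error.
#' Lines starting with `#` are comments.
#'
#' @param path Path to the config file.
#' @return For `read_pipeline_config`, a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  if (any(lengths(kv) < 2L)) {
    stop("malformed config line (expected key: value)", call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = ":"), ""))
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- stats::setNames(as.list(vals), keys)
  numeric_keys <- setdiff(allowed, c("algorithm", "shift_mode"))
  for (k in intersect(names(args), numeric_keys)) {
    args[[k]] <- as.numeric(args[[k]])
  }
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @param cfg A [pipeline_config()] to serialize.
#' @export
write_pipeline_config <- function(cfg, path) {
  writeLines(sprintf("%s: %s", names(cfg),
                     vapply(cfg, as.character, "")), path)
  invisible(path)
}

#' Scaled-down configuration pair for quick runs
#'
#' Returns matched simulation and pipeline configurations in which every
#' pipeline constant is scaled down proportionally (64-frame windows with
#' 32-frame hop, 288 retained frames for 8 windows per axis, 60 landmarks
#' of which the 20 most mobile are kept) so a full end-to-end run
#' completes in seconds. All downstream counts derive from these values;
#' nothing is hard-coded to the full-scale constants.
#'
#' @param n_subjects Cohort size (default 20).
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [pipeline_config()].
#' @return List with elements `sim` ([simulation_config()]) and
#'   `pipeline` ([pipeline_config()]).
#' @export
toy_config <- function(n_subjects = 20, seed = 1L, ...) {
  list(
    sim = simulation_config(
      n_subjects = n_subjects, n_points = 60, n_frames = 600,
      n_signal_points = 30, seed = seed
    ),
    pipeline = pipeline_config(
      retained_frames = 288, fft_window = 64, fft_hop = 32,
      top_points = 20, pca_components = 10, seed = seed, ...
    )
  )
}
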
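#' Simulation configuration for synthetic cohorts
#'
#' Describes a synthetic study cohort: facial-landmark captures at 30 Hz
#' whose oscillation amplitudes are linearly coupled to five latent
#' decision-style traits, plus GDMS scores generated from the same
#' latent traits. The generator stands in for unreleased depth-camera
#' recordings, so its defaults mirror that study design: 240 subjects,
#' 1347 landmarks, captures comfortably longer than the 2112 frames the
#' pipeline retains, millimeter-scale motion, and score distributions
#' matching published young-adult GDMS norms (see [gdms_score_norms()]).
#'
#' @param n_subjects Cohort size (default 240).
#' @param n_points Landmarks per capture (default 1347; scaled-down runs
#'   use 60).
#' @param n_frames Frames per capture (default 2500, i.e. ~83 s at
#'   30 Hz).
#' @param sample_rate_hz Sampling rate (default 30).
#' @param n_signal_points Number of landmarks whose motion carries trait
#'   signal (default 100).
#' @param base_amplitude_m Baseline oscillation amplitude in meters
#'   (default 0.002; facial expressions move landmarks by millimeters).
#' @param coupling_strength Scale of the trait effect on oscillation
#'   amplitude; 0 plants no signal.
#' @param noise_sd_m SD of i.i.d. Gaussian measurement noise per
#'   coordinate (default 0.0003, sub-millimeter sensor jitter).
#' @param score_means,score_sds Named per-dimension means/SDs of the
#'   generated GDMS scores; defaults from [gdms_score_norms()].
#' @param seed Integer seed; all cohort- and subject-level randomness
#'   derives from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 240,
                              n_points = 1347,
                              n_frames = 2500,
                              sample_rate_hz = 30,
                              n_signal_points = 100,
                              base_amplitude_m = 0.002,
                              coupling_strength = 1,
                              noise_sd_m = 0.0003,
                              score_means = NULL,
                              score_sds = NULL,
                              seed = 1L) {
  norms <- gdms_score_norms()
  if (is.null(score_means)) {
    score_means <- stats::setNames(norms$mean, norms$dimension)
  }
  if (is.null(score_sds)) {
    score_sds <- stats::setNames(norms$sd, norms$dimension)
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_points = as.integer(n_points),
    n_frames = as.integer(n_frames),
    sample_rate_hz = as.numeric(sample_rate_hz),
    n_signal_points = as.integer(n_signal_points),
    base_amplitude_m = as.numeric(base_amplitude_m),
    coupling_strength = as.numeric(coupling_strength),
    noise_sd_m = as.numeric(noise_sd_m),
    score_means = score_means[gdms_dimensions()],
    score_sds = score_sds[gdms_dimensions()],
    seed = as.integer(seed)
  )
  if (cfg$n_signal_points > cfg$n_points) {
    stop("`n_signal_points` cannot exceed `n_points`", call. = FALSE)
  }
  if (any(is.na(cfg$score_means)) || any(is.na(cfg$score_sds)) ||
      any(cfg$score_sds <= 0)) {
    stop("`score_means`/`score_sds` must cover all five dimensions with ",
         "positive SDs", call. = FALSE)
  }
  if (cfg$coupling_strength < 0 || cfg$noise_sd_m < 0 ||
      cfg$base_amplitude_m < 0) {
    stop("amplitudes, coupling and noise must be non-negative", call. = FALSE)
  }
  if (cfg$n_subjects < 1L || cfg$n_frames < 2L || cfg$n_points < 1L) {
    stop("invalid cohort dimensions", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# Cohort-level design constants, deterministic given cfg$seed: the face
# template, which landmarks carry signal, their sinusoid frequencies /
# counts, and the per-landmark 5-vector trait weights. Holding these
# fixed across subjects makes the same spectral feature comparable
# across the cohort.
simulation_design <- function(cfg) {
  withr::with_seed(cfg$seed + 1000003L, {
    P <- cfg$n_points
    template <- cbind(
      x = stats::runif(P, -0.08, 0.08),
      y = stats::runif(P, -0.10, 0.10),
      z = stats::runif(P, 0.45, 0.55)
    )
    signal_points <- sort(sample(seq_len(P) - 1L, cfg$n_signal_points))
    n_sin <- sample(2:4, cfg$n_signal_points, replace = TRUE)
    # each sinusoid lives on a random unit-norm axis mixture
    sinusoids <- lapply(seq_len(cfg$n_signal_points), function(j) {
      k <- n_sin[j]
      ax <- matrix(stats::rnorm(3 * k), k, 3)
      ax <- ax / sqrt(rowSums(ax^2))
      list(freq = stats::runif(k, 0.5, 8), axis = ax)
    })
    # trait weights: signal landmarks are assigned to the five dimensions
    # in balanced rotation (equal planted signal per dimension) with
    # random sign; norm 0.25 keeps 1 + coupling*<w, z> almost surely
    # positive, preserving the linear amplitude coupling
    w <- matrix(0, cfg$n_signal_points, 5)
    if (cfg$n_signal_points > 0) {
      dim_of <- rep_len(1:5, cfg$n_signal_points)
      sgn <- sample(c(-1, 1), cfg$n_signal_points, replace = TRUE)
      w[cbind(seq_len(cfg$n_signal_points), dim_of)] <- 0.25 * sgn
    }
    list(template = template, signal_points = signal_points,
         sinusoids = sinusoids, weights = w)
  })
}

#' Latent trait draws for a cohort
#'
#' One standard-normal 5-vector per subject; the same latent values
#' drive both the generated GDMS scores and the planted motion signal.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @return Tibble with `subject_id` and columns `z_<dimension>`.
#' @export
simulate_traits <- function(n_subjects, seed = 1L) {
  z <- withr::with_seed(seed + 2000003L, {
    matrix(stats::rnorm(n_subjects * 5), n_subjects, 5)
  })
  colnames(z) <- paste0("z_", gdms_dimensions())
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%03d", seq_len(n_subjects))),
    tibble::as_tibble(z)
  )
}

#' Simulate one subject's capture
#'
#' Every landmark sits at its template position (plus a per-subject
#' shape offset) and rides a whole-head translation drift shared by all
#' landmarks. Signal landmarks additionally oscillate as a sum of 2-4
#' sinusoids with frequencies in (0.5, 8) Hz whose common amplitude is
#' `base_amplitude_m * max(0, 1 + coupling_strength * <w_j, z>)` — the
#' planted linear coupling between latent traits and motion spectra.
#' I.i.d. Gaussian measurement noise is added to every coordinate.
#'
#' @param traits One row of [simulate_traits()] (or a list with
#'   `subject_id` and the five `z_*` values).
#' @param cfg A [simulation_config()].
#' @param subject_seed Integer seed for this subject's private
#'   randomness (phases, shape offset, drift, noise). Derived from the
#'   cohort seed by [simulate_cohort()].
#' @return A [landmark_sequence()].
#' @export
simulate_sample <- function(traits, cfg, subject_seed) {
  design <- simulation_design(cfg)
  simulate_sample_impl(traits, cfg, design, subject_seed)
}

simulate_sample_impl <- function(traits, cfg, design, subject_seed) {
  z <- as.numeric(traits[paste0("z_", gdms_dimensions())])
  N <- cfg$n_frames
  P <- cfg$n_points
  t <- (seq_len(N) - 1L) / cfg$sample_rate_hz
  withr::with_seed(as.integer(subject_seed), {
    coords <- array(0, c(N, P, 3))
    shape <- matrix(stats::rnorm(P * 3, sd = 5e-4), P, 3)
    base <- design$template + shape
    # shared head drift: two slow sinusoids per axis, cm-scale
    drift <- vapply(1:3, function(m) {
      f <- stats::runif(2, 0.02, 0.2)
      a <- stats::runif(2, 0.002, 0.008)
      ph <- stats::runif(2, 0, 2 * pi)
      a[1] * sin(2 * pi * f[1] * t + ph[1]) +
        a[2] * sin(2 * pi * f[2] * t + ph[2])
    }, numeric(N))
    for (m in 1:3) {
      coords[, , m] <- matrix(base[, m], N, P, byrow = TRUE) + drift[, m]
    }
    amp_gain <- pmax(0, 1 + cfg$coupling_strength * as.vector(design$weights %*% z))
    for (j in seq_along(design$signal_points)) {
      p <- design$signal_points[j] + 1L
      s <- design$sinusoids[[j]]
      a <- cfg$base_amplitude_m * amp_gain[j]
      for (k in seq_along(s$freq)) {
        ph <- stats::runif(1, 0, 2 * pi)
        osc <- a * sin(2 * pi * s$freq[k] * t + ph)
        for (m in 1:3) {
          coords[, p, m] <- coords[, p, m] + s$axis[k, m] * osc
        }
      }
    }
    if (cfg$noise_sd_m > 0) {
      coords <- coords + array(stats::rnorm(length(coords), sd = cfg$noise_sd_m),
                               dim(coords))
    }
    landmark_sequence(coords, traits$subject_id, cfg$sample_rate_hz)
  })
}

#' Simulate a full cohort: captures, GDMS scores, latent traits
#'
#' Draws latent traits, generates one capture per subject via
#' [simulate_sample()] (each subject gets an independent sub-seed), and
#' produces GDMS scores from the same latent traits:
#' `round(mean_d + sd_d * z_d)` clipped to the 5..25 scale range.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `style_cohort` with `sequences` (list of
#'   [landmark_sequence()]), `scores` (tibble), `traits` (tibble) and
#'   `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  traits <- simulate_traits(cfg$n_subjects, cfg$seed)
  design <- simulation_design(cfg)
  subject_seeds <- cfg$seed + 3000017L + 7L * seq_len(cfg$n_subjects)
  sequences <- lapply(seq_len(cfg$n_subjects), function(i) {
    simulate_sample_impl(traits[i, ], cfg, design, subject_seeds[i])
  })
  scores <- simulate_scores(traits, cfg)
  structure(
    list(sequences = sequences, scores = scores, traits = traits,
         config = cfg),
    class = "style_cohort"
  )
}

#' @rdname simulate_cohort
#' @param traits Tibble from [simulate_traits()].
#' @export
simulate_scores <- function(traits, cfg) {
  out <- tibble::tibble(subject_id = traits$subject_id)
  for (d in gdms_dimensions()) {
    raw <- cfg$score_means[[d]] + cfg$score_sds[[d]] * traits[[paste0("z_", d)]]
    out[[d]] <- as.integer(pmin(25, pmax(5, round(raw))))
  }
  out
}

#' @export
print.style_cohort <- function(x, ...) {
  cat(sprintf(
    "<style_cohort> %d subjects, %d landmarks x %d frames @ %g Hz (coupling %.2g, noise sd %.2g m)\n",
    length(x$sequences), x$config$n_points, x$config$n_frames,
    x$config$sample_rate_hz, x$config$coupling_strength, x$config$noise_sd_m
  ))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' One landmark CSV per subject (`<subject_id>.csv`), a `scores.csv`,
#' and a `traits.csv` holding the latent ground truth for validation.
#'
#' @param cohort A `style_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$sequences) {
    write_landmark_table(s, file.path(dir, paste0(s$subject_id, ".csv")))
  }
  write_gdms_scores(cohort$scores, file.path(dir, "scores.csv"))
  readr::write_csv(cohort$traits, file.path(dir, "traits.csv"))
  invisible(dir)
}
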
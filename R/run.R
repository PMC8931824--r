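#' Fit and evaluate one dimension on a fixed stratified hold-out
#'
#' Draws the score-stratified train/validation split for one dimension,
#' fits the PCA + regression pipeline on the training rows and evaluates
#' Pearson r and RMSE on the validation rows.
#'
#' @param features A `feature_matrix` for the whole corpus.
#' @param scores Score tibble covering the corpus subjects.
#' @param dimension One of [gdms_dimensions()].
#' @param cfg A [pipeline_config()].
#' @return List with `metrics` (one-row tibble), `model` (the fitted
#'   `style_model`), `plan` (the `split_plan`) and `predictions` (tibble
#'   of validation subject, actual, predicted).
#' @export
evaluate_holdout <- function(features, scores, dimension, cfg) {
  ids <- features$subject_ids
  scores <- scores[match(ids, scores$subject_id), , drop = FALSE]
  plan <- stratified_split(scores, dimension, cfg$n_strata,
                           cfg$train_fraction, cfg$seed)
  tr <- ids %in% plan$train_ids
  sub <- function(keep) structure(
    list(values = features$values[keep, , drop = FALSE],
         subject_ids = ids[keep], layout = features$layout),
    class = "feature_matrix"
  )
  y <- scores[[dimension]]
  model <- fit_pipeline(sub(tr), y[tr], cfg)
  pred <- predict(model, sub(!tr))
  metrics <- dplyr::bind_cols(
    tibble::tibble(
      dimension = dimension, algorithm = cfg$algorithm,
      filter_window = cfg$filter_window
    ),
    evaluate_predictions(pred, y[!tr]),
    tibble::tibble(
      n_train = sum(tr), n_val = sum(!tr),
      explained_variance = model$explained_variance
    )
  )
  list(
    metrics = metrics, model = model, plan = plan,
    predictions = tibble::tibble(
      subject_id = ids[!tr], dimension = dimension,
      actual = y[!tr], predicted = unname(pred)
    )
  )
}

#' Run the full recognition pipeline on a cohort
#'
#' Orchestrates preprocess, landmark screening, spectral feature
#' extraction, per-dimension stratified fitting and validation for every
#' requested algorithm and mean-filter width, with optional k-fold
#' cross-validation and split-half reliability.
#'
#' @param cohort A `style_cohort` from [simulate_cohort()], or a list
#'   with elements `sequences` (list of [landmark_sequence()]) and
#'   `scores` (tibble).
#' @param cfg A [pipeline_config()]; its `filter_window` and `algorithm`
#'   are overridden by the two arguments below.
#' @param algorithms Algorithms to run (default all four).
#' @param filter_windows Mean-filter widths to run (default both 3
#'   and 5).
#' @param cv Also run k-fold cross-validation per dimension/algorithm
#'   (default `FALSE`).
#' @param reliability Also compute odd/even split-half reliability
#'   (default `FALSE`).
#' @return A `style_report`: list with `results` (tidy metrics tibble),
#'   `reliability`, `predictions`, `preprocess` (per-capture report),
#'   `screening` (per filter width) and `manifest`.
#' @export
run_style_pipeline <- function(cohort, cfg,
                               algorithms = c("lr", "svr", "ridgecv", "br"),
                               filter_windows = c(3, 5),
                               cv = FALSE, reliability = FALSE) {
  t0 <- Sys.time()
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  sequences <- cohort$sequences
  scores <- cohort$scores
  results <- list(); rel <- list(); preds <- list()
  pre_reports <- list(); screenings <- list()
  for (W in filter_windows) {
    cfg_w <- cfg
    cfg_w$filter_window <- as.integer(W)
    validate_pipeline_config(cfg_w)
    pre <- preprocess_cohort(sequences, cfg_w)
    pre_reports[[as.character(W)]] <- pre$report
    if (length(pre$sequences) == 0L) {
      stop("all captures discarded during preprocessing", call. = FALSE)
    }
    screening <- screen_points(pre$sequences, cfg_w$top_points)
    screenings[[as.character(W)]] <- screening
    features <- extract_features(pre$sequences, screening, cfg_w)
    kept_scores <- scores[match(features$subject_ids, scores$subject_id), ]
    for (alg in algorithms) {
      cfg_a <- cfg_w
      cfg_a$algorithm <- alg
      for (dim in gdms_dimensions()) {
        res <- evaluate_holdout(features, kept_scores, dim, cfg_a)
        row <- res$metrics
        if (cv) {
          cv_tab <- crossvalidate(features, kept_scores[[dim]], cfg_a)
          row$cv_r_mean <- mean(cv_tab$pearson_r)
          row$cv_rmse_mean <- mean(cv_tab$rmse)
        }
        results[[length(results) + 1L]] <- row
        preds[[length(preds) + 1L]] <- dplyr::mutate(
          res$predictions, algorithm = alg, filter_window = as.integer(W)
        )
      }
      if (reliability) {
        rel_tab <- split_half_reliability(pre$sequences, kept_scores,
                                          screening, cfg_a)
        rel_tab$filter_window <- as.integer(W)
        rel[[length(rel) + 1L]] <- rel_tab
      }
    }
  }
  results <- dplyr::bind_rows(results)
  pre_report <- dplyr::bind_rows(pre_reports, .id = "filter_window")
  manifest <- list(
    package_version = as.character(utils::packageVersion("facestyle")),
    seed = cfg$seed,
    config = unclass(cfg),
    algorithms = algorithms,
    filter_windows = filter_windows,
    n_subjects_in = length(sequences),
    n_subjects_kept = sum(!pre_reports[[1]]$discarded),
    n_discarded = sum(pre_reports[[1]]$discarded),
    n_features = length(feature_layout(
      screenings[[1]]$selected, cfg
    )),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  structure(
    list(
      results = results,
      reliability = if (length(rel)) dplyr::bind_rows(rel) else NULL,
      predictions = dplyr::bind_rows(preds),
      preprocess = pre_report,
      screening = screenings,
      manifest = manifest
    ),
    class = "style_report"
  )
}

#' @export
print.style_report <- function(x, ...) {
  cat(sprintf(
    "<style_report> %d subjects (%d discarded), %d result rows\n",
    x$manifest$n_subjects_in, x$manifest$n_discarded, nrow(x$results)
  ))
  print(x$results, n = 10)
  invisible(x)
}

#' Tidy / glance methods for pipeline reports
#'
#' `tidy()` returns the long metrics table (one row per dimension x
#' algorithm x filter width, with split-half reliability joined in when
#' computed). `glance()` summarises each algorithm x filter width with
#' the mean and SD of validation Pearson r across the five dimensions —
#' the margins a results table for this design reports.
#'
#' @param x A `style_report`.
#' @param ... Unused.
#' @method tidy style_report
#' @export
tidy.style_report <- function(x, ...) {
  out <- x$results
  if (!is.null(x$reliability)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(x$reliability, -dplyr::any_of("n_val")),
      by = c("dimension", "algorithm", "filter_window")
    )
  }
  out
}

#' @rdname tidy.style_report
#' @method glance style_report
#' @export
glance.style_report <- function(x, ...) {
  x$results |>
    dplyr::group_by(.data$algorithm, .data$filter_window) |>
    dplyr::summarise(
      r_mean = mean(.data$pearson_r),
      r_sd = stats::sd(.data$pearson_r),
      rmse_mean = mean(.data$rmse),
      .groups = "drop"
    )
}

#' Write an evaluation report as a tidy TSV
#'
#' Long format: dimension, algorithm, filter_window, metric, value.
#'
#' @param report A `style_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  long <- tidy.style_report(report) |>
    tidyr::pivot_longer(
      cols = -c("dimension", "algorithm", "filter_window"),
      names_to = "metric", values_to = "value"
    )
  readr::write_tsv(long, path)
  invisible(path)
}
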
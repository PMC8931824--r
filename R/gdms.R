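#' The five GDMS dimensions
#'
#' Canonical ordering of the General Decision-Making Style (GDMS)
#' dimensions used throughout the package. The GDMS is a 25-item
#' questionnaire with five scales; each dimension score is the unweighted
#' sum of five 1-5 Likert items, so scores range over 5..25.
#'
#' @return Character vector of the five dimension names.
#' @export
gdms_dimensions <- function() {
  c("spontaneous", "avoidant", "rational", "dependent", "intuition")
}

#' Default GDMS score distribution for a young-adult cohort
#'
#' Per-dimension means and standard deviations used to calibrate the
#' synthetic-score generator. The defaults pool published gender-specific
#' norms for a young-adult sample (130 women, 110 men) via the law of
#' total variance, so the pooled SD includes both within- and
#' between-gender components. Gender-specific rows are available for
#' overriding the simulator defaults.
#'
#' @param by_gender If `TRUE`, return the gender-specific norms instead of
#'   the pooled ones.
#' @return A tibble with columns `dimension`, `mean`, `sd` (and `gender`
#'   when `by_gender = TRUE`).
#' @export
gdms_score_norms <- function(by_gender = FALSE) {
  norms <- tibble::tribble(
    ~gender,  ~dimension,    ~mean, ~sd,
    "female", "spontaneous", 17.67, 4.60,
    "female", "avoidant",    18.06, 2.61,
    "female", "rational",    16.71, 4.33,
    "female", "dependent",   15.21, 4.02,
    "female", "intuition",   18.49, 3.53,
    "male",   "spontaneous", 15.66, 4.52,
    "male",   "avoidant",    19.90, 3.13,
    "male",   "rational",    15.20, 4.12,
    "male",   "dependent",   17.00, 4.86,
    "male",   "intuition",   17.05, 3.62
  )
  if (by_gender) {
    return(norms[order(match(norms$dimension, gdms_dimensions())), ])
  }
  w <- c(female = 130, male = 110)
  norms |>
    dplyr::mutate(w = w[.data$gender]) |>
    dplyr::group_by(.data$dimension) |>
    dplyr::summarise(
      m = sum(.data$w * .data$mean) / sum(.data$w),
      # law of total variance: within-gender + between-gender components
      v = sum(.data$w * .data$sd^2) / sum(.data$w) +
        sum(.data$w * (.data$mean - sum(.data$w * .data$mean) / sum(.data$w))^2) /
          sum(.data$w),
      .groups = "drop"
    ) |>
    dplyr::transmute(
      dimension = .data$dimension, mean = .data$m, sd = sqrt(.data$v)
    ) |>
    dplyr::arrange(match(.data$dimension, gdms_dimensions()))
}

#' Read GDMS dimension scores from CSV
#'
#' Expects a header with `subject_id` plus the five dimension columns
#' (any column order); extra columns (e.g. `gender`) are carried through.
#'
#' @param path Path to the scores CSV.
#' @return A tibble with one row per subject, integer dimension scores.
#' @export
read_gdms_scores <- function(path) {
  if (!file.exists(path)) stop("scores file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("subject_id", gdms_dimensions()), names(tab))
  if (length(missing) > 0L) {
    stop("scores file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$subject_id)) {
    stop("duplicate subject_id in ", path, call. = FALSE)
  }
  for (d in gdms_dimensions()) {
    v <- tab[[d]]
    if (!is.numeric(v) || anyNA(v) || any(v != floor(v))) {
      stop("non-integer score in column '", d, "' of ", path, call. = FALSE)
    }
    tab[[d]] <- as.integer(v)
  }
  tab$subject_id <- as.character(tab$subject_id)
  tibble::as_tibble(tab[, c("subject_id", gdms_dimensions(),
                            setdiff(names(tab),
                                    c("subject_id", gdms_dimensions())))])
}

#' Write GDMS scores to CSV
#'
#' @param scores Tibble as returned by [read_gdms_scores()] or
#'   [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gdms_scores <- function(scores, path) {
  missing <- setdiff(c("subject_id", gdms_dimensions()), names(scores))
  if (length(missing) > 0L) {
    stop("scores table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(scores, path)
  invisible(path)
}

#' Score the 25 GDMS items into five dimension scores
#'
#' Each dimension score is the unweighted sum of its five 1-5 Likert
#' items, giving the usual 5..25 range. The item-to-dimension key is not
#' standardized across translations, so it is an explicit argument: a
#' named list mapping each dimension to five 1-based item indices that
#' together partition 1..25.
#'
#' @param items Integer vector of 25 item responses, each in 1..5.
#' @param key Named list: for each of the five dimensions, the five
#'   1-based item indices belonging to it. Default assigns items in
#'   consecutive blocks of five, in [gdms_dimensions()] order.
#' @return Named integer vector of the five dimension scores.
#' @export
#' @examples
#' score_gdms_items(rep(3L, 25))
score_gdms_items <- function(items, key = NULL) {
  if (length(items) != 25L) stop("exactly 25 items required", call. = FALSE)
  if (!is.numeric(items) || anyNA(items) || any(items != floor(items)) ||
      any(items < 1 | items > 5)) {
    stop("items must be integers in 1..5", call. = FALSE)
  }
  if (is.null(key)) {
    key <- stats::setNames(
      lapply(0:4, function(b) b * 5L + 1:5), gdms_dimensions()
    )
  }
  if (!setequal(names(key), gdms_dimensions()) ||
      !identical(sort(as.integer(unlist(key, use.names = FALSE))), 1:25) ||
      any(lengths(key) != 5L)) {
    stop("`key` must partition items 1..25 into five blocks of five, ",
         "one per dimension", call. = FALSE)
  }
  vapply(gdms_dimensions(),
         function(d) as.integer(sum(items[key[[d]]])),
         integer(1))
}
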
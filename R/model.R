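#' Score-stratified train/validation split
#'
#' Orders subjects by their score on one GDMS dimension from high to
#' low, cuts the ordering into `n_strata` contiguous blocks (quartiles at
#' defaults; any remainder goes to the highest-score blocks), and draws
#' `round(train_fraction * block size)` training subjects uniformly at
#' random within each block. This keeps every score band represented in
#' both sets: 240 subjects at defaults give four strata of 60 with 48
#' train / 12 validation each, 192 / 48 overall.
#'
#' @param scores Tibble with `subject_id` and the five dimension columns
#'   (as from [read_gdms_scores()] or [simulate_cohort()]).
#' @param dimension One of [gdms_dimensions()].
#' @param n_strata Number of contiguous score-ordered blocks.
#' @param train_fraction Per-stratum training fraction.
#' @param seed Integer seed for the within-stratum draws.
#' @return A `split_plan`: list with `dimension`, `strata` (list of
#'   subject-id vectors, highest scores first), `train_ids`, `val_ids`.
#' @export
stratified_split <- function(scores, dimension, n_strata = 4,
                             train_fraction = 0.8, seed = 1L) {
  dimension <- match.arg(dimension, gdms_dimensions())
  if (nrow(scores) == 0L) stop("no score records supplied", call. = FALSE)
  n <- nrow(scores)
  n_strata <- as.integer(n_strata)
  if (n < n_strata) stop("fewer records than strata", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  ord <- order(-scores[[dimension]], scores$subject_id)
  ids <- scores$subject_id[ord]
  base <- n %/% n_strata
  extra <- n %% n_strata
  sizes <- rep(base, n_strata) + c(rep(1L, extra), rep(0L, n_strata - extra))
  bounds <- cumsum(c(0L, sizes))
  strata <- lapply(seq_len(n_strata), function(k) {
    ids[(bounds[k] + 1L):bounds[k + 1L]]
  })
  draws <- withr::with_seed(seed, {
    lapply(strata, function(s) {
      n_tr <- as.integer(round(train_fraction * length(s)))
      sort(sample(s, n_tr))
    })
  })
  train_ids <- unlist(draws, use.names = FALSE)
  structure(
    list(
      dimension = dimension,
      strata = strata,
      train_ids = train_ids,
      val_ids = setdiff(ids, train_ids)
    ),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "<split_plan> %s: %d strata (%s), %d train / %d validation\n",
    x$dimension, length(x$strata),
    paste(lengths(x$strata), collapse = "/"),
    length(x$train_ids), length(x$val_ids)
  ))
  invisible(x)
}

#' @rdname stratified_split
#' @param x A `split_plan`.
#' @param ... Unused.
#' @method tidy split_plan
#' @export
tidy.split_plan <- function(x, ...) {
  tibble::tibble(
    subject_id = unlist(x$strata, use.names = FALSE),
    stratum = rep(seq_along(x$strata), lengths(x$strata)),
    set = ifelse(unlist(x$strata, use.names = FALSE) %in% x$train_ids,
                 "train", "validation")
  )
}

# ---- regressors -----------------------------------------------------------

# Ridge regression on centered data with penalty chosen by generalized
# cross-validation over a logarithmic grid, computed from one SVD.
fit_ridge_gcv <- function(X, y, lambdas = 10^seq(-3, 3, length.out = 13)) {
  n <- nrow(X)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - ybar
  sv <- svd(Xc)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, yc)
  gcv <- vapply(lambdas, function(l) {
    shrink <- d2 / (d2 + l)
    fit <- sv$u %*% (shrink * uty)
    rss <- sum((yc - fit)^2)
    df <- sum(shrink)
    (rss / n) / (1 - df / n)^2
  }, numeric(1))
  l <- lambdas[which.min(gcv)]
  coef <- sv$v %*% (sv$d / (d2 + l) * uty)
  list(coef = as.vector(coef), intercept = ybar - sum(xbar * coef),
       lambda = l, gcv = stats::setNames(gcv, lambdas))
}

# Bayesian linear ridge with conjugate Gamma hyperpriors on the noise
# precision (alpha) and weight precision (lambda), estimated by evidence
# maximization (iterative MacKay updates on the SVD of the centered
# design).
fit_bayes_ridge <- function(X, y, max_iter = 300, tol = 1e-6,
                            a1 = 1e-6, a2 = 1e-6, l1 = 1e-6, l2 = 1e-6) {
  n <- nrow(X)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - ybar
  sv <- svd(Xc)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, yc)
  vy <- stats::var(yc)
  alpha <- if (vy > 0) 1 / vy else 1
  lambda <- 1
  coef_old <- rep(Inf, ncol(X))
  for (it in seq_len(max_iter)) {
    # posterior mean in the SVD basis
    w <- sv$d * uty * (alpha / (lambda + alpha * d2))
    coef <- as.vector(sv$v %*% w)
    gamma <- sum(alpha * d2 / (lambda + alpha * d2))
    rss <- sum((yc - sv$u %*% (sv$d * w))^2)
    lambda <- (gamma + 2 * l1) / (sum(coef^2) + 2 * l2)
    alpha <- (n - gamma + 2 * a1) / (rss + 2 * a2)
    if (sum(abs(coef - coef_old)) < tol) break
    coef_old <- coef
  }
  list(coef = coef, intercept = ybar - sum(xbar * coef),
       alpha = alpha, lambda = lambda, n_iter = it)
}

fit_regressor <- function(Z, y, algorithm) {
  switch(
    algorithm,
    lr = {
      fit <- stats::lm.fit(cbind(1, Z), y)
      co <- fit$coefficients
      co[is.na(co)] <- 0
      list(kind = "linear", coef = co[-1], intercept = co[1])
    },
    ridgecv = {
      fit <- fit_ridge_gcv(Z, y)
      c(list(kind = "linear"), fit)
    },
    br = {
      fit <- fit_bayes_ridge(Z, y)
      c(list(kind = "linear"), fit)
    },
    svr = {
      fit <- e1071::svm(
        x = Z, y = y, type = "eps-regression", kernel = "linear",
        cost = 1, epsilon = 0.1 * stats::sd(y), scale = TRUE
      )
      list(kind = "svm", model = fit)
    },
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

predict_regressor <- function(reg, Z) {
  if (reg$kind == "linear") {
    as.vector(Z %*% reg$coef + reg$intercept)
  } else {
    as.vector(stats::predict(reg$model, Z))
  }
}

#' Fit the PCA + regression pipeline for one dimension
#'
#' Centers the training features, fits a PCA basis on the training rows
#' only, projects to `pca_components` dimensions, and fits the
#' configured regressor on the component scores. The achieved PCA
#' explained-variance fraction is recorded and a warning is emitted when
#' it falls below 0.98, the fraction the full-scale reduction
#' (19200 -> 80 components) is designed to retain.
#'
#' @param features A `feature_matrix` (training rows only) or bare
#'   numeric matrix.
#' @param scores Numeric vector of training scores, one per row.
#' @param cfg A [pipeline_config()]; `cfg$algorithm` selects the
#'   regressor.
#' @return A `style_model`: PCA center/basis, regressor parameters,
#'   explained-variance fraction, the training subject ids and a config
#'   snapshot.
#' @export
fit_pipeline <- function(features, scores, cfg) {
  X <- if (inherits(features, "feature_matrix")) features$values else features
  layout <- if (inherits(features, "feature_matrix")) features$layout else colnames(X)
  if (nrow(X) < 2L) stop("at least 2 training rows required", call. = FALSE)
  if (nrow(X) != length(scores)) {
    stop("features and scores disagree in length", call. = FALSE)
  }
  k <- min(cfg$pca_components, nrow(X) - 1L, ncol(X))
  if (cfg$pca_components > k) {
    stop("`pca_components` (", cfg$pca_components,
         ") exceeds what ", nrow(X), " samples x ", ncol(X),
         " features support (max ", k, ")", call. = FALSE)
  }
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  explained <- sum(pca$sdev[seq_len(k)]^2) / sum(pca$sdev^2)
  if (explained < 0.98) {
    warning(sprintf(
      "PCA retains %.1f%% of feature variance (< 98%%) with %d components",
      100 * explained, k
    ), call. = FALSE)
  }
  Z <- pca$x[, seq_len(k), drop = FALSE]
  reg <- fit_regressor(Z, scores, cfg$algorithm)
  structure(
    list(
      algorithm = cfg$algorithm,
      pca_mean = pca$center,
      pca_basis = pca$rotation[, seq_len(k), drop = FALSE],
      explained_variance = explained,
      regressor = reg,
      layout = layout,
      fitted_on = rownames(X),
      config = cfg
    ),
    class = "style_model"
  )
}

#' @export
print.style_model <- function(x, ...) {
  cat(sprintf(
    "<style_model> %s on %d components (%.1f%% variance), %d training samples\n",
    x$algorithm, ncol(x$pca_basis), 100 * x$explained_variance,
    length(x$fitted_on)
  ))
  invisible(x)
}

#' Predict scores from a fitted pipeline
#'
#' Applies the stored centering, PCA projection and regression; a pure
#' function of the feature rows.
#'
#' @param object A `style_model`.
#' @param features A `feature_matrix` or bare numeric matrix whose
#'   columns match the model's fitted layout.
#' @param ... Unused.
#' @return Numeric vector of predicted scores, named by subject id when
#'   available.
#' @export
predict.style_model <- function(object, features, ...) {
  X <- if (inherits(features, "feature_matrix")) features$values else features
  layout <- if (inherits(features, "feature_matrix")) features$layout else colnames(X)
  if (ncol(X) != nrow(object$pca_basis)) {
    stop("feature layout does not match the fitted model: ", ncol(X),
         " columns vs ", nrow(object$pca_basis), " fitted features",
         call. = FALSE)
  }
  if (!is.null(layout) && !is.null(object$layout) &&
      !identical(as.character(layout), as.character(object$layout))) {
    stop("feature layout does not match the fitted model", call. = FALSE)
  }
  Z <- sweep(X, 2L, object$pca_mean) %*% object$pca_basis
  p <- predict_regressor(object$regressor, Z)
  names(p) <- rownames(X)
  p
}

#' Tidy / glance methods for fitted pipelines
#'
#' @param x,object A `style_model`.
#' @param ... Unused.
#' @return `tidy()`: one row per principal component with its regression
#'   weight (linear regressors only). `glance()`: one-row model summary.
#' @method tidy style_model
#' @export
tidy.style_model <- function(x, ...) {
  if (x$regressor$kind != "linear") {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(
    term = c("(Intercept)", paste0("PC", seq_along(x$regressor$coef))),
    estimate = c(x$regressor$intercept, x$regressor$coef)
  )
}

#' @rdname tidy.style_model
#' @method glance style_model
#' @export
glance.style_model <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    n_components = ncol(x$pca_basis),
    explained_variance = x$explained_variance,
    n_train = length(x$fitted_on)
  )
}

#' Pearson correlation and RMSE between predicted and actual scores
#'
#' @param pred Numeric vector of predictions.
#' @param actual Numeric vector of observed scores, same length (>= 3).
#' @return One-row tibble with `pearson_r` and `rmse`. When `actual` is
#'   constant the correlation is undefined: `pearson_r` is `NA` with a
#'   warning.
#' @export
evaluate_predictions <- function(pred, actual) {
  if (length(pred) != length(actual)) {
    stop("prediction and actual vectors differ in length", call. = FALSE)
  }
  if (length(pred) < 3L) stop("at least 3 pairs required", call. = FALSE)
  r <- if (stats::sd(actual) == 0) {
    warning("actual scores are constant; Pearson r is undefined",
            call. = FALSE)
    NA_real_
  } else {
    stats::cor(pred, actual)
  }
  tibble::tibble(
    pearson_r = r,
    rmse = sqrt(mean((pred - actual)^2))
  )
}

#' k-fold cross-validation of the full pipeline
#'
#' Shuffles the samples with the configured seed, cuts them into
#' `cv_folds` near-equal folds, and for each fold fits the whole
#' pipeline (PCA included) on the remaining folds and evaluates on the
#' held-out one.
#'
#' @param features A `feature_matrix` for the whole corpus.
#' @param scores Numeric score vector aligned with the feature rows.
#' @param cfg A [pipeline_config()].
#' @return Tibble with one row per fold: `fold`, `n_val`, `pearson_r`,
#'   `rmse`.
#' @export
crossvalidate <- function(features, scores, cfg) {
  X <- if (inherits(features, "feature_matrix")) features else
    structure(list(values = features, subject_ids = rownames(features),
                   layout = colnames(features)), class = "feature_matrix")
  n <- nrow(X$values)
  k <- cfg$cv_folds
  if (n < k) stop("fewer samples than folds", call. = FALSE)
  fold_of <- withr::with_seed(cfg$seed, {
    sample(rep(seq_len(k), length.out = n))
  })
  purrr::map_dfr(seq_len(k), function(f) {
    tr <- fold_of != f
    m <- fit_pipeline(
      structure(list(values = X$values[tr, , drop = FALSE],
                     subject_ids = X$subject_ids[tr], layout = X$layout),
                class = "feature_matrix"),
      scores[tr], cfg
    )
    p <- predict(m, structure(
      list(values = X$values[!tr, , drop = FALSE],
           subject_ids = X$subject_ids[!tr], layout = X$layout),
      class = "feature_matrix"
    ))
    dplyr::bind_cols(
      tibble::tibble(fold = f, n_val = sum(!tr)),
      evaluate_predictions(p, scores[!tr])
    )
  })
}
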
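make_scores <- function(n, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      spontaneous = sample(5:25, n, replace = TRUE),
      avoidant = sample(5:25, n, replace = TRUE),
      rational = sample(5:25, n, replace = TRUE),
      dependent = sample(5:25, n, replace = TRUE),
      intuition = sample(5:25, n, replace = TRUE)
    )
  })
}

test_that("stratified split reproduces the 240 -> 4x60 -> 192/48 design", {
  scores <- make_scores(240)
  plan <- stratified_split(scores, "spontaneous", 4, 0.8, seed = 3)
  expect_equal(lengths(plan$strata), rep(60L, 4))
  expect_length(plan$train_ids, 192L)
  expect_length(plan$val_ids, 48L)
  td <- tidy(plan)
  per <- dplyr::count(td, stratum, set)
  expect_equal(per$n[per$set == "train"], rep(48L, 4))
  expect_equal(per$n[per$set == "validation"], rep(12L, 4))
  # strata are contiguous score blocks, high scores first
  s <- scores$spontaneous[match(td$subject_id, scores$subject_id)]
  expect_true(min(s[td$stratum == 1]) >= max(s[td$stratum == 4]))
  expect_true(!anyDuplicated(c(plan$train_ids, plan$val_ids)))
})

test_that("stratified split is seed-deterministic with stable strata", {
  scores <- make_scores(50)
  a <- stratified_split(scores, "rational", 4, 0.8, seed = 7)
  b <- stratified_split(scores, "rational", 4, 0.8, seed = 7)
  c <- stratified_split(scores, "rational", 4, 0.8, seed = 8)
  expect_identical(a$train_ids, b$train_ids)
  expect_identical(a$strata, c$strata)  # strata do not depend on the seed
  expect_false(identical(a$train_ids, c$train_ids))
  # remainder goes to the highest-score strata: 50 = 13+13+12+12
  expect_equal(lengths(a$strata), c(13L, 13L, 12L, 12L))
  # per-stratum rounding: 10 samples at 0.8 -> 8 train / 2 validation
  small <- stratified_split(make_scores(10, seed = 2), "avoidant", 1, 0.8,
                            seed = 1)
  expect_length(small$train_ids, 8L)
  expect_length(small$val_ids, 2L)
  expect_error(stratified_split(scores[0, ], "rational"), "no score")
})

test_that("OLS pipeline interpolates an exactly linear target", {
  set.seed(51)
  X <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(sprintf("S%03d", 1:40), NULL))
  beta <- c(2, -1, 0.5, 3, -2)
  y <- as.vector(X[, 1:5] %*% beta) + 4
  cfg <- tiny_pipeline(pca_components = 12, algorithm = "lr")
  fm <- structure(list(values = X, subject_ids = rownames(X),
                       layout = paste0("f", 1:12)),
                  class = "feature_matrix")
  m <- fit_pipeline(fm, y, cfg)
  expect_equal(ncol(m$pca_basis), 12L)
  expect_equal(unname(predict(m, fm)), y, tolerance = 1e-6)
  # basis columns are orthonormal
  expect_equal(unname(crossprod(m$pca_basis)), diag(12), tolerance = 1e-8)
  # duplicated input row gives duplicated prediction
  fm2 <- structure(list(values = X[c(1, 1), ], subject_ids = c("a", "b"),
                        layout = fm$layout), class = "feature_matrix")
  p2 <- unname(predict(m, fm2))
  expect_equal(p2[1], p2[2])
  # layout mismatch is refused
  fm3 <- structure(list(values = X, subject_ids = rownames(X),
                        layout = paste0("g", 1:12)), class = "feature_matrix")
  expect_error(predict(m, fm3), "layout")
})

test_that("evaluation metrics match direct-formula oracles", {
  y <- c(3, 7, 1, 9, 4)
  expect_equal(evaluate_predictions(y, y)$pearson_r, 1)
  expect_equal(evaluate_predictions(y, y)$rmse, 0)
  shifted <- evaluate_predictions(y + 2, y)
  expect_equal(shifted$pearson_r, 1)
  expect_equal(shifted$rmse, 2)
  set.seed(52)
  a <- rnorm(5); b <- rnorm(5)
  got <- evaluate_predictions(a, b)
  expect_equal(got$pearson_r, brute_pearson(a, b), tolerance = 1e-12)
  expect_equal(got$rmse, brute_rmse(a, b), tolerance = 1e-12)
  expect_warning(out <- evaluate_predictions(a, rep(1, 5)), "constant")
  expect_true(is.na(out$pearson_r))
  expect_error(evaluate_predictions(1:3, 1:4), "length")
})

test_that("GCV ridge matches an independent implementation and OLS limit", {
  set.seed(53)
  n <- 60; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- as.vector(X %*% rnorm(p)) + rnorm(n, sd = 0.5)
  # penalty -> 0 recovers OLS on well-conditioned data
  fit0 <- facestyle:::fit_ridge_gcv(X, y, lambdas = 1e-10)
  ols <- stats::lm.fit(cbind(1, X), y)$coefficients
  expect_equal(fit0$coef, unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit0$intercept, unname(ols[1]), tolerance = 1e-6)
  # GCV profile agrees with MASS::lm.ridge's independent GCV computation
  skip_if_not_installed("MASS")
  lambdas <- 10^seq(-2, 2, length.out = 9)
  ours <- facestyle:::fit_ridge_gcv(scale(X, scale = FALSE), y, lambdas)
  mass <- MASS::lm.ridge(y ~ X, lambda = lambdas)
  # same argmin over the shared grid
  expect_equal(unname(which.min(ours$gcv)), unname(which.min(mass$GCV)))
})

test_that("Bayesian ridge shrinks toward but tracks the OLS solution", {
  set.seed(54)
  n <- 80; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(3, -2, 1.5, 0, 0.5, -1)
  y <- as.vector(X %*% beta) + rnorm(n, sd = 0.3)
  fit <- facestyle:::fit_bayes_ridge(X, y)
  expect_equal(fit$coef, beta, tolerance = 0.15)
  # estimated noise precision close to the truth (sd 0.3 -> alpha ~ 11)
  expect_gt(fit$alpha, 1 / 0.5^2)
  expect_lt(fit$alpha, 1 / 0.15^2)
  ols <- stats::lm.fit(cbind(1, X), y)$coefficients[-1]
  expect_lt(sum(fit$coef^2), sum(ols^2) + 1e-8)  # shrinkage
})

test_that("linear fits are invariant to training-row order", {
  set.seed(55)
  X <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(sprintf("S%03d", 1:50), NULL))
  y <- as.vector(X[, 1:3] %*% c(1, 2, -1)) + rnorm(50, sd = 0.2)
  perm <- sample(50)
  newX <- matrix(rnorm(5 * 10), 5, 10)
  colnames(newX) <- NULL
  for (alg in c("lr", "ridgecv", "br")) {
    cfg <- tiny_pipeline(pca_components = 10, algorithm = alg)
    m1 <- fit_pipeline(X, y, cfg)
    m2 <- fit_pipeline(X[perm, ], y[perm], cfg)
    p1 <- predict(m1, newX)
    p2 <- predict(m2, newX)
    expect_equal(unname(p1), unname(p2), tolerance = 1e-8)
  }
})

test_that("misconfigured fits are refused", {
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- rnorm(20)
  cfg <- tiny_pipeline(pca_components = 8)
  expect_error(fit_pipeline(X, y, cfg), "pca_components")
  cfg2 <- tiny_pipeline(pca_components = 4)
  cfg2$algorithm <- "xgboost"
  expect_error(fit_pipeline(X, y, cfg2), "unknown algorithm")
  expect_error(fit_pipeline(X[1, , drop = FALSE], y[1], cfg2), "2 training")
  expect_error(fit_pipeline(X, y[1:5], cfg2), "disagree")
})

test_that("cross-validation folds are balanced, disjoint and seeded", {
  set.seed(56)
  n <- 40
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(sprintf("S%03d", 1:n), NULL))
  y <- as.vector(X[, 1] * 3) + rnorm(n, sd = 0.1)
  cfg <- tiny_pipeline(pca_components = 6, cv_folds = 10, seed = 5L)
  cv <- crossvalidate(X, y, cfg)
  expect_equal(nrow(cv), 10L)
  expect_equal(sum(cv$n_val), n)
  expect_true(all(cv$n_val == 4L))
  cv2 <- crossvalidate(X, y, cfg)
  expect_equal(cv, cv2)
  # strong linear signal is recovered in every fold
  expect_gt(mean(cv$pearson_r), 0.9)
  expect_error(crossvalidate(X[1:5, ], y[1:5], cfg), "fewer samples")
})
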
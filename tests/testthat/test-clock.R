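## Small deterministic feature designs for clock unit tests; the full
## simulated-cohort behaviour is exercised in the acceptance suite.
toy_features <- function(n = 40, p = 20, ages = NULL, seed = 1) {
  set.seed(seed)
  ages <- ages %||% runif(n, 25, 100)
  x <- matrix(0, n, p)
  x[, 5] <- ages          # one perfectly predictive feature, all else 0
  rownames(x) <- sprintf("s%02d", seq_len(n))
  structure(x, feature_kind = "custom", grid = seq_len(p),
            class = c("feature_matrix", "matrix", "array"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("feature matrices are deterministic with unit-sum size rows", {
  spec <- cohort_spec(n_subjects = 2, genome_length = 5e5,
                      n_fragments_per_subject = 5e3, seed = 2)
  co <- generate_cohort(spec, ages = c(30, 90))
  f <- build_features(co$samples, "size_dist")
  expect_equal(dim(f), c(2, 501))
  expect_equal(unname(rowSums(f)), c(1, 1), tolerance = 1e-9)
  ## the same sample twice gives identical rows
  f2 <- build_features(list(co$samples[[1]], co$samples[[1]]),
                       "size_dist")
  expect_equal(f2[1, ], f2[2, ])
  fa <- build_features(co$samples, "distance_autocorr")
  expect_equal(ncol(fa), 2000 - 120 + 1)
  expect_identical(fa, build_features(co$samples, "distance_autocorr"))
})

test_that("phasogram features separate NRL groups more than within-group", {
  specA <- cohort_spec(genome_length = 1e6, n_fragments_per_subject = 3e4,
                       nrl_beta0 = 175, nrl_beta1 = 0, nrl_sigma = 0,
                       seed = 81)
  specB <- cohort_spec(genome_length = 1e6, n_fragments_per_subject = 3e4,
                       nrl_beta0 = 195, nrl_beta1 = 0, nrl_sigma = 0,
                       seed = 82)
  samples <- c(lapply(1:2, function(i) generate_subject(specA, 50, i)),
               lapply(3:4, function(i) generate_subject(specB, 50, i)))
  f <- build_features(samples, "distance_autocorr")
  cm <- cor(t(unclass(f)))
  within <- c(cm[1, 2], cm[3, 4])
  between <- c(cm[1, 3], cm[1, 4], cm[2, 3], cm[2, 4])
  expect_gt(min(within), max(between))
})

test_that("a perfectly predictive feature gives an exact test fit", {
  f <- toy_features(seed = 3)
  ages <- f[, 5]
  m <- train_clock(f, ages, k = 5, seed = 4)
  expect_equal(m$metrics$pearson_r, 1, tolerance = 1e-6)
  expect_lt(m$metrics$median_abs_error, 1e-6)
})

test_that("training is deterministic and leakage-free", {
  f <- toy_features(seed = 5)
  ages <- f[, 5] + rnorm(40, 0, 3)
  m1 <- train_clock(f, ages, seed = 9)
  m2 <- train_clock(f, ages, seed = 9)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$predictions, m2$predictions)
  ## removing one test sample changes nothing fitted
  test_idx <- 31:40
  a <- train_clock(f, ages, test_idx = test_idx)
  b <- train_clock(unclass(f)[1:39, ], ages[1:39], test_idx = 31:39)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-12)
  expect_equal(a$center, b$center, tolerance = 1e-12)
})

test_that("predictions match a closed-form OLS solve on projected scores", {
  set.seed(6)
  f <- matrix(rnorm(40 * 20), 40, 20)  # full-rank random design
  ages <- 60 + 10 * f[, 1] + rnorm(40, 0, 2)
  m <- train_clock(f, ages, k = 6, test_idx = 33:40)
  tr <- 1:32
  z <- sweep(sweep(unclass(f)[tr, ], 2, m$center), 2, m$scale, "/")
  s <- z %*% m$loadings
  X <- cbind(1, s)
  beta <- solve(crossprod(X), crossprod(X, ages[tr]))
  expect_lt(max(abs(drop(X %*% beta) -
                      predict(m, unclass(f)[tr, ]))), 1e-8)
  ## OLS residuals on the training rows have mean zero
  expect_lt(abs(mean(predict(m, unclass(f)[tr, ]) - ages[tr])), 1e-8)
  ## all-zero feature row still yields a finite prediction
  expect_true(is.finite(predict(m, rep(0, 20))))
  expect_error(predict(m, rep(0, 7)), "grid mismatch")
})

test_that("noise features degrade cohort clocks only gracefully", {
  ## appending uninformative i.i.d. noise features to the (correlated)
  ## cohort feature set must not raise test MedAE by more than 2 years
  spec <- cohort_spec(n_subjects = 40, genome_length = 5e5,
                      n_fragments_per_subject = 1e4, seed = 91)
  co <- generate_cohort(spec)
  f <- build_features(co$samples, "size_dist")
  deltas <- vapply(1:3, function(s) {
    base <- train_clock(f, co$meta$age,
                        seed = s)$metrics$median_abs_error
    set.seed(1000 + s)
    noisy <- cbind(unclass(f), matrix(rnorm(40 * 100), 40, 100))
    aug <- train_clock(noisy, co$meta$age,
                       seed = s)$metrics$median_abs_error
    aug - (2 * base + 2)  # bound: noise-free MedAE + 2 years
  }, 0)
  expect_lt(mean(deltas), 0)
})

test_that("ridge mode fits and predicts on standard features", {
  skip_if_not_installed("glmnet")
  f <- toy_features(seed = 12)
  ages <- f[, 5] + rnorm(40, 0, 2)
  m <- train_clock(f, ages, mode = "ridge", seed = 2)
  expect_gt(m$metrics$pearson_r, 0.9)
  expect_identical(train_clock(f, ages, mode = "ridge",
                               seed = 2)$coefficients, m$coefficients)
})

test_that("metrics agree with direct formulas to 1e-12", {
  expect_equal(unclass(evaluate_metrics(1:10, 1:10))[1:3],
               list(pearson_r = 1, mse = 0, median_abs_error = 0))
  m <- evaluate_metrics(1:10 + 2, 1:10)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$mse, 4)
  expect_equal(m$median_abs_error, 2)
  set.seed(14)
  for (i in 1:5) {
    p <- rnorm(50, 60, 20); a <- rnorm(50, 60, 20)
    m <- evaluate_metrics(p, a)
    n <- 50
    r <- (sum(p * a) - n * mean(p) * mean(a)) /
      sqrt((sum(p^2) - n * mean(p)^2) * (sum(a^2) - n * mean(a)^2))
    expect_equal(m$pearson_r, r, tolerance = 1e-12)
    expect_equal(m$mse, sum((p - a)^2) / n, tolerance = 1e-12)
    expect_equal(m$median_abs_error, median(abs(p - a)),
                 tolerance = 1e-12)
  }
  z <- evaluate_metrics(rep(5, 10), 1:10)
  expect_true(z$degenerate)
})

test_that("rank AUC equals the ROC integral and external references", {
  ## step-function ROC integration oracle (trapezoid over thresholds)
  roc_integral <- function(scores, labels) {
    th <- sort(unique(scores), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(scores[labels] >= t), 0)
    fpr <- vapply(th, function(t) mean(scores[!labels] >= t), 0)
    tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  expect_equal(auc_rank(c(0, 0, 1, 1), c(FALSE, FALSE, TRUE, TRUE)), 1)
  set.seed(15)
  for (i in 1:10) {
    scores <- round(rnorm(40), 1)  # rounding forces ties
    labels <- runif(40) < 0.4
    if (length(unique(labels)) < 2) next
    expect_equal(auc_rank(scores, labels), roc_integral(scores, labels),
                 tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  scores <- rnorm(60); labels <- runif(60) < 0.5
  expect_equal(auc_rank(scores, labels),
               as.numeric(suppressMessages(
                 pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                     levels = c(FALSE, TRUE),
                                     direction = "<")))),
               tolerance = 1e-12)
  expect_error(auc_rank(1:4, rep(TRUE, 4)), "both classes")
})

test_that("age-group classification uses the clock score by default", {
  f <- toy_features(n = 40, seed = 16)
  ages <- f[, 5]
  cl <- classify_age_group(f, ages, threshold_years = 55, seed = 5)
  expect_equal(cl$auc, 1)
  cl2 <- classify_age_group(f, ages, threshold_years = 55,
                            mode = "logistic", k = 2, seed = 5)
  expect_gt(cl2$auc, 0.9)
  expect_error(classify_age_group(f, ages, threshold_years = 200,
                                  seed = 5),
               "single age class")
})
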
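## Linear-regression aging clocks on cfDNA nucleosomics features.
##
## Two feature kinds are supported: per-sample fragment-size frequency
## vectors ("size_dist") and smoothed, normalised phasograms
## ("distance_autocorr").  Both are high-dimensional relative to typical
## cohort sizes (hundreds of features, tens of samples), so the default
## clock is principal-component regression (PCR): standardise features on
## the training split, project onto the top-k training-set principal
## components, and fit OLS on the projected scores.  This is still a
## linear model in the original features.  A ridge mode on raw
## standardised features (via glmnet) is provided as an alternative.

#' Build a feature matrix for the clock
#'
#' @param samples list of `fragment_set` objects.
#' @param feature_kind `"size_dist"` (fragment-size frequencies, one
#'   feature per bp of the size window) or `"distance_autocorr"`
#'   (smoothed normalised phasogram, one feature per bp of distance in
#'   `[d_min_fit, d_max]`).
#' @param size_range size window for `"size_dist"`, bp.
#' @param d_max,d_min_fit,window,polyorder phasogram parameters for
#'   `"distance_autocorr"`.
#' @return An object of class `feature_matrix`: numeric matrix (samples
#'   x features, rownames = sample ids) with attributes `feature_kind`
#'   and `grid`; samples with an empty distribution are excluded with a
#'   warning and listed in attribute `excluded`.
#' @export
build_features <- function(samples,
                           feature_kind = c("size_dist",
                                            "distance_autocorr"),
                           size_range = c(100, 600), d_max = 2000,
                           d_min_fit = 120, window = 51, polyorder = 3) {
  feature_kind <- match.arg(feature_kind)
  rows <- list(); ids <- character(0); excluded <- character(0)
  for (fs in samples) {
    if (feature_kind == "size_dist") {
      d <- size_distribution(fs, size_range[1], size_range[2])
      if (d$empty) { excluded <- c(excluded, fs$sample_id); next }
      row <- d$freq
      grid <- d$size
    } else {
      p <- compute_phasogram(fs, d_max = d_max)
      if (p$n_pairs == 0) { excluded <- c(excluded, fs$sample_id); next }
      p <- smooth_phasogram(p, window = window, polyorder = polyorder)
      sel <- p$d >= d_min_fit
      row <- p$smoothed[sel]
      grid <- p$d[sel]
    }
    rows[[length(rows) + 1L]] <- row
    ids <- c(ids, fs$sample_id)
  }
  if (length(excluded))
    warning("excluded empty samples: ", paste(excluded, collapse = ", "))
  if (length(rows) == 0L) stop("no usable samples")
  x <- do.call(rbind, rows)
  rownames(x) <- ids
  structure(x, feature_kind = feature_kind, grid = grid,
            excluded = excluded, class = c("feature_matrix", "matrix",
                                           "array"))
}

## Seeded train/test partition stratified by age tertile, so the test
## split spans the age range even at small n.
stratified_split <- function(ages, split_fraction, seed) {
  n <- length(ages)
  br <- unique(stats::quantile(ages, c(0, 1/3, 2/3, 1)))
  tert <- if (length(br) > 2)
    cut(ages, breaks = br, include.lowest = TRUE, labels = FALSE)
  else rep(1L, n)
  with_seed(derive_seed(seed, 911L), {
    test <- integer(0)
    for (g in unique(tert)) {
      idx <- which(tert == g)
      n_test <- round(length(idx) * (1 - split_fraction))
      if (n_test > 0)
        test <- c(test, sample(idx, n_test))
    }
    sort(test)
  })
}

#' Train an aging clock
#'
#' Splits samples into training/test sets (seeded, stratified by age
#' tertile), fits the clock on the training rows only, and reports
#' metrics on the untouched test rows.  Standardisation, projection
#' loadings and regression coefficients all come from the training set
#' alone, so test metrics are leakage-free.
#'
#' @param features a `feature_matrix` (or plain matrix, samples x
#'   features).
#' @param ages numeric ages, one per row.
#' @param split_fraction training fraction (default 0.8).
#' @param k number of principal components for PCR mode (capped at
#'   `n_train - 2`).
#' @param seed integer seed for the split.
#' @param mode `"pcr"` (default) or `"ridge"` (glmnet, alpha = 0,
#'   lambda by deterministic cross-validation).
#' @param test_idx optional explicit test-row indices, overriding the
#'   seeded split (for leakage audits and fixed designs).
#' @return An object of class `cfdna_clock`; see Details.  Fields
#'   include `center`/`scale` (feature standardisation), `loadings`,
#'   `coefficients`, `metrics` (a `clock_metrics` on the test split),
#'   `predictions` (data.frame over all samples with the split label).
#' @export
train_clock <- function(features, ages, split_fraction = 0.8, k = 10,
                        seed = 1L, mode = c("pcr", "ridge"),
                        test_idx = NULL) {
  mode <- match.arg(mode)
  x <- unclass(features)
  stopifnot(is.matrix(x), nrow(x) == length(ages), all(is.finite(ages)))
  n <- nrow(x)
  if (n < 10) stop("need at least 10 samples")
  if (is.null(test_idx))
    test_idx <- stratified_split(ages, split_fraction, seed)
  test_idx <- sort(unique(as.integer(test_idx)))
  if (length(test_idx) < 2) stop("degenerate test split (n_test < 2)")
  train_idx <- setdiff(seq_len(n), test_idx)
  n_train <- length(train_idx)
  if (mode == "pcr" && k >= n_train - 1)
    stop("k must be <= n_train - 2")
  xtr <- x[train_idx, , drop = FALSE]
  mu <- colMeans(xtr)
  sd <- apply(xtr, 2L, stats::sd)
  sd[sd == 0] <- 1  # constant features carry no information; leave at 0
  ztr <- sweep(sweep(xtr, 2L, mu), 2L, sd, "/")
  if (mode == "pcr") {
    pc <- stats::prcomp(ztr, center = FALSE, scale. = FALSE)
    k_use <- min(k, ncol(pc$rotation))
    loadings <- pc$rotation[, seq_len(k_use), drop = FALSE]
    str <- ztr %*% loadings
    fit <- stats::lm.fit(cbind(1, str), ages[train_idx])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    coefficients <- beta
  } else {
    if (!requireNamespace("glmnet", quietly = TRUE))
      stop("ridge mode requires the glmnet package")
    foldid <- rep_len(1:5, n_train)[
      with_seed(derive_seed(seed, 913L), sample.int(n_train))]
    cv <- glmnet::cv.glmnet(ztr, ages[train_idx], alpha = 0,
                            foldid = foldid)
    loadings <- NULL
    coefficients <- as.numeric(stats::coef(cv, s = "lambda.min"))
    k_use <- NA_integer_
  }
  model <- structure(list(
    feature_kind = attr(features, "feature_kind") %||% "custom",
    grid = attr(features, "grid"),
    mode = mode, center = mu, scale = sd, loadings = loadings,
    coefficients = coefficients, k = k_use, seed = seed,
    split_fraction = split_fraction,
    train_ids = rownames(x)[train_idx] %||% train_idx,
    test_ids = rownames(x)[test_idx] %||% test_idx),
    class = "cfdna_clock")
  pred_all <- predict(model, x)
  model$metrics <- evaluate_metrics(pred_all[test_idx], ages[test_idx])
  model$predictions <- data.frame(
    sample_id = rownames(x) %||% as.character(seq_len(n)),
    age = ages, predicted_age = pred_all,
    split = ifelse(seq_len(n) %in% test_idx, "test", "train"),
    stringsAsFactors = FALSE)
  model
}

#' Predict ages with a fitted clock
#'
#' Standardise with training means/SDs, project onto the stored
#' loadings (PCR mode), and apply the linear coefficients.  Fully
#' deterministic.
#'
#' @param object a `cfdna_clock`.
#' @param features matrix (samples x features) on the model's feature
#'   grid, or a `feature_matrix`.
#' @param ... unused.
#' @return numeric vector of predicted ages (years).
#' @export
predict.cfdna_clock <- function(object, features, ...) {
  x <- unclass(features)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(object$center))
    stop("feature grid mismatch: model has ", length(object$center),
         " features, input has ", ncol(x))
  z <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  if (object$mode == "pcr") {
    s <- z %*% object$loadings
    drop(cbind(1, s) %*% object$coefficients)
  } else {
    drop(cbind(1, z) %*% object$coefficients)
  }
}

#' @export
print.cfdna_clock <- function(x, ...) {
  cat(sprintf(
    "cfdna_clock (%s, %s): %d train / %d test samples%s\n",
    x$feature_kind, x$mode, length(x$train_ids), length(x$test_ids),
    if (x$mode == "pcr") sprintf(", k = %d components", x$k) else ""))
  m <- x$metrics
  cat(sprintf("  test: r = %.3f, MSE = %.2f yr^2, MedAE = %.2f yr\n",
              m$pearson_r, m$mse, m$median_abs_error))
  invisible(x)
}

#' @export
summary.cfdna_clock <- function(object, ...) {
  print(object)
  cat("\npredictions (test split):\n")
  print(object$predictions[object$predictions$split == "test", ],
        row.names = FALSE)
  invisible(object)
}

#' @export
coef.cfdna_clock <- function(object, ...) object$coefficients

#' Predicted-vs-chronological age plot
#' @param x a `cfdna_clock`.
#' @param ... passed to [plot()].
#' @export
plot.cfdna_clock <- function(x, ...) {
  p <- x$predictions
  cols <- ifelse(p$split == "test", "red", "grey40")
  plot(p$age, p$predicted_age, col = cols,
       pch = ifelse(p$split == "test", 19, 1),
       xlab = "chronological age (years)",
       ylab = "predicted age (years)", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", c("train", "test"), col = c("grey40", "red"),
                   pch = c(1, 19), bty = "n")
  invisible(x)
}

#' Regression metrics for an age predictor
#'
#' @param predicted,chronological equal-length numeric vectors, n >= 2.
#' @return An object of class `clock_metrics`: list with `pearson_r`
#'   (NA with a flag if predictions have zero variance), `mse`
#'   (mean squared residual, years^2) and `median_abs_error` (years).
#' @export
evaluate_metrics <- function(predicted, chronological) {
  stopifnot(length(predicted) == length(chronological),
            length(predicted) >= 2)
  resid <- predicted - chronological
  r <- if (stats::sd(predicted) == 0 || stats::sd(chronological) == 0)
    NA_real_
  else stats::cor(predicted, chronological)
  structure(list(pearson_r = r, mse = mean(resid^2),
                 median_abs_error = stats::median(abs(resid)),
                 degenerate = is.na(r), n = length(predicted)),
            class = "clock_metrics")
}

#' @export
print.clock_metrics <- function(x, ...) {
  cat(sprintf("clock_metrics: r = %s, MSE = %.3f, MedAE = %.3f (n = %d)\n",
              if (is.na(x$pearson_r)) "NA (degenerate)"
              else sprintf("%.3f", x$pearson_r),
              x$mse, x$median_abs_error, x$n))
  invisible(x)
}

#' Area under the ROC curve by the rank formula
#'
#' Mann-Whitney statistic with midrank tie correction:
#' `AUC = (sum of positive-class ranks - n1 (n1 + 1) / 2) / (n1 n0)`.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels logical or 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Age-group classification AUC
#'
#' Labels samples as old (`age > threshold_years`) and scores them with
#' the regression clock's predicted age (mode `"clock"`) or a logistic
#' model on the clock's projected training features (mode
#' `"logistic"`); reports the ROC AUC on the test split.
#'
#' @param features a `feature_matrix`.
#' @param ages numeric ages.
#' @param threshold_years class boundary (label 1 iff age > threshold).
#' @param mode `"clock"` or `"logistic"`.
#' @param split_fraction,k,seed,test_idx passed to [train_clock()].
#' @return list with `auc`, `threshold_years`, `mode`, `scores`,
#'   `labels` (test split) and the underlying `model`.
#' @export
classify_age_group <- function(features, ages, threshold_years = 55,
                               mode = c("clock", "logistic"),
                               split_fraction = 0.8, k = 10, seed = 1L,
                               test_idx = NULL) {
  mode <- match.arg(mode)
  model <- train_clock(features, ages, split_fraction = split_fraction,
                       k = k, seed = seed, test_idx = test_idx)
  p <- model$predictions
  test <- p$split == "test"
  labels <- ages > threshold_years
  if (length(unique(labels[test])) < 2)
    stop("test split contains a single age class")
  if (mode == "clock") {
    scores <- p$predicted_age[test]
  } else {
    x <- unclass(features)
    tr <- !test
    z <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
    s <- z %*% model$loadings
    df_tr <- data.frame(y = as.integer(labels[tr]), s[tr, , drop = FALSE])
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = df_tr, family = stats::binomial()))
    scores <- as.numeric(
      stats::predict(fit, newdata = data.frame(s[test, , drop = FALSE]),
                     type = "link"))
  }
  list(auc = auc_rank(scores, labels[test]),
       threshold_years = threshold_years, mode = mode,
       scores = scores, labels = labels[test], model = model)
}

#' Serialise a clock model to JSON
#' @param model a `cfdna_clock`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clock_model <- function(model, path) {
  jsonlite::write_json(
    list(feature_kind = model$feature_kind, mode = model$mode,
         grid = model$grid, center = model$center, scale = model$scale,
         loadings = if (is.null(model$loadings)) NULL else
           apply(model$loadings, 2L, identity, simplify = FALSE),
         coefficients = model$coefficients, k = model$k,
         seed = model$seed, split_fraction = model$split_fraction,
         train_ids = model$train_ids, test_ids = model$test_ids),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
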
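# Disease-status prediction: PCA on the training portion of each split,
# logistic regression on the leading component scores, AUROC on the held-out
# portion, averaged over repeated 80:20 splits.

#' Configuration for the disease classifier
#'
#' Defaults are desk-scale (100 splits); the full-scale analysis uses 1000.
#'
#' @param n_components Number of leading principal components used as
#'   predictors.
#' @param n_splits Number of independent train-test samplings.
#' @param test_fraction Held-out fraction per split.
#' @param seed Integer seed.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(n_components = 30L, n_splits = 100L,
                              test_fraction = 0.2, seed = 1L) {
  check_fields(
    n_components = n_components >= 1,
    n_splits = n_splits >= 1,
    test_fraction = test_fraction > 0 && test_fraction < 1,
    seed = length(seed) == 1 && is.finite(seed)
  )
  structure(list(n_components = as.integer(n_components),
                 n_splits = as.integer(n_splits),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "classifier_config")
}

# internal: logistic scores with a small-ridge fallback on separation
logistic_scores <- function(S_train, y_train, S_test) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, S_train), y_train, family = stats::binomial()),
    warning = function(w) {
      sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (!sep && fit$converged) {
    co <- fit$coefficients
    co[is.na(co)] <- 0
    return(drop(cbind(1, S_test) %*% co))
  }
  # separation or non-convergence: small ridge keeps the decision scores finite
  rfit <- glmnet::glmnet(S_train, y_train, family = "binomial", alpha = 0,
                         lambda = 1e-2, standardize = FALSE)
  drop(stats::predict(rfit, newx = S_test))
}

#' Evaluate the PCA + logistic classifier over repeated splits
#'
#' Per split: PCA is fit on the training portion only (no leakage; the
#' leaky variant that fits PCA once on all data is available via
#' `leaky_pca`), the first `n_components` scores are fed to an unpenalized
#' logistic regression (with a small-ridge fallback under separation), and
#' the AUROC is computed on the held-out portion. Splits that land a single
#' class in train or test are redrawn.
#'
#' @param X Subjects x features matrix, median-imputed and z-scaled.
#' @param labels Binary factor (second level is the positive class) or 0/1
#'   vector.
#' @param config A [classifier_config()].
#' @param leaky_pca Fit PCA once on all subjects instead of per split.
#' @return Object of class `classifier_result`: `mean_auroc`, `sd_auroc`,
#'   `aurocs` (per split), `n_components`, and `loadings` (PCA rotation on
#'   the full data, diagnostic).
#' @export
evaluate_classifier <- function(X, labels, config = classifier_config(),
                                leaky_pca = FALSE) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  stopifnot(nrow(X) == length(y), all(y %in% 0:1), !anyNA(X))
  set.seed(config$seed)
  n <- nrow(X)
  k <- min(config$n_components, ncol(X))
  full_pca <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  aurocs <- numeric(config$n_splits)
  for (s in seq_len(config$n_splits)) {
    for (try in 1:100) {
      test <- sample.int(n, round(config$test_fraction * n))
      train <- setdiff(seq_len(n), test)
      if (length(unique(y[train])) == 2 && length(unique(y[test])) == 2) break
      if (try == 100) stop("could not draw a split with both classes", call. = FALSE)
    }
    if (leaky_pca) {
      S_tr <- full_pca$x[train, , drop = FALSE]
      S_te <- full_pca$x[test, , drop = FALSE]
    } else {
      kk <- min(k, length(train) - 1L)
      pca <- stats::prcomp(X[train, , drop = FALSE], center = TRUE,
                           scale. = FALSE, rank. = kk)
      S_tr <- pca$x
      S_te <- stats::predict(pca, X[test, , drop = FALSE])
    }
    score <- logistic_scores(S_tr, y[train], S_te)
    roc <- pROC::roc(response = y[test], predictor = score,
                     levels = c(0, 1), direction = "<", quiet = TRUE)
    aurocs[s] <- as.numeric(roc$auc)
  }
  structure(list(
    mean_auroc = mean(aurocs), sd_auroc = stats::sd(aurocs), aurocs = aurocs,
    n_components = k, loadings = full_pca$rotation
  ), class = "classifier_result")
}

#' Compare classifier performance across feature sets
#'
#' Runs [evaluate_classifier()] on each supplied feature matrix with a
#' shared seed schedule (identical split draws in every arm), and reports
#' the mean AUROCs in decreasing order. The canonical arms are uncorrected
#' features, all age-corrected features, and the significant age-corrected
#' features; an empty arm is skipped with a warning.
#'
#' @param feature_sets Named list of subjects x features matrices over the
#'   same subjects.
#' @param labels Binary labels as in [evaluate_classifier()].
#' @param config A [classifier_config()].
#' @return Object of class `feature_set_comparison`: list with `summary`
#'   (data frame: arm, mean_auroc, sd_auroc, n_features, ordered by
#'   decreasing AUROC) and `results` (per-arm `classifier_result`s).
#' @export
compare_feature_sets <- function(feature_sets, labels,
                                 config = classifier_config()) {
  stopifnot(is.list(feature_sets), length(feature_sets) >= 1,
            !is.null(names(feature_sets)))
  results <- list()
  for (arm in names(feature_sets)) {
    Xa <- feature_sets[[arm]]
    if (is.null(Xa) || ncol(Xa) == 0) {
      warning("feature set '", arm, "' is empty; skipped")
      next
    }
    results[[arm]] <- evaluate_classifier(Xa, labels, config)
  }
  summary <- data.frame(
    arm = names(results),
    mean_auroc = vapply(results, function(r) r$mean_auroc, numeric(1)),
    sd_auroc = vapply(results, function(r) r$sd_auroc, numeric(1)),
    n_features = vapply(names(results), function(a) ncol(feature_sets[[a]]),
                        numeric(1)),
    row.names = NULL
  )
  summary <- summary[order(-summary$mean_auroc), ]
  structure(list(summary = summary, results = results),
            class = "feature_set_comparison")
}
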
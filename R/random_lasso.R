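# The immunological-age estimator: a two-stage random-lasso ensemble over
# repeated train-test splits, an elbow-based importance cutoff estimated by
# repeated cross-validation, and downstream residual-age analyses.

#' Configuration for the random-lasso immunological age model
#'
#' Defaults are the desk-scale reduced settings (100 outer splits, 100
#' bootstraps per stage); the full-scale analysis uses 1000 of each.
#'
#' @param n_splits Number of outer random train-test splits.
#' @param test_fraction Held-out fraction per split (0 disables the split).
#' @param n_boot1,n_boot2 Bootstrap count per stage.
#' @param q1_range Stage-1 feature fraction range: each bootstrap fits a
#'   lasso on a fraction of features drawn uniformly from this range.
#' @param q2 Stage-2 feature fraction, sampled with probability proportional
#'   to the absolute stage-1 importance.
#' @param cv_folds,cv_repeats Fold count and repeat count for the importance
#'   cutoff estimation.
#' @param bootstrap Resample subjects with replacement inside each stage?
#'   `FALSE` gives the oracle-reduction mode (each "bootstrap" is the full
#'   training set).
#' @param lambda Optional fixed lasso penalty; by default each bootstrap's
#'   penalty is chosen by the extended BIC along a geometric path.
#' @param n_lambda,lambda_min_ratio Path settings for the penalty selection.
#' @param ebic_gamma Extended-BIC parameter of the per-bootstrap penalty
#'   selection (0 = ordinary BIC; 0.5 is the standard choice for sparse
#'   support recovery).
#' @param signed_importance Use signed stage-1 importance as the stage-2
#'   selection weight (default uses the absolute value, per the original
#'   random-lasso formulation).
#' @param average_over_appearances Average bootstrap coefficients over
#'   appearances only, instead of counting absent features as 0 (default
#'   off, per the original formulation).
#' @param scale_within_train Re-standardize features inside each outer
#'   training set (leak-free variant); default off, matching the original
#'   full-cohort scaling.
#' @param seed Integer seed for the whole procedure.
#' @return Object of class `random_lasso_config`.
#' @export
random_lasso_config <- function(n_splits = 100L, test_fraction = 0.2,
                                n_boot1 = 100L, n_boot2 = 100L,
                                q1_range = c(0.15, 0.20), q2 = 0.10,
                                cv_folds = 5L, cv_repeats = 20L,
                                bootstrap = TRUE, lambda = NULL,
                                n_lambda = 25L, lambda_min_ratio = 0.01,
                                ebic_gamma = 0.5,
                                signed_importance = FALSE,
                                average_over_appearances = FALSE,
                                scale_within_train = FALSE,
                                seed = 1L) {
  check_fields(
    n_splits = n_splits >= 1, test_fraction = test_fraction >= 0 && test_fraction < 1,
    n_boot1 = n_boot1 >= 1, n_boot2 = n_boot2 >= 1,
    q1_range = length(q1_range) == 2 && q1_range[1] > 0 && q1_range[1] <= q1_range[2] &&
      q1_range[2] <= 1,
    q2 = q2 > 0 && q2 <= 1,
    cv_folds = cv_folds >= 2, cv_repeats = cv_repeats >= 1,
    lambda = is.null(lambda) || lambda >= 0,
    seed = length(seed) == 1 && is.finite(seed)
  )
  structure(list(
    n_splits = as.integer(n_splits), test_fraction = test_fraction,
    n_boot1 = as.integer(n_boot1), n_boot2 = as.integer(n_boot2),
    q1_range = q1_range, q2 = q2, cv_folds = as.integer(cv_folds),
    cv_repeats = as.integer(cv_repeats), bootstrap = isTRUE(bootstrap),
    lambda = lambda, n_lambda = as.integer(n_lambda),
    lambda_min_ratio = lambda_min_ratio, ebic_gamma = ebic_gamma,
    signed_importance = isTRUE(signed_importance),
    average_over_appearances = isTRUE(average_over_appearances),
    scale_within_train = isTRUE(scale_within_train),
    seed = as.integer(seed)
  ), class = "random_lasso_config")
}

# internal: draw a subject bootstrap, retrying (rarely) if y is degenerate
draw_bootstrap <- function(train, y, bootstrap) {
  if (!bootstrap) return(train)
  for (i in 1:20) {
    rows <- train[sample.int(length(train), length(train), replace = TRUE)]
    if (stats::sd(y[rows]) > 0) return(rows)
  }
  stop("could not draw a bootstrap with non-constant response", call. = FALSE)
}

# internal: one lasso on a (rows, feats) subsample; returns full-length
# coefficient vector with zeros for absent features, plus the intercept.
subsample_lasso <- function(X, y, rows, feats, config) {
  Xs <- X[rows, feats, drop = FALSE]
  ys <- y[rows]
  fit <- if (is.null(config$lambda)) {
    lasso_bic(Xs, ys, n_lambda = config$n_lambda,
              lambda_min_ratio = config$lambda_min_ratio,
              gamma = config$ebic_gamma)
  } else {
    lasso_fit(Xs, ys, config$lambda)
  }
  beta <- numeric(ncol(X))
  beta[feats] <- fit$beta
  list(beta = beta, intercept = fit$intercept)
}

# internal: one full two-stage random lasso on a training set
random_lasso_split <- function(X, y, train, config) {
  p <- ncol(X)
  if (config$scale_within_train) {
    ctr <- colMeans(X[train, , drop = FALSE])
    scl <- apply(X[train, , drop = FALSE], 2, stats::sd)
    scl[scl <= 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  # stage 1: uniform random feature subsets
  sum1 <- numeric(p)
  cnt1 <- numeric(p)
  for (b in seq_len(config$n_boot1)) {
    rows <- draw_bootstrap(train, y, config$bootstrap)
    q <- stats::runif(1, config$q1_range[1], config$q1_range[2])
    k <- max(1L, round(q * p))
    feats <- if (k >= p) seq_len(p) else sample.int(p, k)
    fit <- subsample_lasso(X, y, rows, feats, config)
    sum1 <- sum1 + fit$beta
    cnt1[feats] <- cnt1[feats] + 1
  }
  imp1 <- if (config$average_over_appearances) {
    ifelse(cnt1 > 0, sum1 / pmax(cnt1, 1), 0)
  } else {
    sum1 / config$n_boot1
  }
  # stage 2: feature subsets drawn proportional to stage-1 importance
  w <- if (config$signed_importance) pmax(imp1, 0) else abs(imp1)
  if (all(w == 0)) w <- rep(1, p)   # uniform fallback
  k2 <- max(1L, round(config$q2 * p))
  if (sum(w > 0) < k2) {
    # not enough positively weighted features to fill the subset: remaining
    # slots are drawn (almost) uniformly from the zero-importance features
    w[w == 0] <- min(w[w > 0]) * 1e-6
  }
  sum2 <- numeric(p)
  cnt2 <- numeric(p)
  int2 <- 0
  for (b in seq_len(config$n_boot2)) {
    rows <- draw_bootstrap(train, y, config$bootstrap)
    feats <- if (k2 >= p) seq_len(p)
             else sample.int(p, k2, prob = w)
    fit <- subsample_lasso(X, y, rows, feats, config)
    sum2 <- sum2 + fit$beta
    cnt2[feats] <- cnt2[feats] + 1
    int2 <- int2 + fit$intercept
  }
  beta <- if (config$average_over_appearances) {
    ifelse(cnt2 > 0, sum2 / pmax(cnt2, 1), 0)
  } else {
    sum2 / config$n_boot2
  }
  list(beta = beta, intercept = int2 / config$n_boot2, stage1 = imp1)
}

#' Fit the random-lasso immunological age model
#'
#' Runs `n_splits` outer train-test splits; within each, stage 1 averages
#' lasso coefficients over bootstraps fit on 15-20% random feature subsets,
#' and stage 2 averages another round of bootstrapped lassos whose feature
#' subsets (10% of features) are drawn with probability proportional to the
#' absolute stage-1 importance. Features absent from a bootstrap's subset
#' contribute a coefficient of 0 to the average. The final importance score
#' (also the final coefficient vector) averages the per-split averages.
#'
#' The whole procedure is a pure function of `(X, y, config)`: rerunning
#' with the same seed reproduces importances bit for bit.
#'
#' @param X Standardized subjects x features matrix (no missing values).
#' @param y Response (chronological age, years).
#' @param config A [random_lasso_config()].
#' @return Object of class `random_lasso`: list with `importance` (named
#'   per-feature score = averaged coefficients), `intercept`, `cutoff`
#'   (`NA` until [estimate_cutoff()] is run), `retained`, `r2_train`,
#'   `r2_test` (per-split averages), and `config`.
#' @export
random_lasso <- function(X, y, config = random_lasso_config()) {
  stopifnot(nrow(X) == length(y), !anyNA(X))
  set.seed(config$seed)
  n <- nrow(X)
  p <- ncol(X)
  beta_sum <- numeric(p)
  int_sum <- 0
  r2_tr <- r2_te <- rep(NA_real_, config$n_splits)
  for (s in seq_len(config$n_splits)) {
    n_test <- round(config$test_fraction * n)
    test <- if (n_test > 0) sample.int(n, n_test) else integer(0)
    train <- setdiff(seq_len(n), test)
    fit <- random_lasso_split(X, y, train, config)
    beta_sum <- beta_sum + fit$beta
    int_sum <- int_sum + fit$intercept
    pred_tr <- fit$intercept + drop(X[train, , drop = FALSE] %*% fit$beta)
    r2_tr[s] <- 1 - sum((y[train] - pred_tr)^2) / sum((y[train] - mean(y[train]))^2)
    if (n_test > 0) {
      pred_te <- fit$intercept + drop(X[test, , drop = FALSE] %*% fit$beta)
      r2_te[s] <- 1 - sum((y[test] - pred_te)^2) / sum((y[test] - mean(y[test]))^2)
    }
  }
  importance <- beta_sum / config$n_splits
  names(importance) <- colnames(X) %||% as.character(seq_len(p))
  structure(list(
    importance = importance, intercept = int_sum / config$n_splits,
    cutoff = NA_real_, retained = names(importance)[importance != 0],
    r2_train = mean(r2_tr), r2_test = mean(r2_te),
    config = config
  ), class = "random_lasso")
}

# internal: OLS RMSE helper with rank-deficiency tolerance
ols_rmse <- function(Xtr, ytr, Xte, yte) {
  if (ncol(Xtr) == 0) return(sqrt(mean((yte - mean(ytr))^2)))
  fit <- stats::lm.fit(cbind(1, Xtr), ytr)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  pred <- drop(cbind(1, Xte) %*% co)
  sqrt(mean((yte - pred)^2))
}

#' Estimate the importance-score cutoff by repeated cross-validation
#'
#' For each candidate cutoff on a grid over the sorted absolute importance
#' scores, refits an ordinary linear model on the features whose absolute
#' importance exceeds the cutoff and records the cross-validated RMSE. Per
#' repeat, a cutoff is chosen from the RMSE-versus-cutoff curve; the final
#' cutoff is the mean of the per-repeat choices, and the model's retained
#' set becomes the features with `|importance| > cutoff`.
#'
#' Two per-repeat selection rules are available. `"one_se"` (the default)
#' takes the largest cutoff whose mean RMSE across folds is within one
#' standard error of the minimum, with the standard error computed from the
#' paired per-fold differences against the minimizer (the folds are shared
#' across candidates, so the paired comparison discounts the common
#' fold-to-fold variation); it targets the parsimonious shoulder of the
#' curve and is markedly more stable when the curve is flat near its
#' minimum, which is typical here because dropping a handful of weakly
#' spurious features barely moves the CV error.
#' `"elbow"` locates, per fold, the point of maximum perpendicular distance
#' from the chord joining the curve's endpoints ([find_elbow()]; ties,
#' including a perfectly flat curve, resolve to the largest cutoff) and
#' averages over folds and repeats.
#'
#' @param model A fitted `random_lasso`.
#' @param X,y The data the model was trained on.
#' @param cutoff_rule `"one_se"` or `"elbow"` (see Details).
#' @param max_candidates Cap on the cutoff grid size.
#' @return The `random_lasso` model with `cutoff` and `retained` filled in,
#'   plus a `cutoff_curve` (mean RMSE per candidate, for diagnostics).
#' @export
estimate_cutoff <- function(model, X, y, cutoff_rule = c("one_se", "elbow"),
                            max_candidates = 40L) {
  stopifnot(inherits(model, "random_lasso"))
  cutoff_rule <- match.arg(cutoff_rule)
  config <- model$config
  imp <- abs(model$importance)
  cand <- sort(unique(c(0, imp)))
  if (length(cand) < 2) stop("need at least 2 candidate cutoffs", call. = FALSE)
  if (length(cand) > max_candidates) {
    cand <- cand[unique(round(seq(1, length(cand), length.out = max_candidates)))]
  }
  sets <- lapply(cand, function(ct) which(imp > ct))
  n <- nrow(X)
  cuts <- numeric(0)
  rmse_sum <- numeric(length(cand))
  for (r in seq_len(config$cv_repeats)) {
    folds <- sample(rep_len(seq_len(config$cv_folds), n))
    M <- vapply(seq_len(config$cv_folds), function(f) {
      te <- which(folds == f)
      tr <- which(folds != f)
      vapply(sets, function(js) {
        ols_rmse(X[tr, js, drop = FALSE], y[tr], X[te, js, drop = FALSE], y[te])
      }, numeric(1))
    }, numeric(length(cand)))          # candidates x folds
    rmse_sum <- rmse_sum + rowMeans(M)
    if (cutoff_rule == "one_se") {
      mu <- rowMeans(M)
      imin <- which.min(mu)
      # paired SE: fold-to-fold variation is common across candidates (the
      # folds are shared), so the relevant uncertainty is that of the
      # per-fold RMSE *differences* against the minimizer
      ok <- vapply(seq_along(cand), function(i) {
        d <- M[i, ] - M[imin, ]
        mean(d) <= stats::sd(d) / sqrt(config$cv_folds) + 1e-12
      }, logical(1))
      cuts <- c(cuts, cand[max(which(ok))])
    } else {
      cuts <- c(cuts, vapply(seq_len(ncol(M)), function(f) {
        cand[find_elbow(cand, M[, f])]
      }, numeric(1)))
    }
  }
  model$cutoff <- mean(cuts)
  model$retained <- names(model$importance)[imp > model$cutoff]
  model$cutoff_curve <- data.frame(cutoff = cand,
                                   rmse = rmse_sum / config$cv_repeats)
  model
}

#' Predict immunological age
#'
#' The affine map `intercept + X beta` over the model's retained features
#' (all nonzero-importance features if no cutoff has been estimated).
#'
#' @param object A `random_lasso` model.
#' @param X_new Preprocessed subjects x features matrix (same transform as
#'   training); must contain every retained feature column.
#' @param ... Unused.
#' @return Numeric vector of predicted ages.
#' @export
predict.random_lasso <- function(object, X_new, ...) {
  feats <- object$retained
  if (!is.null(colnames(X_new))) {
    miss <- setdiff(feats, colnames(X_new))
    if (length(miss)) {
      stop("missing retained feature column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  beta <- object$importance[feats]
  drop(object$intercept + X_new[, feats, drop = FALSE] %*% beta)
}

#' @rdname predict.random_lasso
#' @param model A `random_lasso` model.
#' @export
predict_age <- function(model, X_new) predict.random_lasso(model, X_new)

#' Train the immune age model on a cohort
#'
#' Convenience wrapper: median-imputes and z-scales the cohort's features
#' (no log transform on this path), trains the random lasso on the reference
#' group (unaffected controls by default), estimates the importance cutoff,
#' and returns the model together with the fitted transform and predictions
#' for every subject.
#'
#' @param cohort A `cohort` object.
#' @param config A [random_lasso_config()].
#' @param train_group Group(s) used for training.
#' @param cutoff Estimate the importance cutoff (repeated CV)?
#' @return List of class `immune_age_model`: `model` (random_lasso),
#'   `transform` (transform_spec), `predicted` (ages for all subjects),
#'   `train_rows`.
#' @export
immune_age_model <- function(cohort, config = random_lasso_config(),
                             train_group = "CTR", cutoff = TRUE) {
  spec <- fit_transform(cohort, log_transform = FALSE)
  X <- apply_transform(spec, cohort)
  train <- which(cohort$group %in% train_group)
  model <- random_lasso(X[train, , drop = FALSE], cohort$age[train], config)
  if (cutoff) {
    model <- estimate_cutoff(model, X[train, , drop = FALSE], cohort$age[train])
  }
  structure(list(
    model = model, transform = spec,
    predicted = predict.random_lasso(model, X),
    train_rows = train
  ), class = "immune_age_model")
}

#' Residual-age analyses of predicted versus chronological age
#'
#' Restricted to subjects under `age_ceiling` years: (i) regresses predicted
#' age on chronological age and extracts residuals; (ii) estimates the
#' T1D-versus-unaffected contrast (years) from a linear model of predicted
#' age on chronological age plus a disease indicator; (iii) fits a
#' multivariable model of predicted age (or the residuals) on standardized
#' covariates, returning standardized coefficients with p values. A
#' piecewise linear fit of predicted on chronological age with a fixed break
#' (default 30 years) is computed on all subjects.
#'
#' @param predicted Predicted ages, one per cohort subject.
#' @param cohort The `cohort`.
#' @param covariates Covariate columns used in the multivariable model.
#' @param age_ceiling Analysis restricted to subjects younger than this.
#' @param break_age Break point of the piecewise fit.
#' @param response `"predicted"` (default) or `"residual"` as the
#'   multivariable response.
#' @return Object of class `residual_age_result`: list with `residuals`
#'   (per analyzed subject), `contrast` (estimate, se, p), `coefficients`
#'   (standardized multivariable table), `piecewise` (slopes before/after
#'   the break), and `rows` (analyzed subject indices).
#' @export
residual_age_analysis <- function(predicted, cohort,
                                  covariates = c("bmi_pct", "hba1c", "glucose",
                                                 "duration", "grs"),
                                  age_ceiling = 30, break_age = 30,
                                  response = c("predicted", "residual")) {
  response <- match.arg(response)
  stopifnot(length(predicted) == length(cohort$age))
  rows <- which(cohort$age < age_ceiling & cohort$group %in% c("CTR", "REL", "T1D"))
  a <- cohort$age[rows]
  pa <- predicted[rows]
  ref <- stats::lm(pa ~ a)
  r <- stats::residuals(ref)
  t1d <- as.numeric(cohort$group[rows] == "T1D")
  cfit <- stats::lm(pa ~ a + t1d)
  cs <- summary(cfit)$coefficients
  contrast <- list(estimate = cs["t1d", 1], se = cs["t1d", 2], p = cs["t1d", 4])
  # multivariable model on standardized covariates
  Z <- list(age = as.numeric(scale(a)))
  for (cv in covariates) {
    v <- cohort$covariates[rows, cv]
    if (is.factor(v)) v <- as.numeric(v) - 1
    if (stats::sd(v) == 0) {
      warning("covariate ", cv, " has zero variance; dropped")
      next
    }
    Z[[cv]] <- as.numeric(scale(v))
  }
  Z <- as.data.frame(Z)
  yresp <- if (response == "predicted") pa else r
  mfit <- stats::lm(yresp ~ ., data = Z)
  coefs <- summary(mfit)$coefficients
  # piecewise fit on all subjects
  a_all <- cohort$age
  hinge <- pmax(a_all - break_age, 0)
  pw <- stats::lm(predicted ~ a_all + hinge)
  pwc <- stats::coef(pw)
  structure(list(
    residuals = r, contrast = contrast,
    coefficients = data.frame(
      term = rownames(coefs), beta = coefs[, 1], se = coefs[, 2], p = coefs[, 4],
      row.names = NULL
    ),
    piecewise = list(break_age = break_age, slope_before = unname(pwc["a_all"]),
                     slope_after = unname(pwc["a_all"] + pwc["hinge"])),
    rows = rows
  ), class = "residual_age_result")
}

#' Serialize a random-lasso model to / from JSON
#'
#' @param x An `immune_age_model` or `random_lasso`.
#' @param path File path.
#' @return `write_immune_age_model()` returns `path` invisibly.
#' @export
write_immune_age_model <- function(x, path) {
  if (inherits(x, "immune_age_model")) {
    obj <- list(model = unclass_model(x$model), transform = unclass(x$transform))
  } else {
    obj <- list(model = unclass_model(x), transform = NULL)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_model <- function(m) {
  list(importance = as.list(m$importance), intercept = m$intercept,
       cutoff = m$cutoff, retained = m$retained,
       r2_train = m$r2_train, r2_test = m$r2_test,
       config = unclass(m$config))
}

#' @rdname write_immune_age_model
#' @export
read_immune_age_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$model
  model <- structure(list(
    importance = unlist(m$importance), intercept = m$intercept,
    cutoff = m$cutoff %||% NA_real_, retained = m$retained,
    r2_train = m$r2_train, r2_test = m$r2_test,
    config = structure(m$config, class = "random_lasso_config")
  ), class = "random_lasso")
  if (!is.null(obj$transform)) {
    structure(list(model = model,
                   transform = structure(obj$transform, class = "transform_spec"),
                   predicted = NULL, train_rows = NULL),
              class = "immune_age_model")
  } else {
    model
  }
}
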
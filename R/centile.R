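# Weighted distributional regression over age (GAMLSS-style) producing
# per-subject, per-feature age-corrected centiles. Per feature: location is
# a natural cubic spline of age (df 3; log link under BCT), log scale a
# lower-df spline of age (df 2), and for the BCT family the power nu and the
# t degrees of freedom tau are constant in age. Fitting maximizes the
# weight-multiplied log-likelihood directly (optim / L-BFGS-B).

#' Route a feature to the BCT or normal family by skewness
#'
#' Features whose adjusted Fisher-Pearson sample skewness exceeds the cutoff
#' are fit with the Box-Cox t distribution, the rest with the normal
#' distribution, unless the feature appears in the explicit override list
#' (which exists because empirical routing occasionally misassigns a
#' borderline feature).
#'
#' @param values Observed feature values (`NA`s dropped; at least 30).
#' @param feature Feature id used to look up overrides.
#' @param overrides Named character vector, e.g. `c(F010 = "NO")`.
#' @param skew_cutoff Skewness threshold (default 0.5).
#' @return `"BCT"` or `"NO"`.
#' @export
route_family <- function(values, feature = NULL, overrides = NULL,
                         skew_cutoff = 0.5) {
  if (!is.null(feature) && !is.null(overrides) && feature %in% names(overrides)) {
    return(match.arg(overrides[[feature]], c("BCT", "NO")))
  }
  values <- values[!is.na(values)]
  if (length(values) < 30) stop("need at least 30 observed values", call. = FALSE)
  if (sample_skewness(values) > skew_cutoff) "BCT" else "NO"
}

#' Observation weights over age
#'
#' Relative weights countering the age-density imbalance of the reference
#' population: ages strictly below 10 years get weight 10, ages strictly
#' above 70 years weight 0.1, all other ages weight 1.
#'
#' @param ages Ages in years.
#' @param young_age,young_weight,old_age,old_weight The rule's thresholds
#'   and weights.
#' @return Numeric weight vector.
#' @export
assign_weights <- function(ages, young_age = 10, young_weight = 10,
                           old_age = 70, old_weight = 0.1) {
  w <- rep(1, length(ages))
  w[ages < young_age] <- young_weight
  w[ages > old_age] <- old_weight
  w
}

# internal: natural-spline basis spec that can be re-evaluated at new ages
make_basis <- function(ages, df) {
  B <- splines::ns(ages, df = df)
  list(df = df, knots = as.numeric(attr(B, "knots")),
       boundary = as.numeric(attr(B, "Boundary.knots")))
}

eval_basis <- function(spec, ages) {
  kn <- if (length(spec$knots)) spec$knots else NULL
  splines::ns(ages, knots = kn, Boundary.knots = spec$boundary)
}

# internal: unpack parameter vector -> per-subject distribution parameters
centile_pars <- function(theta, Bmu, Bsig, family) {
  pmu <- ncol(Bmu) + 1
  psig <- ncol(Bsig) + 1
  eta_mu <- drop(cbind(1, Bmu) %*% theta[seq_len(pmu)])
  eta_sig <- drop(cbind(1, Bsig) %*% theta[pmu + seq_len(psig)])
  mu <- if (family == "BCT") exp(eta_mu) else eta_mu
  sigma <- exp(eta_sig)
  if (family == "BCT") {
    list(mu = mu, sigma = sigma, nu = theta[pmu + psig + 1],
         tau = exp(theta[pmu + psig + 2]))
  } else {
    list(mu = mu, sigma = sigma)
  }
}

centile_negloglik <- function(theta, y, Bmu, Bsig, w, family) {
  pr <- centile_pars(theta, Bmu, Bsig, family)
  ll <- if (family == "BCT") {
    if (any(!is.finite(pr$mu)) || any(pr$mu <= 0)) return(1e10)
    dbct(y, pr$mu, pr$sigma, pr$nu, pr$tau, log = TRUE)
  } else {
    stats::dnorm(y, pr$mu, pr$sigma, log = TRUE)
  }
  out <- -sum(w * ll)
  if (!is.finite(out)) 1e10 else out
}

#' Fit a weighted age-centile model for one feature
#'
#' Maximizes the weight-multiplied log-likelihood of the routed family with
#' location a natural cubic spline of age (df `mu_df`; log link for BCT),
#' log scale a spline of age (df `sigma_df`), and — for BCT — constant power
#' and degrees-of-freedom parameters. Values are shifted by a constant to
#' ensure positivity when the BCT family requires it. On convergence
#' failure the fit is retried unweighted (all weights 1); if that also
#' fails, an error with diagnostics is raised.
#'
#' @param values Feature values (missing entries dropped pairwise).
#' @param ages Ages in years.
#' @param weights Observation weights; default from [assign_weights()].
#' @param family `"BCT"`, `"NO"`, or `NULL` to route by skewness.
#' @param mu_df,sigma_df Spline df for the location and log-scale curves.
#' @param feature Optional feature id carried in the model.
#' @return Object of class `centile_model`.
#' @export
fit_centile_model <- function(values, ages, weights = NULL, family = NULL,
                              mu_df = 3, sigma_df = 2, feature = NULL) {
  ok <- !is.na(values) & !is.na(ages)
  y <- values[ok]
  a <- ages[ok]
  w <- (weights %||% assign_weights(ages))[ok]
  family <- family %||% route_family(y, feature = feature)
  shift <- 0
  if (family == "BCT" && min(y) <= 0) {
    shift <- -min(y) + 0.001 * max(diff(range(y)), 1)
    y <- y + shift
  }
  mu_basis <- make_basis(a, mu_df)
  sig_basis <- make_basis(a, sigma_df)
  Bmu <- eval_basis(mu_basis, a)
  Bsig <- eval_basis(sig_basis, a)

  start_fit <- function(yy) {
    fit <- stats::lm.wfit(cbind(1, Bmu), yy, w)
    res <- yy - fit$fitted.values
    s0 <- sqrt(sum(w * res^2) / sum(w))
    list(beta = fit$coefficients, lsig = log(max(s0, 1e-6)))
  }
  if (family == "BCT") {
    st <- start_fit(log(y))
    theta0 <- c(st$beta, st$lsig, rep(0, ncol(Bsig)), 0, log(10))
    lower <- c(rep(-Inf, ncol(Bmu) + 1), rep(-12, ncol(Bsig) + 1), -5, log(1.01))
    upper <- c(rep(Inf, ncol(Bmu) + 1), rep(5, ncol(Bsig) + 1), 5, log(1e4))
  } else {
    st <- start_fit(y)
    theta0 <- c(st$beta, st$lsig, rep(0, ncol(Bsig)))
    lower <- c(rep(-Inf, ncol(Bmu) + 1), rep(-12, ncol(Bsig) + 1))
    upper <- c(rep(Inf, ncol(Bmu) + 1), rep(12, ncol(Bsig) + 1))
  }

  run_optim <- function(wts) {
    tryCatch(
      stats::optim(theta0, centile_negloglik, y = y, Bmu = Bmu, Bsig = Bsig,
                   w = wts, family = family, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 400, factr = 1e4)),
      error = function(e) list(convergence = 99L, message = conditionMessage(e))
    )
  }
  opt <- run_optim(w)
  weighted <- TRUE
  if (opt$convergence != 0) {
    opt2 <- run_optim(rep(1, length(y)))
    if (opt2$convergence == 0) {
      opt <- opt2
      weighted <- FALSE
    } else {
      stop("centile model did not converge for feature ",
           feature %||% "<unnamed>", " (family ", family, "): code ",
           opt$convergence, " / ", opt2$convergence, call. = FALSE)
    }
  }
  theta <- opt$par
  pmu <- ncol(Bmu) + 1
  psig <- ncol(Bsig) + 1
  structure(list(
    feature = feature, family = family, shift = shift,
    mu_coef = theta[seq_len(pmu)], sigma_coef = theta[pmu + seq_len(psig)],
    nu = if (family == "BCT") theta[pmu + psig + 1] else NA_real_,
    tau = if (family == "BCT") exp(theta[pmu + psig + 2]) else NA_real_,
    mu_basis = mu_basis, sigma_basis = sig_basis,
    age_range = range(a), weighted = weighted,
    loglik = -opt$value
  ), class = "centile_model")
}

#' Evaluate the fitted distribution parameters at given ages
#'
#' @param model A `centile_model`.
#' @param ages Ages in years (within the fitted range).
#' @return Data frame with one row per age: mu, sigma (and nu, tau for BCT).
#' @export
centile_params <- function(model, ages) {
  Bmu <- eval_basis(model$mu_basis, ages)
  Bsig <- eval_basis(model$sigma_basis, ages)
  eta_mu <- drop(cbind(1, Bmu) %*% model$mu_coef)
  sigma <- exp(drop(cbind(1, Bsig) %*% model$sigma_coef))
  mu <- if (model$family == "BCT") exp(eta_mu) else eta_mu
  data.frame(age = ages, mu = mu, sigma = sigma, nu = model$nu, tau = model$tau)
}

#' Age-corrected centile of a value
#'
#' The CDF of the fitted family at the parameters predicted for the
#' subject's age, clipped to `[eps, 1 - eps]`. For any fixed age the map
#' value -> centile is strictly increasing.
#'
#' @param model A `centile_model`.
#' @param age Age(s) in years.
#' @param value Feature value(s), same length as `age` (or one of the two
#'   of length 1).
#' @param extrapolate If `FALSE` (default), ages outside the fitted range
#'   raise an error; if `TRUE`, they are clamped to the boundary parameters.
#' @param eps Clipping bound.
#' @return Centiles in (0, 1).
#' @export
centile <- function(model, age, value, extrapolate = FALSE, eps = 1e-6) {
  if (any(age < model$age_range[1] | age > model$age_range[2])) {
    if (!extrapolate) {
      stop("age outside fitted range [", round(model$age_range[1], 2), ", ",
           round(model$age_range[2], 2), "]; set extrapolate = TRUE to clamp",
           call. = FALSE)
    }
    age <- pmin(pmax(age, model$age_range[1]), model$age_range[2])
  }
  pr <- centile_params(model, age)
  v <- value + model$shift
  q <- if (model$family == "BCT") {
    v <- pmax(v, eps * pmax(pr$mu, 1))   # guard: BCT support is y > 0
    pbct(v, pr$mu, pr$sigma, pr$nu[1], pr$tau[1])
  } else {
    stats::pnorm(v, pr$mu, pr$sigma)
  }
  pmin(pmax(q, eps), 1 - eps)
}

#' Fit centile models for every feature of a cohort
#'
#' Models are fit on the reference population (by default the AAb-negative
#' CTR and REL groups) with the age-density weights of [assign_weights()].
#'
#' @param cohort A `cohort`.
#' @param reference_groups Groups composing the reference population.
#' @param features Feature ids to fit (default all).
#' @param overrides Family overrides passed to [route_family()].
#' @param weights Optional weights (length = reference subjects).
#' @return A named list of `centile_model`s, class `centile_model_set`.
#' @export
fit_centile_models <- function(cohort, reference_groups = c("CTR", "REL"),
                               features = NULL, overrides = NULL,
                               weights = NULL) {
  ref <- cohort$group %in% reference_groups
  features <- features %||% colnames(cohort$values)
  ages <- cohort$age[ref]
  w <- weights %||% assign_weights(ages)
  models <- lapply(features, function(f) {
    fit_centile_model(cohort$values[ref, f], ages, weights = w,
                      feature = f,
                      family = if (!is.null(overrides) && f %in% names(overrides))
                        overrides[[f]] else NULL)
  })
  names(models) <- features
  structure(models, class = "centile_model_set")
}

#' Age-corrected quantile matrix for a cohort
#'
#' Applies each feature's centile model to every subject, producing the
#' age-corrected data used by the group-comparison and classifier stages.
#' Missing raw values stay missing.
#'
#' @param models A `centile_model_set`.
#' @param cohort A `cohort`.
#' @param extrapolate Clamp out-of-range ages to the boundary parameters.
#' @return Subjects x features matrix of centiles in (0, 1).
#' @export
centile_transform <- function(models, cohort, extrapolate = TRUE) {
  feats <- names(models)
  out <- matrix(NA_real_, nrow(cohort$values), length(feats),
                dimnames = list(rownames(cohort$values), feats))
  for (f in feats) {
    v <- cohort$values[, f]
    ok <- !is.na(v)
    out[ok, f] <- centile(models[[f]], cohort$age[ok], v[ok],
                          extrapolate = extrapolate)
  }
  out
}

#' Serialize centile models to / from JSON
#'
#' @param models A `centile_model_set`.
#' @param path File path.
#' @export
write_centile_models <- function(models, path) {
  obj <- lapply(unclass(models), function(m) {
    m$age_range <- as.numeric(m$age_range)
    unclass(m)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_centile_models
#' @export
read_centile_models <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(obj, function(m) {
    m$mu_coef <- unlist(m$mu_coef)
    m$sigma_coef <- unlist(m$sigma_coef)
    m$mu_basis$knots <- unlist(m$mu_basis$knots)
    m$mu_basis$boundary <- unlist(m$mu_basis$boundary)
    m$sigma_basis$knots <- unlist(m$sigma_basis$knots)
    m$sigma_basis$boundary <- unlist(m$sigma_basis$boundary)
    m$age_range <- unlist(m$age_range)
    structure(m, class = "centile_model")
  })
  structure(models, class = "centile_model_set")
}
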
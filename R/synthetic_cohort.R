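#' Configuration for the synthetic immunophenotyping cohort generator
#'
#' Describes a cross-sectional cohort with the statistical structure the
#' downstream pipeline assumes: four clinical groups (CTR, REL, RSK, T1D), a
#' bimodal age distribution, features whose age trajectories follow one of
#' four canonical shapes (increasing linear, upward parabolic, decreasing
#' linear, stable), a fraction of right-skewed intensity-like readouts, a
#' per-cluster disease shift and/or an effective-age acceleration applied to
#' the T1D group, and missing-completely-at-random dropout.
#'
#' @param n_per_group Named integer vector of subjects per clinical group;
#'   names must be among `CTR`, `REL`, `RSK`, `T1D`.
#' @param age_components Data frame with columns `mean`, `sd`, `weight`
#'   (years, years, mixture weight) describing the mixture from which ages
#'   are drawn; weights must sum to 1.
#' @param age_range Length-2 numeric, inclusive age bounds within [2, 83].
#' @param n_features_per_cluster Length-4 integer vector: number of features
#'   with increasing-linear, upward-parabolic, decreasing-linear, and stable
#'   age-trajectory shapes.
#' @param effect_size_range Length-2 numeric: per-feature trajectory
#'   amplitude is drawn uniformly from this range, on the standardized
#'   latent scale (stable-cluster features get amplitude 0).
#' @param noise_sd Residual standard deviation on the standardized latent
#'   scale.
#' @param skew_fraction Fraction of features generated as right-skewed
#'   intensity readouts (log-normal latent scale); the rest are bounded
#'   percentage readouts.
#' @param disease_shift Length-4 numeric: additive mean offset (standardized
#'   latent scale) applied to T1D subjects, per trajectory cluster.
#' @param aging_acceleration_years Extra effective age (years) applied to
#'   T1D subjects' age-dependent features (clusters 1-3).
#' @param missing_rate MCAR missingness fraction; must be below 0.0503, the
#'   per-feature missingness ceiling the analysis pipeline assumes.
#' @param group_age_weights Optional named list mapping a group to its own
#'   mixture-weight vector (same length as `nrow(age_components)`), so that
#'   groups may share mixture components but differ in their proportions.
#' @param latent_factor_sd Standard deviation of an optional shared
#'   per-subject latent factor loading on all features (default 0, i.e.
#'   features are independent given age and group).
#' @param seed Integer seed; all randomness in [generate_cohort()] flows
#'   from this single seed.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_per_group = c(CTR = 252, REL = 310, RSK = 24, T1D = 240),
                          age_components = data.frame(
                            mean = c(12, 42), sd = c(4, 11), weight = c(0.55, 0.45)
                          ),
                          age_range = c(2, 83),
                          n_features_per_cluster = c(66, 20, 74, 12),
                          effect_size_range = c(0.5, 1.5),
                          noise_sd = 1,
                          skew_fraction = 0.2,
                          disease_shift = c(0.3, 0, -0.2, 0),
                          aging_acceleration_years = 3,
                          missing_rate = 0.03,
                          group_age_weights = NULL,
                          latent_factor_sd = 0,
                          seed = 1L) {
  groups <- c("CTR", "REL", "RSK", "T1D")
  n_per_group <- n_per_group[intersect(groups, names(n_per_group))]
  check_fields(
    n_per_group = length(n_per_group) >= 1 && all(names(n_per_group) %in% groups) &&
      all(n_per_group >= 0) && all(n_per_group == round(n_per_group)),
    age_components = is.data.frame(age_components) &&
      all(c("mean", "sd", "weight") %in% names(age_components)) &&
      all(age_components$sd > 0) && all(age_components$weight >= 0) &&
      abs(sum(age_components$weight) - 1) < 1e-8,
    age_range = length(age_range) == 2 && age_range[1] < age_range[2] &&
      age_range[1] >= 2 && age_range[2] <= 83,
    n_features_per_cluster = length(n_features_per_cluster) == 4 &&
      all(n_features_per_cluster >= 0) && sum(n_features_per_cluster) >= 1,
    effect_size_range = length(effect_size_range) == 2 &&
      effect_size_range[1] >= 0 && effect_size_range[1] <= effect_size_range[2],
    noise_sd = length(noise_sd) == 1 && noise_sd >= 0,
    skew_fraction = length(skew_fraction) == 1 && skew_fraction >= 0 && skew_fraction <= 1,
    disease_shift = length(disease_shift) == 4 && all(is.finite(disease_shift)),
    aging_acceleration_years = length(aging_acceleration_years) == 1 &&
      is.finite(aging_acceleration_years),
    missing_rate = length(missing_rate) == 1 && missing_rate >= 0 && missing_rate < 0.0503,
    latent_factor_sd = length(latent_factor_sd) == 1 && latent_factor_sd >= 0,
    seed = length(seed) == 1 && is.finite(seed)
  )
  if (!is.null(group_age_weights)) {
    check_fields(group_age_weights = is.list(group_age_weights) &&
      all(names(group_age_weights) %in% groups) &&
      all(vapply(group_age_weights, function(w) {
        length(w) == nrow(age_components) && all(w >= 0) && abs(sum(w) - 1) < 1e-8
      }, logical(1))))
  }
  structure(list(
    n_per_group = n_per_group, age_components = age_components,
    age_range = age_range, n_features_per_cluster = n_features_per_cluster,
    effect_size_range = effect_size_range, noise_sd = noise_sd,
    skew_fraction = skew_fraction, disease_shift = disease_shift,
    aging_acceleration_years = aging_acceleration_years,
    missing_rate = missing_rate, group_age_weights = group_age_weights,
    latent_factor_sd = latent_factor_sd, seed = as.integer(seed)
  ), class = "cohort_config")
}

# internal: canonical unit trajectory shapes on u in [-1, 1]
# 1 increasing linear, 2 upward parabolic (vertex in early adulthood, so the
# curve rises over most of the adult range), 3 decreasing linear, 4 stable
trajectory_shape <- function(u, cluster) {
  switch(cluster,
    u,
    2 * ((u + 0.4) / 1.4)^2 - 1,
    -u,
    rep(0, length(u))
  )
}

# internal: draw ages from the truncated mixture for one group
draw_ages <- function(n, config, weights) {
  if (n == 0) return(numeric(0))
  comp <- config$age_components
  lo <- config$age_range[1]
  hi <- config$age_range[2]
  out <- numeric(0)
  while (length(out) < n) {
    k <- sample.int(nrow(comp), n, replace = TRUE, prob = weights)
    a <- stats::rnorm(n, comp$mean[k], comp$sd[k])
    out <- c(out, a[a >= lo & a <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic immunophenotyping cohort
#'
#' Deterministic given `config$seed`. Each feature's noiseless latent mean
#' over age follows its assigned cluster shape, scaled by a per-feature
#' amplitude; T1D subjects receive the configured per-cluster additive shift
#' and evaluate age-dependent shapes at `age + aging_acceleration_years`.
#' Percentage-domain features are produced by logistic squashing of the
#' latent value into (0, 100) (no atoms at the bounds); skew-flagged
#' features are exponentiated onto a log-normal intensity scale so their
#' sample skewness is well above 0.5. An MCAR mask is applied last.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort`: a list with `values` (subjects x
#'   features matrix, `NA` for missing), `age`, `group` (factor), a
#'   `covariates` data frame (sex, BMI percentile, HbA1c, rested glucose,
#'   disease duration, genetic risk score), and `feature_meta` (feature id,
#'   value domain, true cluster label and amplitude — synthetic truth only).
#' @export
#' @examples
#' cfg <- cohort_config(n_per_group = c(CTR = 40, T1D = 40), seed = 7)
#' coh <- generate_cohort(cfg)
#' dim(coh$values)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- names(config$n_per_group)
  group <- factor(rep(groups, config$n_per_group),
                  levels = c("CTR", "REL", "RSK", "T1D"))
  n <- length(group)
  if (n == 0) stop("invalid configuration: n_per_group (no subjects)", call. = FALSE)

  age <- numeric(n)
  for (g in groups) {
    w <- (config$group_age_weights[[g]] %||% config$age_components$weight)
    age[group == g] <- draw_ages(sum(group == g), config, w)
  }

  p <- sum(config$n_features_per_cluster)
  cluster <- rep(1:4, config$n_features_per_cluster)
  amp <- stats::runif(p, config$effect_size_range[1], config$effect_size_range[2])
  amp[cluster == 4] <- 0
  n_skew <- round(config$skew_fraction * p)
  skewed <- logical(p)
  if (n_skew > 0) skewed[sample.int(p, n_skew)] <- TRUE
  feature <- sprintf("F%03d", seq_len(p))

  lo <- config$age_range[1]
  hi <- config$age_range[2]
  age_eff <- age + ifelse(group == "T1D", config$aging_acceleration_years, 0)
  u <- 2 * (age - lo) / (hi - lo) - 1
  u_eff <- 2 * (age_eff - lo) / (hi - lo) - 1
  lf <- if (config$latent_factor_sd > 0) stats::rnorm(n, 0, config$latent_factor_sd)
        else numeric(n)

  values <- matrix(NA_real_, n, p, dimnames = list(sprintf("S%04d", seq_len(n)), feature))
  t1d <- group == "T1D"
  ref <- if (any(!t1d)) !t1d else rep(TRUE, n)
  for (j in seq_len(p)) {
    cj <- cluster[j]
    uj <- if (cj %in% 1:3) u_eff else u   # acceleration acts on age-dependent shapes
    uj[!t1d] <- u[!t1d]
    latent <- amp[j] * trajectory_shape(uj, cj) + lf +
      stats::rnorm(n, 0, config$noise_sd)
    # standardize to the reference (non-T1D) population so that the disease
    # shift is planted in true standardized units
    s <- stats::sd(latent[ref])
    if (s > 0) latent <- (latent - mean(latent[ref])) / s
    latent <- latent + config$disease_shift[cj] * t1d
    values[, j] <- if (skewed[j]) exp(0.4 * latent + log(100))
                   else 100 * stats::plogis(0.4 * latent)
  }

  # covariates (plumbing; plausible scales, not asserted from any source)
  covariates <- data.frame(
    sex = factor(sample(c("F", "M"), n, replace = TRUE)),
    bmi_pct = 100 * stats::rbeta(n, 2, 2),
    hba1c = ifelse(t1d, stats::rnorm(n, 8, 1.3), stats::rnorm(n, 5.2, 0.3)),
    glucose = pmax(40, ifelse(t1d, stats::rnorm(n, 170, 50), stats::rnorm(n, 90, 10))),
    duration = ifelse(t1d, pmin(stats::rexp(n, 1 / 5), pmax(age - 0.5, 0)), 0),
    grs = stats::rnorm(n) + 0.6 * t1d + 0.3 * (group == "RSK") + 0.15 * (group == "REL"),
    row.names = rownames(values)
  )

  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * p) < config$missing_rate, n, p)
    values[mask] <- NA_real_
  }

  structure(list(
    values = values, age = age, group = group, covariates = covariates,
    feature_meta = data.frame(
      feature = feature,
      domain = ifelse(skewed, "intensity", "percent"),
      cluster = cluster, amplitude = amp, skewed = skewed
    ),
    config = config
  ), class = "cohort")
}

#' Generate a null cohort (no disease effect)
#'
#' As [generate_cohort()] but with `disease_shift = 0` and
#' `aging_acceleration_years = 0` forced, so group labels are exchangeable
#' by construction. Used for type-I-error and centile-uniformity checks.
#'
#' @inheritParams generate_cohort
#' @return A `cohort` object.
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  config$disease_shift <- c(0, 0, 0, 0)
  config$aging_acceleration_years <- 0
  generate_cohort(config)
}

#' @method print cohort
#' @export
print.cohort <- function(x, ...) {
  cat("synthetic immunophenotyping cohort\n")
  cat(sprintf("  subjects: %d (%s)\n", nrow(x$values),
              paste(sprintf("%s=%d", levels(x$group), table(x$group)), collapse = ", ")))
  cat(sprintf("  features: %d (%s)\n", ncol(x$values),
              paste(sprintf("cluster%d=%d", 1:4, tabulate(x$feature_meta$cluster, 4)),
                    collapse = ", ")))
  cat(sprintf("  ages: %.1f-%.1f yr; missing: %.2f%%\n",
              min(x$age), max(x$age), 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Subset a cohort by subjects
#'
#' @param cohort A `cohort`.
#' @param rows Row indices (or logical mask) of the subjects to keep.
#' @return A `cohort` with the selected subjects.
#' @export
subset_cohort <- function(cohort, rows) {
  cohort$values <- cohort$values[rows, , drop = FALSE]
  cohort$age <- cohort$age[rows]
  cohort$group <- cohort$group[rows]
  cohort$covariates <- cohort$covariates[rows, , drop = FALSE]
  cohort
}

#' Write / read a cohort as tidy CSV files
#'
#' `write_cohort()` writes `subjects.csv` (one row per subject: subject_id,
#' age, group, covariates, then one column per feature) and
#' `feature_meta.csv` into `dir`. `read_cohort()` reads them back.
#'
#' @param cohort A `cohort` object.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `cohort` object (without the generating config).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subj <- data.frame(subject_id = rownames(cohort$values), age = cohort$age,
                     group = cohort$group, cohort$covariates, cohort$values,
                     check.names = FALSE)
  utils::write.csv(subj, file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(cohort$feature_meta, file.path(dir, "feature_meta.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subj <- utils::read.csv(file.path(dir, "subjects.csv"), check.names = FALSE)
  meta <- utils::read.csv(file.path(dir, "feature_meta.csv"))
  feat_cols <- meta$feature
  values <- as.matrix(subj[, feat_cols, drop = FALSE])
  rownames(values) <- subj$subject_id
  cov_cols <- setdiff(names(subj), c("subject_id", "age", "group", feat_cols))
  covariates <- subj[, cov_cols, drop = FALSE]
  covariates$sex <- factor(covariates$sex)
  rownames(covariates) <- subj$subject_id
  structure(list(
    values = values, age = subj$age,
    group = factor(subj$group, levels = c("CTR", "REL", "RSK", "T1D")),
    covariates = covariates, feature_meta = meta, config = NULL
  ), class = "cohort")
}
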
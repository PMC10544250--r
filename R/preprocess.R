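# Preprocessing: median imputation, shifted log transform, z-scaling.
# Pipeline order is impute -> log_shift -> zscale; a fitted transform_spec is
# a pure function that can be re-applied to new subjects without refitting.

# internal: accept a cohort or a plain matrix
as_values <- function(x) {
  if (inherits(x, "cohort")) x$values
  else if (is.matrix(x)) x
  else stop("expected a cohort or a subjects x features matrix", call. = FALSE)
}

#' Median-impute missing feature values
#'
#' Replaces each missing entry by the median of the observed entries of that
#' feature (computed on `reference` rows if given), leaving observed entries
#' unchanged. The median of an even count is the mean of the two middle
#' order statistics.
#'
#' @param x A `cohort` or a subjects x features matrix.
#' @param reference Optional row indices on which to compute the medians
#'   (e.g. a training subset); defaults to all rows.
#' @return Same shape as the input values, with no missing entries.
#' @export
impute_median <- function(x, reference = NULL) {
  X <- as_values(x)
  ref <- if (is.null(reference)) seq_len(nrow(X)) else reference
  for (j in seq_len(ncol(X))) {
    obs <- X[ref, j]
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0) {
      stop("feature ", colnames(X)[j] %||% j, " has no observed values", call. = FALSE)
    }
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- stats::median(obs)
  }
  X
}

#' Shifted log transform
#'
#' Applies `log(values + shift)` with the shift chosen so the transformed
#' values are nonnegative: for a value domain that cannot fall below 0 and
#' data with `min >= 0`, the shift is 1; otherwise the shift is
#' `1 + max(0, -min(values))`, so the smallest value maps to `log(1) = 0`.
#'
#' @param values Numeric vector with no missing entries (post-imputation).
#' @param domain One of `"percent"`, `"intensity"`, `"count"` (value domains
#'   bounded below by 0) or `"real"`.
#' @return List with `values` (transformed) and `shift`.
#' @export
log_shift <- function(values, domain = c("percent", "intensity", "count", "real")) {
  domain <- match.arg(domain)
  stopifnot(!anyNA(values))
  mn <- min(values)
  nonneg <- domain != "real"
  shift <- if (nonneg && mn >= 0) 1 else 1 + max(0, -mn)
  if (any(values + shift <= 0)) stop("non-positive value after shift", call. = FALSE)
  list(values = log(values + shift), shift = shift)
}

#' Z-scale a feature vector
#'
#' Centers to mean 0 and scales to sample (n-1) standard deviation 1. When
#' `center`/`scale` are supplied (a stored transform), they are applied
#' as-is.
#'
#' @param values Numeric vector with no missing entries.
#' @param center,scale Optional stored parameters.
#' @return Standardized vector with attributes `center` and `scale`.
#' @export
zscale <- function(values, center = NULL, scale = NULL) {
  center <- center %||% mean(values)
  scale <- scale %||% stats::sd(values)
  if (!is.finite(scale) || scale <= 0) {
    stop("constant feature cannot be z-scaled", call. = FALSE)
  }
  structure((values - center) / scale, center = center, scale = scale)
}

#' Fit the preprocessing transform for a cohort
#'
#' Learns, per feature, the imputation median, the log-shift constant
#' (if `log_transform = TRUE`; the trajectory-analysis path), and the
#' z-scaling mean and standard deviation, in pipeline order
#' impute -> log_shift -> zscale. The immune-age model path uses
#' `log_transform = FALSE` (imputation and scaling only).
#'
#' @param x A `cohort` or a subjects x features matrix.
#' @param log_transform Apply the shifted log before scaling?
#' @param reference Optional row indices (e.g. training subjects) on which
#'   the medians, means and standard deviations are computed.
#' @param domains Optional character vector of per-feature value domains;
#'   defaults to the cohort's `feature_meta$domain` or `"real"`.
#' @param on_constant For a constant feature, `"error"` (default) or
#'   `"drop"` (feature removed with a warning).
#' @return An object of class `transform_spec`.
#' @export
fit_transform <- function(x, log_transform = TRUE, reference = NULL,
                          domains = NULL, on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  X <- as_values(x)
  if (is.null(domains)) {
    domains <- if (inherits(x, "cohort")) x$feature_meta$domain
               else rep("real", ncol(X))
  }
  domains <- rep_len(domains, ncol(X))
  ref <- if (is.null(reference)) seq_len(nrow(X)) else reference
  p <- ncol(X)
  med <- shift <- ctr <- scl <- rep(NA_real_, p)
  keep <- rep(TRUE, p)
  for (j in seq_len(p)) {
    obs <- X[ref, j]
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0) {
      stop("feature ", colnames(X)[j] %||% j, " has no observed values", call. = FALSE)
    }
    med[j] <- stats::median(obs)
    v <- X[ref, j]
    v[is.na(v)] <- med[j]
    if (log_transform) {
      ls <- log_shift(v, domains[j])
      shift[j] <- ls$shift
      v <- ls$values
    }
    s <- stats::sd(v)
    if (!is.finite(s) || s <= 0) {
      if (on_constant == "drop") {
        warning("dropping constant feature ", colnames(X)[j] %||% j)
        keep[j] <- FALSE
        next
      }
      stop("constant feature ", colnames(X)[j] %||% j, " cannot be z-scaled",
           call. = FALSE)
    }
    ctr[j] <- mean(v)
    scl[j] <- s
  }
  structure(list(
    feature = colnames(X) %||% as.character(seq_len(p)),
    domain = domains, impute = med, log_transform = log_transform,
    shift = shift, center = ctr, scale = scl, keep = keep
  ), class = "transform_spec")
}

#' Apply (or invert) a fitted preprocessing transform
#'
#' `apply_transform()` is a pure function of its inputs: imputation values,
#' shifts and scaling parameters are the stored ones, never refit.
#' `invert_transform()` undoes scaling and (if fitted) the shifted log,
#' returning imputed values on the original scale.
#'
#' @param spec A `transform_spec` from [fit_transform()].
#' @param x A `cohort` or matrix with the same feature columns.
#' @return A subjects x features numeric matrix.
#' @export
apply_transform <- function(spec, x) {
  X <- as_values(x)
  if (!is.null(colnames(X))) {
    missing_f <- setdiff(spec$feature[spec$keep], colnames(X))
    if (length(missing_f)) {
      stop("missing feature column(s): ", paste(missing_f, collapse = ", "),
           call. = FALSE)
    }
    X <- X[, spec$feature, drop = FALSE]
  }
  out <- X
  for (j in seq_len(ncol(X))) {
    if (!spec$keep[j]) next
    v <- X[, j]
    v[is.na(v)] <- spec$impute[j]
    if (spec$log_transform) v <- log(v + spec$shift[j])
    out[, j] <- (v - spec$center[j]) / spec$scale[j]
  }
  out[, spec$keep, drop = FALSE]
}

#' @rdname apply_transform
#' @export
invert_transform <- function(spec, x) {
  X <- as_values(x)
  out <- X
  idx <- which(spec$keep)
  for (k in seq_along(idx)) {
    j <- idx[k]
    v <- X[, k] * spec$scale[j] + spec$center[j]
    if (spec$log_transform) v <- exp(v) - spec$shift[j]
    out[, k] <- v
  }
  colnames(out) <- spec$feature[idx]
  out
}

#' Serialize a transform_spec to / from JSON
#'
#' Stores every fitted constant so the exact transform can be re-applied to
#' new subjects alongside saved model outputs.
#'
#' @param spec A `transform_spec`.
#' @param path File path.
#' @return `write_transform()` returns `path` invisibly; `read_transform()`
#'   a `transform_spec`.
#' @export
write_transform <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$log_transform <- isTRUE(obj$log_transform)
  structure(obj, class = "transform_spec")
}
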
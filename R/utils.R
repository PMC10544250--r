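#' Adjusted Fisher-Pearson sample skewness
#'
#' Skewness estimator with the small-sample adjustment factor
#' \eqn{\sqrt{n(n-1)}/(n-2)}, the convention used to route features to the
#' Box-Cox t versus normal family in [route_family()].
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @return Skewness as a single numeric value (`NA` if fewer than 3
#'   observations or zero variance).
#' @export
#' @examples
#' sample_skewness(rexp(1000)) # about 2
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(NA_real_)
  g1 <- mean((x - m)^3) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Elbow of a curve by maximum distance to the chord
#'
#' Finds the point of a curve farthest (perpendicular distance) from the
#' straight chord joining its first and last points, after rescaling both
#' axes to [0, 1]. Used to locate the knee of the RMSE-versus-cutoff curve
#' when estimating the random-lasso importance cutoff. Ties (including a
#' perfectly flat curve, where every distance is 0) resolve to the largest
#' `x`, i.e. the most parsimonious cutoff.
#'
#' @param x,y Numeric vectors of equal length (>= 2); `x` must be sorted
#'   increasing.
#' @return Index of the elbow point into `x`.
#' @export
find_elbow <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L, !is.unsorted(x))
  rng_x <- diff(range(x))
  rng_y <- diff(range(y))
  u <- if (rng_x > 0) (x - x[1]) / rng_x else rep(0, length(x))
  v <- if (rng_y > 0) (y - y[1]) / rng_y else rep(0, length(y))
  # chord from (u1,v1) to (un,vn); perpendicular distance of each point
  du <- u[length(u)] - u[1]
  dv <- v[length(v)] - v[1]
  nrm <- sqrt(du^2 + dv^2)
  d <- if (nrm > 0) abs(du * (v[1] - v) - (u[1] - u) * dv) / nrm else rep(0, length(u))
  # ties -> largest x (last index among maxima)
  max(which(d >= max(d) - 1e-12))
}

# internal: default operator
`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: stop unless all named conditions hold, naming the offender
check_fields <- function(...) {
  conds <- list(...)
  for (nm in names(conds)) {
    if (!isTRUE(conds[[nm]])) stop("invalid configuration: ", nm, call. = FALSE)
  }
  invisible(TRUE)
}
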
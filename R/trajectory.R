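# Age-trajectory modeling: per-feature cubic smoothing splines (3 effective
# degrees of freedom, the convention of stats::smooth.spline), evaluated on a
# common age grid, shape clustering, and cohort-versus-cohort comparison.

#' Default evaluation grid for age trajectories
#'
#' Ages 5 to 75 years inclusive at a 0.5-year step: fine enough that
#' crossing counts stabilize, coarse enough for speed.
#'
#' @param from,to,by Grid limits (years) and step.
#' @return Numeric vector of grid ages.
#' @export
age_grid <- function(from = 5, to = 75, by = 0.5) seq(from, to, by = by)

#' Fit a smoothing-spline age trajectory for one feature
#'
#' Fits a cubic smoothing spline of the (preprocessed) feature values on age
#' with the requested effective degrees of freedom and evaluates it on the
#' common grid.
#'
#' @param ages Ages in years (at least 10 distinct values).
#' @param values Preprocessed feature values (impute -> log-shift -> zscale).
#' @param df Target effective degrees of freedom of the smoother.
#' @param grid Evaluation grid, by default [age_grid()].
#' @param feature Optional feature id carried in the result.
#' @return An object of class `trajectory`: list with `feature`, `grid`,
#'   `values` (smoothed, on the grid), and `df` (the effective df actually
#'   used).
#' @export
fit_trajectory <- function(ages, values, df = 3, grid = age_grid(), feature = NULL) {
  stopifnot(length(ages) == length(values), !anyNA(values))
  n_distinct <- length(unique(ages))
  if (n_distinct < max(10, df + 1)) {
    stop("need at least ", max(10, df + 1), " distinct ages, got ", n_distinct,
         call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    # degenerate constant input: the smoother is the constant itself
    fit_vals <- rep(values[1], length(grid))
    edf <- 1
  } else {
    fit <- stats::smooth.spline(ages, values, df = df, cv = FALSE)
    fit_vals <- stats::predict(fit, grid)$y
    edf <- fit$df
  }
  if (!all(is.finite(fit_vals))) stop("non-finite smoothed values", call. = FALSE)
  structure(list(feature = feature, grid = grid, values = fit_vals, df = edf),
            class = "trajectory")
}

#' Fit trajectories for every feature of a preprocessed matrix
#'
#' @param X Subjects x features matrix of preprocessed values.
#' @param ages Ages in years, one per row of `X`.
#' @param df,grid As in [fit_trajectory()].
#' @return An object of class `trajectory_set`: list with `grid`, `values`
#'   (features x grid matrix of smoothed values), and `df` (per-feature
#'   effective df).
#' @export
fit_trajectories <- function(X, ages, df = 3, grid = age_grid()) {
  p <- ncol(X)
  out <- matrix(NA_real_, p, length(grid),
                dimnames = list(colnames(X), NULL))
  edf <- numeric(p)
  for (j in seq_len(p)) {
    tr <- fit_trajectory(ages, X[, j], df = df, grid = grid,
                         feature = colnames(X)[j])
    out[j, ] <- tr$values
    edf[j] <- tr$df
  }
  structure(list(grid = grid, values = out, df = edf), class = "trajectory_set")
}

# internal: grid-value matrix from a trajectory_set or matrix
traj_matrix <- function(x) {
  if (inherits(x, "trajectory_set")) x$values
  else if (is.matrix(x)) x
  else stop("expected a trajectory_set or features x grid matrix", call. = FALSE)
}

#' Initial trend of a trajectory over ages 5-15
#'
#' The mean of successive differences of the smoothed trajectory over the
#' grid points with ages in [5, 15]; positive means initially increasing,
#' negative initially decreasing.
#'
#' @param trajectory A `trajectory`, or a numeric vector of grid values (in
#'   which case `grid` must be supplied).
#' @param grid Grid ages matching the values.
#' @return Single numeric trend value.
#' @export
initial_trend <- function(trajectory, grid = NULL) {
  if (inherits(trajectory, "trajectory")) {
    grid <- trajectory$grid
    v <- trajectory$values
  } else {
    v <- trajectory
  }
  stopifnot(!is.null(grid), length(grid) == length(v))
  idx <- which(grid >= 5 & grid <= 15)
  if (length(idx) < 2) stop("grid must cover ages 5-15", call. = FALSE)
  mean(diff(v[idx]))
}

# internal: Canberra distance sum(|x - y| / (|x| + |y|)) between trajectory
# rows, with the denominator floored. The raw ratio saturates near 1
# wherever both trajectories sit close to zero (the denominator vanishes),
# which makes flat standardized trajectories look maximally distant from
# everything, including each other. Flooring the denominator at `floor`
# (standardized units) leaves distances between non-degenerate trajectory
# values untouched and lets flat trajectories cluster together.
canberra_dist <- function(M, floor = 0) {
  p <- nrow(M)
  absM <- abs(M)
  D <- matrix(0, p, p, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(p - 1)) {
    num <- abs(sweep(M[(i + 1):p, , drop = FALSE], 2, M[i, ]))
    den <- pmax(sweep(absM[(i + 1):p, , drop = FALSE], 2, absM[i, ], "+"), floor)
    den[den == 0] <- 1   # both exactly zero: no contribution
    D[i, (i + 1):p] <- D[(i + 1):p, i] <- rowSums(num / den)
  }
  stats::as.dist(D)
}

#' Cluster trajectory shapes
#'
#' Complete-linkage hierarchical clustering on Canberra distances between
#' grid-value vectors, cut to `k` clusters. The Canberra denominator is
#' floored at `floor` standardized units (default one standard
#' deviation): without the floor, grid points where two near-flat
#' trajectories both approach zero contribute ratios saturating at 1, and
#' flat trajectories end up maximally distant from one another instead of
#' forming the stable-shape cluster. Cluster labels are renumbered by
#' descending mean initial trend of their members, so the numbering is
#' deterministic and independent of feature order.
#'
#' @param trajectories A `trajectory_set` (or features x grid matrix; then
#'   supply `grid`).
#' @param k Number of clusters to cut.
#' @param grid Grid ages (taken from the trajectory_set when given).
#' @param floor Denominator floor of the Canberra ratio, in standardized
#'   trajectory units; 0 gives the textbook metric.
#' @return Object of class `trajectory_clustering`: list with `cluster`
#'   (named integer vector), `tree` (the hclust object), `metric`, and
#'   `members` (list of feature ids per cluster).
#' @export
cluster_trajectories <- function(trajectories, k = 4, grid = NULL, floor = 1) {
  M <- traj_matrix(trajectories)
  if (inherits(trajectories, "trajectory_set")) grid <- trajectories$grid
  if (!all(is.finite(M))) stop("non-finite trajectory values", call. = FALSE)
  d <- canberra_dist(M, floor = floor)
  tree <- stats::hclust(d, method = "complete")
  raw <- stats::cutree(tree, k = k)
  trends <- apply(M, 1, initial_trend, grid = grid)
  mean_trend <- tapply(trends, raw, mean)
  relabel <- order(mean_trend, decreasing = TRUE) # new label 1 = steepest initial rise
  map <- integer(k)
  map[relabel] <- seq_len(k)
  cluster <- map[raw]
  names(cluster) <- rownames(M)
  structure(list(
    cluster = cluster, tree = tree, metric = "canberra",
    members = split(names(cluster), cluster)
  ), class = "trajectory_clustering")
}

#' Count strict sign changes between two trajectories
#'
#' Number of strict sign changes of `A - B` along the grid. Exact zeros are
#' collapsed: a touch without a sign change does not count as a crossing.
#'
#' @param trajA,trajB Numeric vectors of grid values on identical grids (or
#'   `trajectory` objects).
#' @return Nonnegative integer crossing count.
#' @export
count_crossings <- function(trajA, trajB) {
  a <- if (inherits(trajA, "trajectory")) trajA$values else trajA
  b <- if (inherits(trajB, "trajectory")) trajB$values else trajB
  stopifnot(length(a) == length(b))
  s <- sign(a - b)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

#' Compare cohort trajectories cluster by cluster
#'
#' For each feature, the trajectory shift is the mean over the grid of
#' (cohort B - cohort A); for each cluster, a one-sample two-sided t test of
#' the member shifts against 0 summarizes whether cohort B sits above or
#' below cohort A. Initial trend signs, crossing counts, and a
#' sampling-variation flag (differing initial trends that cross at least
#' `crossing_threshold` times) are reported per feature.
#'
#' @param fitsA,fitsB `trajectory_set`s for the two cohorts on identical
#'   grids (A is the reference whose clustering is used); plain features x
#'   grid matrices are accepted if `grid` is supplied.
#' @param clustering A `trajectory_clustering` computed from cohort A.
#' @param crossing_threshold Crossing count at or above which a discordant
#'   initial trend is flagged as sampling variation.
#' @param grid Grid ages (taken from the trajectory sets when given).
#' @return Object of class `trajectory_comparison`: list with `features`
#'   (data frame: feature, cluster, shift, trend A/B, crossings, flag) and
#'   `clusters` (data frame: cluster, n, mean shift, t statistic, p value;
#'   p is `NA` for clusters with fewer than 2 members).
#' @export
compare_trajectories <- function(fitsA, fitsB, clustering, crossing_threshold = 2,
                                 grid = NULL) {
  A <- traj_matrix(fitsA)
  B <- traj_matrix(fitsB)
  stopifnot(identical(dim(A), dim(B)))
  if (inherits(fitsA, "trajectory_set") && inherits(fitsB, "trajectory_set")) {
    stopifnot(isTRUE(all.equal(fitsA$grid, fitsB$grid)))
  }
  if (inherits(fitsA, "trajectory_set")) grid <- fitsA$grid
  stopifnot(!is.null(grid))
  cl <- clustering$cluster
  shift <- rowMeans(B - A)
  trendA <- apply(A, 1, initial_trend, grid = grid)
  trendB <- apply(B, 1, initial_trend, grid = grid)
  crossings <- vapply(seq_len(nrow(A)), function(j) count_crossings(A[j, ], B[j, ]),
                      integer(1))
  feat <- data.frame(
    feature = rownames(A) %||% as.character(seq_len(nrow(A))),
    cluster = as.integer(cl),
    shift = shift,
    trend_sign_a = sign(trendA), trend_sign_b = sign(trendB),
    crossings = crossings,
    sampling_variation = sign(trendA) != sign(trendB) &
      crossings >= crossing_threshold,
    row.names = NULL
  )
  ks <- sort(unique(feat$cluster))
  clus <- do.call(rbind, lapply(ks, function(k) {
    s <- feat$shift[feat$cluster == k]
    if (length(s) >= 2 && stats::sd(s) > 0) {
      tt <- stats::t.test(s, mu = 0)
      data.frame(cluster = k, n = length(s), mean_shift = mean(s),
                 t = unname(tt$statistic), p = tt$p.value)
    } else {
      data.frame(cluster = k, n = length(s), mean_shift = mean(s),
                 t = if (length(s) >= 2) 0 else NA_real_, p = NA_real_)
    }
  }))
  structure(list(features = feat, clusters = clus),
            class = "trajectory_comparison")
}

#' Spearman screen of feature-age association
#'
#' Spearman rank correlation (midranks for ties) and two-sided p value
#' between each feature and age, computed on the reference subjects
#' (by default the AAb-negative CTR and REL groups). Constant features give
#' `NA`.
#'
#' @param cohort A `cohort` object.
#' @param groups Groups defining the reference subjects.
#' @param use_values Optional subjects x features matrix to screen instead
#'   of the cohort's raw values (e.g. imputed data).
#' @return Data frame: feature, rho, p, n.
#' @export
spearman_age_screen <- function(cohort, groups = c("CTR", "REL"),
                                use_values = NULL) {
  keep <- cohort$group %in% groups
  X <- (use_values %||% cohort$values)[keep, , drop = FALSE]
  age <- cohort$age[keep]
  if (nrow(X) < 3) stop("need at least 3 subjects", call. = FALSE)
  res <- lapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    ok <- !is.na(v)
    if (sum(ok) < 3 || stats::sd(v[ok]) == 0) {
      return(data.frame(feature = colnames(X)[j], rho = NA_real_, p = NA_real_,
                        n = sum(ok)))
    }
    ct <- suppressWarnings(
      stats::cor.test(age[ok], v[ok], method = "spearman", exact = FALSE)
    )
    data.frame(feature = colnames(X)[j], rho = unname(ct$estimate),
               p = ct$p.value, n = sum(ok))
  })
  do.call(rbind, res)
}
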
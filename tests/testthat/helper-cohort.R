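# Shared fixture builders. Everything is generated in code at test time.

# Small two-group cohort with age-dependent and stable features.
small_cohort_config <- function(seed = 1, n = 80, ...) {
  args <- list(
    n_per_group = c(CTR = n, T1D = n),
    n_features_per_cluster = c(3, 2, 3, 2),
    effect_size_range = c(0.8, 1.2), noise_sd = 0.5,
    disease_shift = c(0, 0, 0, 0), aging_acceleration_years = 0,
    missing_rate = 0.02, seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(cohort_config, args)
}

# Regression design with a planted sparse support: y depends on the first
# `k` of `p` standardized gaussian features.
planted_regression <- function(n, p, k, beta = 1, noise = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("x%03d", 1:p)))
  coef <- rep(0, p)
  coef[seq_len(k)] <- beta
  y <- drop(X %*% coef) + rnorm(n, 0, noise)
  list(X = X, y = y, support = colnames(X)[seq_len(k)], coef = coef)
}

# Brute-force oracle: textbook Kruskal-Wallis H (tie-corrected) and Dunn z
# on explicitly sorted midranks.
brute_kw_dunn <- function(v, g, pair) {
  r <- brute_ranks(v)
  N <- length(v)
  groups <- split(r, g)
  Rbar <- vapply(groups, mean, numeric(1))
  n_i <- vapply(groups, length, numeric(1))
  H <- (12 / (N * (N + 1))) * sum(n_i * (Rbar - (N + 1) / 2)^2)
  tt <- table(v)
  C <- 1 - sum(tt^3 - tt) / (N^3 - N)
  H <- H / C
  se <- sqrt((N * (N + 1) / 12 - sum(tt^3 - tt) / (12 * (N - 1))) *
               (1 / n_i[pair[1]] + 1 / n_i[pair[2]]))
  z <- (Rbar[pair[1]] - Rbar[pair[2]]) / se
  list(H = unname(H), z = unname(z))
}

# Brute-force midrank vector (independent of base rank()): average position
# of tied values after explicit sorting.
brute_ranks <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  pos <- seq_along(x)
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(pos[i:j])
    i <- j + 1
  }
  r
}
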
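test_that("a 3-df smoother reproduces exactly linear data", {
  set.seed(1)
  ages <- runif(60, 3, 80)
  v <- 0.04 * ages - 1
  tr <- fit_trajectory(ages, v)
  expect_equal(tr$values, 0.04 * tr$grid - 1, tolerance = 1e-6)
  expect_true(all(tr$grid >= 5 & tr$grid <= 75))
})

test_that("constant input gives a constant trajectory", {
  ages <- seq(5, 75, length.out = 30)
  tr <- fit_trajectory(ages, rep(0.3, 30))
  expect_equal(tr$values, rep(0.3, length(tr$grid)))
})

test_that("too few distinct ages is an error", {
  expect_error(fit_trajectory(rep(1:5, 4), rnorm(20)), "distinct ages")
})

test_that("grid values agree with an independent penalized-spline smoother", {
  # oracle: mgcv thin-plate smoother with its penalty tuned to the same
  # effective df (different basis, same target)
  set.seed(40)
  ages <- sort(runif(40, 4, 78))
  v <- sin(ages / 12) + rnorm(40, 0, 0.2)
  tr <- fit_trajectory(ages, v)
  edf_at <- function(lsp) {
    g <- mgcv::gam(v ~ s(ages, k = 20), sp = exp(lsp))
    sum(g$edf) - 3              # total edf (incl. intercept) minus target
  }
  lsp <- uniroot(edf_at, c(-10, 25))$root
  g <- mgcv::gam(v ~ s(ages, k = 20), sp = exp(lsp))
  oracle <- predict(g, data.frame(ages = tr$grid))
  expect_lt(max(abs(tr$values - oracle)), 0.02)
})

test_that("clustering groups planted trajectory shapes correctly", {
  cfg <- cohort_config(n_per_group = c(CTR = 300),
                       n_features_per_cluster = c(10, 10, 10, 10),
                       effect_size_range = c(0.9, 1.1), noise_sd = 0.3,
                       missing_rate = 0, seed = 55)
  coh <- generate_cohort(cfg)
  X <- apply_transform(fit_transform(coh), coh)
  ts <- fit_trajectories(X, coh$age)
  cl <- cluster_trajectories(ts)
  expect_length(cl$cluster, 40)
  expect_setequal(unique(cl$cluster), 1:4)
  ari <- mclust::adjustedRandIndex(cl$cluster, coh$feature_meta$cluster)
  expect_gte(ari, 0.9)
  # invariance to feature order
  perm <- sample(nrow(ts$values))
  ts2 <- ts
  ts2$values <- ts$values[perm, ]
  cl2 <- cluster_trajectories(ts2)
  expect_identical(cl2$cluster[names(cl$cluster)], cl$cluster)
})

test_that("identical trajectories have Canberra distance 0 and share a cluster", {
  # metric definition check: d((1,2),(3,2)) = |1-3|/(1+3) = 0.5, matching
  # both the hand computation and base R's canberra distance
  expect_equal(as.numeric(immunage:::canberra_dist(rbind(c(1, 2), c(3, 2)),
                                                   floor = 0.5)), 0.5)
  set.seed(31)
  P <- matrix(abs(rnorm(4 * 10)) + 1, 4)   # away from zero: floor inactive
  expect_equal(as.numeric(immunage:::canberra_dist(P, floor = 0.5)),
               as.numeric(dist(P, method = "canberra")), tolerance = 1e-12)
  grid <- age_grid()
  M <- rbind(a = sin(grid / 10), b = sin(grid / 10), c = cos(grid / 10) + 2)
  cl <- cluster_trajectories(M, k = 2, grid = grid)
  expect_identical(cl$cluster[["a"]], cl$cluster[["b"]])
})

test_that("trajectory comparison recovers exact constant offsets", {
  grid <- age_grid()
  A <- rbind(f1 = 0.01 * grid, f2 = -0.01 * grid, f3 = sin(grid / 15))
  cl <- cluster_trajectories(A, k = 2, grid = grid)
  B <- A + 0.3
  cmp <- compare_trajectories(A, B, cl, grid = grid)
  expect_equal(cmp$features$shift, rep(0.3, 3))
  expect_equal(cmp$clusters$mean_shift, rep(0.3, nrow(cmp$clusters)))
  # self-comparison: all shifts exactly 0, t statistic 0
  cmp0 <- compare_trajectories(A, A, cl, grid = grid)
  expect_identical(cmp0$features$shift, rep(0, 3))
  expect_true(all(cmp0$clusters$t == 0, na.rm = TRUE))
})

test_that("trajectory shift is translation-equivariant", {
  grid <- age_grid()
  set.seed(3)
  A <- matrix(rnorm(5 * length(grid)), 5,
              dimnames = list(paste0("f", 1:5), NULL))
  B <- matrix(rnorm(5 * length(grid)), 5,
              dimnames = list(paste0("f", 1:5), NULL))
  cl <- cluster_trajectories(A, k = 2, grid = grid)
  base <- compare_trajectories(A, B, cl, grid = grid)$features$shift
  shifted <- compare_trajectories(A, B + 0.7, cl, grid = grid)$features$shift
  expect_equal(shifted, base + 0.7, tolerance = 1e-12)
})

test_that("initial trend has the expected sign and value", {
  grid <- age_grid()
  expect_gt(initial_trend(0.1 * grid, grid = grid), 0)
  expect_identical(initial_trend(rep(1, length(grid)), grid = grid), 0)
  # symmetric parabola with vertex at age 10: direct enumeration oracle
  v <- (grid - 10)^2
  idx <- which(grid >= 5 & grid <= 15)
  expect_equal(initial_trend(v, grid = grid), mean(diff(v[idx])))
  expect_equal(initial_trend(v, grid = grid), 0)  # symmetry about 10
})

test_that("crossing counts match a brute-force scan", {
  grid <- age_grid()
  expect_identical(count_crossings(rep(2, 141), rep(1, 141)), 0L)
  expect_identical(count_crossings(rep(1, 141), rep(1, 141)), 0L)
  A <- sin(3.5 * pi * (grid - 5) / 70) # 3 interior sign changes vs zero line
  brute <- {
    s <- sign(A)
    s <- s[s != 0]
    sum(head(s, -1) * tail(s, -1) < 0)
  }
  expect_equal(count_crossings(A, rep(0, length(A))), brute)
  expect_equal(brute, 3)
  # exact zeros collapse: a touch without sign change is not a crossing,
  # a zero run between opposite signs counts once
  touch <- rep(1, 20); touch[8:9] <- 0
  expect_identical(count_crossings(touch, rep(0, 20)), 0L)
  crossing <- c(rep(1, 8), 0, 0, rep(-1, 10))
  expect_identical(count_crossings(crossing, rep(0, 20)), 1L)
})

test_that("the Spearman age screen matches the rank-formula oracle", {
  cfg <- small_cohort_config(seed = 14, n = 120, missing_rate = 0)
  coh <- generate_cohort(cfg)
  scr <- spearman_age_screen(coh)
  # feature = age exactly
  coh2 <- coh
  coh2$values <- cbind(coh$values, agecopy = coh$age)
  coh2$feature_meta <- rbind(coh$feature_meta,
                             data.frame(feature = "agecopy", domain = "count",
                                        cluster = 1, amplitude = 1, skewed = FALSE))
  scr2 <- spearman_age_screen(coh2)
  expect_equal(scr2$rho[scr2$feature == "agecopy"], 1)
  # independent feature: |rho| < 3/sqrt(n)
  set.seed(8)
  coh2$values[, "agecopy"] <- rnorm(nrow(coh2$values))
  scr3 <- spearman_age_screen(coh2)
  n_ref <- scr3$n[scr3$feature == "agecopy"]
  expect_lt(abs(scr3$rho[scr3$feature == "agecopy"]), 3 / sqrt(n_ref))
  # 10-point table with a tie: midrank oracle via explicit sorting
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  a <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  oracle <- cor(brute_ranks(x), brute_ranks(a))
  keep <- coh$group %in% c("CTR", "REL")
  coh3 <- coh
  coh3$age[which(keep)[1:10]] <- a
  coh3$values <- matrix(NA_real_, nrow(coh$values), 1,
                        dimnames = list(rownames(coh$values), "toy"))
  coh3$values[which(keep)[1:10], "toy"] <- x
  scr4 <- spearman_age_screen(coh3)
  expect_equal(scr4$rho[1], oracle, tolerance = 1e-12)
  expect_identical(scr4$n[1], 10L)
})

test_that("cluster shift t tests are calibrated on null cohorts", {
  # 120 simulated null cohorts; two same-law halves compared per cohort
  n_sim <- 120
  p_cl <- numeric(0)
  for (i in seq_len(n_sim)) {
    cfg <- cohort_config(n_per_group = c(CTR = 120, T1D = 120),
                         n_features_per_cluster = c(8, 0, 8, 0),
                         effect_size_range = c(0.9, 1.1), noise_sd = 0.6,
                         missing_rate = 0, seed = 9000 + i)
    coh <- generate_null_cohort(cfg)
    X <- apply_transform(fit_transform(coh, log_transform = FALSE), coh)
    a_rows <- coh$group == "CTR"
    tsA <- fit_trajectories(X[a_rows, ], coh$age[a_rows])
    tsB <- fit_trajectories(X[!a_rows, ], coh$age[!a_rows])
    cl <- cluster_trajectories(tsA, k = 2)
    cmp <- compare_trajectories(tsA, tsB, cl)
    p_cl <- c(p_cl, cmp$clusters$p)
  }
  rate <- mean(p_cl < 0.05, na.rm = TRUE)
  m <- sum(!is.na(p_cl))
  # binomial tolerance around the nominal 5% level
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / m) + 0.02)
})
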
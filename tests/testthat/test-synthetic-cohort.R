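test_that("generation is deterministic given the seed", {
  cfg <- small_cohort_config(seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$values, b$values)
  expect_identical(a$age, b$age)
  expect_identical(a$covariates, b$covariates)
  c2 <- generate_cohort(small_cohort_config(seed = 43))
  expect_false(identical(a$values, c2$values))
})

test_that("invalid configuration errors name the offending field", {
  expect_error(small_cohort_config(missing_rate = 0.06), "missing_rate")
  expect_error(small_cohort_config(age_range = c(1, 83)), "age_range")
  expect_error(small_cohort_config(skew_fraction = 1.2), "skew_fraction")
  expect_error(
    small_cohort_config(age_components = data.frame(mean = c(10, 40),
                                                    sd = c(3, 9),
                                                    weight = c(0.5, 0.6))),
    "age_components"
  )
})

test_that("value domains are respected where observed", {
  coh <- generate_cohort(small_cohort_config(seed = 5, n = 150))
  meta <- coh$feature_meta
  pct <- coh$values[, meta$domain == "percent", drop = FALSE]
  expect_true(all(pct >= 0 & pct <= 100, na.rm = TRUE))
  pos <- coh$values[, meta$domain == "intensity", drop = FALSE]
  expect_true(all(pos > 0, na.rm = TRUE))
  expect_true(all(coh$age >= 2 & coh$age <= 83))
  expect_true(all(coh$group %in% c("CTR", "REL", "RSK", "T1D")))
})

test_that("noiseless features are exact monotone functions of age", {
  cfg <- small_cohort_config(seed = 9, noise_sd = 0, missing_rate = 0)
  coh <- generate_cohort(cfg)
  f_up <- coh$feature_meta$feature[coh$feature_meta$cluster == 1][1]
  v <- coh$values[, f_up]
  expect_true(all(diff(v[order(coh$age)]) >= 0))
  # equal-age subjects (the value depends on age alone) would be equal:
  # the map age -> value is single-valued by construction
  expect_equal(length(unique(round(v, 12))), length(unique(round(coh$age, 12))))
})

test_that("aging acceleration matches CTR shifted by the configured years", {
  # Monte-Carlo oracle: bin a large cohort by age and compare group means
  cfg <- cohort_config(
    n_per_group = c(CTR = 4000, T1D = 4000),
    n_features_per_cluster = c(2, 0, 0, 0),
    effect_size_range = c(1.2, 1.2), noise_sd = 1,
    disease_shift = c(0, 0, 0, 0), aging_acceleration_years = 3,
    missing_rate = 0, seed = 31
  )
  coh <- generate_cohort(cfg)
  f <- coh$feature_meta$feature[1]
  bins <- seq(10, 60, by = 5)
  z <- vapply(bins, function(b) {
    t1d <- coh$group == "T1D" & abs(coh$age - b) < 2.5
    ctr <- coh$group == "CTR" & abs(coh$age - (b + 3)) < 2.5
    d <- mean(coh$values[t1d, f]) - mean(coh$values[ctr, f])
    se <- sqrt(var(coh$values[t1d, f]) / sum(t1d) +
                 var(coh$values[ctr, f]) / sum(ctr))
    d / se
  }, numeric(1))
  expect_lt(max(abs(z)), 4)
  expect_lt(abs(mean(z)), 1.5)
})

test_that("null cohorts have exchangeable groups (means within analytic SE)", {
  cfg <- cohort_config(
    n_per_group = c(CTR = 600, T1D = 600),
    n_features_per_cluster = c(10, 5, 10, 5),
    noise_sd = 1, missing_rate = 0, seed = 17,
    disease_shift = c(0.5, 0.5, 0.5, 0.5), aging_acceleration_years = 5
  )
  coh <- generate_null_cohort(cfg)   # forces shift = 0, acceleration = 0
  expect_identical(coh$config$disease_shift, c(0, 0, 0, 0))
  z <- vapply(seq_len(ncol(coh$values)), function(j) {
    v1 <- coh$values[coh$group == "CTR", j]
    v2 <- coh$values[coh$group == "T1D", j]
    (mean(v1) - mean(v2)) / sqrt(var(v1) / length(v1) + var(v2) / length(v2))
  }, numeric(1))
  expect_lt(max(abs(z)), 4.5)  # 30 features, null z scores
})

test_that("a group with zero subjects yields no rows of that group", {
  cfg <- cohort_config(n_per_group = c(CTR = 30, REL = 20, RSK = 0, T1D = 25),
                       n_features_per_cluster = c(2, 1, 2, 1),
                       missing_rate = 0, seed = 3)
  coh <- generate_cohort(cfg)
  expect_identical(sum(coh$group == "RSK"), 0L)
  expect_identical(nrow(coh$values), 75L)
})

test_that("skew-flagged features are right-skewed at generation scale", {
  cfg <- cohort_config(n_per_group = c(CTR = 600),
                       n_features_per_cluster = c(10, 5, 10, 15),
                       skew_fraction = 0.5, missing_rate = 0, seed = 8)
  coh <- generate_cohort(cfg)
  sk <- vapply(which(coh$feature_meta$skewed),
               function(j) sample_skewness(coh$values[, j]), numeric(1))
  expect_gte(mean(sk > 0.5), 0.95)
  nsk <- vapply(which(!coh$feature_meta$skewed),
                function(j) sample_skewness(coh$values[, j]), numeric(1))
  expect_lt(mean(abs(nsk)), 0.5)
})

test_that("the age distribution is bimodal with the configured components", {
  cfg <- cohort_config(n_per_group = c(CTR = 700), missing_rate = 0, seed = 12,
                       n_features_per_cluster = c(1, 0, 0, 0))
  coh <- generate_cohort(cfg)
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  fit <- mclust::Mclust(coh$age, G = 2, modelNames = "V", verbose = FALSE)
  mu <- sort(fit$parameters$mean)
  expect_lt(abs(mu[1] - cfg$age_components$mean[1]), 2)
  expect_lt(abs(mu[2] - cfg$age_components$mean[2]), 2)
})

test_that("missingness is MCAR at the configured rate", {
  coh <- generate_cohort(small_cohort_config(seed = 21, n = 500,
                                             missing_rate = 0.03))
  rate <- mean(is.na(coh$values))
  expect_lt(abs(rate - 0.03), 0.005)
})

test_that("cohorts round-trip through the tidy CSV representation", {
  coh <- generate_cohort(small_cohort_config(seed = 2, n = 25))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$values, coh$values, tolerance = 1e-12)
  expect_equal(back$age, coh$age, tolerance = 1e-12)
  expect_identical(as.character(back$group), as.character(coh$group))
})
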
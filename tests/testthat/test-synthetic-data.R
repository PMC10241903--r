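test_that("degenerate profile produces an all-zero trial", {
  prof <- accel_profile(amplitude = 0, irregularity = 0, spike_rate = 0,
                        baseline_offset = 0, duration = 1,
                        sampling_rate = 200)
  tr <- generate_accel_trial(prof, seed = 1)
  expect_equal(unname(tr$axes), matrix(0, 200, 3))
  expect_equal(apply(tr$axes, 2, sd), c(x = 0, y = 0, z = 0))
})

test_that("a pure sinusoid has per-axis SD A/sqrt(2)", {
  prof <- accel_profile(amplitude = 0.10, harmonic_weights = 1,
                        irregularity = 0, spike_rate = 0, duration = 10,
                        sampling_rate = 500)
  tr <- generate_accel_trial(prof, seed = 7)
  for (a in c("x", "y", "z")) {
    expect_equal(sd(tr$axes[, a]), 0.10 / sqrt(2), tolerance = 0.01)
  }
})

test_that("spike injection plants exactly rate x duration isolated spikes", {
  prof <- accel_profile(amplitude = 0.1, irregularity = 0.2,
                        spike_rate = 0.4, spike_magnitude = 10,
                        duration = 30, sampling_rate = 200)
  clean_prof <- prof
  clean_prof$spike_rate <- 0
  tr <- generate_accel_trial(prof, seed = 11)
  clean <- generate_accel_trial(clean_prof, seed = 11)
  for (a in c("x", "y", "z")) {
    dev <- abs(tr$axes[, a] - clean$axes[, a])
    clean_sd <- sd(clean$axes[, a])
    hit <- which(dev > 5 * clean_sd)
    expect_length(hit, 12L)                       # 0.4/s x 30 s
    expect_identical(hit, tr$spike_indices[[a]])
    expect_true(all(diff(tr$spike_indices[[a]]) >= 3))
    expect_equal(sum(dev[-hit]), 0)               # spikes only touch spikes
  }
})

test_that("trial generation is a pure function of (profile, seed)", {
  prof <- accel_profile(duration = 2, sampling_rate = 200)
  a <- generate_accel_trial(prof, seed = 3)
  b <- generate_accel_trial(prof, seed = 3)
  expect_identical(a$axes, b$axes)
  expect_identical(a$spike_indices, b$spike_indices)
  c <- generate_accel_trial(prof, seed = 4)
  expect_false(identical(a$axes, c$axes))
})

test_that("profile invariants are enforced", {
  expect_error(accel_profile(duration = -1), "positive")
  expect_error(accel_profile(irregularity = 1.5), "irregularity")
  expect_error(accel_profile(sampling_rate = 5, movement_rate = 3),
               "twice the highest harmonic")
  expect_error(accel_profile(duration = 1.0005, sampling_rate = 100),
               "integer sample count")
})

test_that("null cohort design yields group mean changes compatible with 0", {
  des <- cohort_design(group_sizes = c(PD = 500, PSP = 500, MSA = 500,
                                       HC = 500))
  des$decline_means[, ] <- 0
  # keep scores far from the zero clamp so the null mean is exactly 0
  des$visit1_means[, ] <- 20
  des$visit1_sds[, ] <- 2
  ch <- generate_cohort(des, seed = 21)
  cs <- one_year_change(ch, tasks = "both")
  for (g in levels(cs$diagnosis)) {
    v <- cs$change[cs$diagnosis == g]
    expect_lt(abs(mean(v)), 2.58 * sd(v) / sqrt(length(v)) + 0.05)
  }
})

test_that("planted PD both-hands decline is recovered at n = 1000", {
  des <- single_group_design("PD", 1000)
  ch <- generate_cohort(des, seed = 33)
  cs <- one_year_change(ch, tasks = "both")
  # planted mean -1.268, SD 3.527: CLT bound 3 SD / sqrt(n) < 0.34
  expect_lt(abs(mean(cs$change) - (-1.268)), 0.3)
})

test_that("planted change correlation survives the copula at n = 2000", {
  des <- single_group_design("PD", 2000, rho = -0.30)
  ch <- generate_cohort(des, seed = 55)
  cs <- one_year_change(ch, tasks = "dominant")
  rho <- correlate_changes(cs$updrs_change, cs$change, "spearman")$estimate
  expect_gte(rho, -0.36)
  expect_lte(rho, -0.24)
})

test_that("cohort generation is deterministic and honors group sizes", {
  des <- cohort_design(group_sizes = c(PD = 10, HC = 8))
  a <- generate_cohort(des, seed = 9)
  b <- generate_cohort(des, seed = 9)
  expect_identical(a, b)
  expect_equal(as.vector(table(a$diagnosis)), c(10, 8))
  expect_true(all(is.na(a$disease_duration[a$diagnosis == "HC"])))
  ppt_cols <- grep("^ppt_", names(a), value = TRUE)
  expect_true(all(as.matrix(a[ppt_cols]) >= 0))
})

test_that("empty predictor support yields a null model", {
  des <- predictor_design(n_subjects = 300, true_support = numeric(0))
  sim <- generate_predictors(des, seed = 2)
  fit <- lm(sim$y ~ sim$x)
  # under the null, R^2 concentrates near p/(n-1)
  expect_lt(summary(fit)$r.squared, 3 * 40 / 299)
  expect_equal(unname(sim$beta), rep(0, 40))
})

test_that("OLS on the true support recovers planted coefficients", {
  des <- predictor_design(n_subjects = 300, n_predictors = 10,
                          true_support = c(X01 = 0.4, X02 = -0.4, X03 = 0.4),
                          noise_sd = 1, predictor_correlation = 0)
  sim <- generate_predictors(des, seed = 4)
  bhat <- naive_ols(sim$x[, 1:3], sim$y)[-1]
  expect_lt(max(abs(bhat - c(0.4, -0.4, 0.4))), 0.15)
})

test_that("predictor generation is bitwise reproducible and standardized", {
  a <- generate_predictors(predictor_design(), seed = 12)
  b <- generate_predictors(predictor_design(), seed = 12)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_equal(unname(apply(a$x, 2, sd)), rep(1, 40))
  expect_error(predictor_design(predictor_correlation = 1), "singular")
})
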
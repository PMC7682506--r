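test_that("trial datasets have exact arm counts and MCAR missingness", {
  s <- trial_scenario()
  d <- generate_trial_dataset(s, seed = 61)
  expect_equal(nrow(d), 500L)
  expect_equal(sum(d$z == 1), 250L)
  expect_equal(sum(d$z == 0), 250L)
  expect_false(anyNA(d$x))
  # only y is ever missing
  expect_gt(sum(is.na(d$y)), 0)

  d0 <- generate_trial_dataset(trial_scenario(missing_prob = 0), seed = 62)
  expect_false(anyNA(d0$y))
})

test_that("trial generator reproduces the stated moments at large n", {
  s <- trial_scenario(n = 100000L, arm_size = 50000L, missing_prob = 0)
  d <- generate_trial_dataset(s, seed = 63)
  act <- d$z == 1
  expect_equal(mean(d$y[act]), 2.2, tolerance = 0.01)
  expect_equal(mean(d$y[!act]), 2.0, tolerance = 0.01)
  expect_equal(mean(d$x), 2.0, tolerance = 0.01)
  expect_equal(cov(d$x[act], d$y[act]), 0.2, tolerance = 0.01)
  expect_equal(var(d$y[act]), 0.4, tolerance = 0.01)
})

test_that("invalid scenario parameters are rejected", {
  expect_error(trial_scenario(n = 500, arm_size = 200), "sum to n")
  expect_error(trial_scenario(cov_xy = 0.9), "positive definite")
  expect_error(trial_scenario(missing_prob = 1.2), "missing_prob")
  expect_error(anthro_scenario("subgroup", eta = 3), "eta must be 1")
  expect_error(anthro_scenario("subgroup", Sigma = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("null anthro parameters give sex-balanced distributions", {
  s <- anthro_scenario("omitted_interaction", n = 200000L,
                       missing_prob = 0)
  d <- generate_anthro_dataset(s, seed = 64)
  men <- d$sex == 1
  for (v in c("age", "height", "weight", "loginsindex")) {
    se_diff <- sd(d[[v]]) * sqrt(2 / sum(men))
    expect_lt(abs(mean(d[[v]][men]) - mean(d[[v]][!men])), 4 * se_diff)
    expect_equal(sd(d[[v]][men]) / sd(d[[v]][!men]), 1, tolerance = 0.02)
  }
})

test_that("the heteroscedastic switch doubles the male error SD", {
  s <- anthro_scenario("heteroscedastic", n = 50000L, missing_prob = 0)
  d <- generate_anthro_dataset(s, seed = 65)
  resid_w <- d$weight - (s$iota[1] + s$iota[2] * d$sex +
                           s$iota[3] * d$age + s$iota[4] * d$height)
  ratio <- sd(resid_w[d$sex == 1]) / sd(resid_w[d$sex == 0])
  expect_equal(ratio, 2, tolerance = 0.03)
})

test_that("weight missingness hits the configured fraction and subgroup", {
  s <- anthro_scenario("heteroscedastic", n = 100000L)
  d <- generate_anthro_dataset(s, seed = 66)
  expect_equal(mean(is.na(d$weight)), 0.6, tolerance = 0.01)

  ssub <- anthro_scenario("subgroup", n = 100000L)
  dsub <- generate_anthro_dataset(ssub, seed = 67)
  expect_equal(mean(is.na(dsub$weight[dsub$sex == 1])), 0.6,
               tolerance = 0.015)
  expect_false(anyNA(dsub$weight[dsub$sex == 0]))
})

test_that("non-normal scenario draws log-normal errors", {
  s <- anthro_scenario("non_normal", n = 50000L, missing_prob = 0)
  d <- generate_anthro_dataset(s, seed = 68)
  resid_w <- d$weight - (s$iota[1] + s$iota[3] * d$age +
                           s$iota[4] * d$height)
  # exp(N(0, 1/16)) is strictly positive with mean exp(1/32)
  expect_gt(min(resid_w), 0)
  expect_equal(mean(resid_w), exp(1 / 32), tolerance = 0.01)
})

test_that("Monte-Carlo SE formula matches its stated values", {
  expect_equal(mc_se(0.95, 1000), 0.689, tolerance = 0.001)
  expect_equal(mc_se(0.5, 4), 25, tolerance = 1e-12)
  expect_equal(mc_se(0.95, 10000), 100 * sqrt(0.95 * 0.05 / 10000),
               tolerance = 1e-12)
})

test_that("study summaries aggregate the replication records", {
  s <- trial_scenario(n = 100L, arm_size = 50L)
  methods <- list(method_settings("rubin", M = 3),
                  method_settings("boot_mi_vonhippel", M = 2, B = 20))
  st <- run_study(s, methods, n_reps = 6, seed = 71)
  expect_equal(nrow(st$replications), 12L)
  expect_equal(nrow(st$summary), 2L)
  for (j in 1:2) {
    lab <- st$summary$method[j]
    d <- st$replications[st$replications$method == lab, ]
    expect_equal(st$summary$coverage_pct[j], 100 * mean(d$covered),
                 tolerance = 1e-12)
    expect_equal(st$summary$median_ci_width[j], median(d$width),
                 tolerance = 1e-12)
    expect_equal(d$width, d$ci_upper - d$ci_lower, tolerance = 1e-12)
    expect_equal(d$covered,
                 d$ci_lower <= 0.2 & 0.2 <= d$ci_upper)
  }
  expect_equal(st$summary$mc_se_pct,
               rep(mc_se(0.95, 6), 2), tolerance = 1e-12)
})

test_that("identical master seeds reproduce a study exactly", {
  s <- trial_scenario(n = 100L, arm_size = 50L)
  methods <- list(method_settings("rubin", M = 3),
                  method_settings("mi_boot_pooled", M = 2, B = 15))
  st1 <- run_study(s, methods, n_reps = 4, seed = 72)
  st2 <- run_study(s, methods, n_reps = 4, seed = 72)
  expect_identical(st1$summary, st2$summary)
  expect_identical(st1$replications, st2$replications)
})

test_that("the J2R estimand reflects the imputation assumption", {
  mar <- trial_scenario()
  j2r <- trial_scenario(imputation_method = "jump_to_reference")
  expect_equal(scenario_truth(mar), 0.2)
  expect_equal(scenario_truth(j2r), 0.1)
  expect_equal(scenario_truth(trial_scenario(
    imputation_method = "jump_to_reference", missing_prob = 0.3)),
    0.7 * 0.2, tolerance = 1e-12)
})

test_that("method failures are recorded, not fatal", {
  s <- trial_scenario(n = 12L, arm_size = 6L, missing_prob = 0.9)
  st <- run_study(s, list(method_settings("rubin", M = 2)), n_reps = 5,
                  seed = 73)
  expect_true(all(c("n_failed", "coverage_pct") %in% names(st$summary)))
  fails <- st$replications[is.na(st$replications$covered), ]
  if (nrow(fails) > 0) expect_true(all(!is.na(fails$error)))
})
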
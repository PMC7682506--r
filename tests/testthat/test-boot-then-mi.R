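test_that("hand-worked ANOVA component examples are exact", {
  # rows are bootstrap replicates: (1,1) and (3,3)
  g <- estimate_grid(matrix(c(1, 3, 1, 3), 2), "bootstrap_major")
  vc <- anova_components(g)
  expect_equal(vc$MSB, 4, tolerance = 1e-12)
  expect_equal(vc$MSW, 0, tolerance = 1e-12)
  expect_equal(vc$sigma2_inf, 2, tolerance = 1e-12)
  expect_equal(vc$sigma2_btw, 0, tolerance = 1e-12)
  expect_false(vc$fallback_used)

  # rows (1,3) and (2,4): MSB < MSW engages the fallback
  g <- estimate_grid(matrix(c(1, 2, 3, 4), 2), "bootstrap_major")
  vc <- anova_components(g)
  expect_equal(vc$MSB, 1, tolerance = 1e-12)
  expect_equal(vc$MSW, 2, tolerance = 1e-12)
  expect_equal(vc$sigma2_inf, 0, tolerance = 1e-12)
  expect_equal(vc$sigma2_btw, 5 / 3, tolerance = 1e-12)
  expect_true(vc$fallback_used)

  # degenerate grid
  g <- estimate_grid(matrix(2, 3, 2), "bootstrap_major")
  vc <- anova_components(g)
  expect_equal(vc$MSB + vc$MSW + vc$sigma2_inf + vc$sigma2_btw, 0,
               tolerance = 1e-12)
})

test_that("hand-worked variance-component inference examples are exact", {
  g <- estimate_grid(matrix(c(1, 3, 1, 3), 2), "bootstrap_major")
  v <- von_hippel_inference(g)
  expect_equal(v$estimate, 2, tolerance = 1e-12)
  expect_equal(v$variance, 3, tolerance = 1e-12)
  expect_equal(v$df, 1, tolerance = 1e-12)   # B - 1 since MSW = 0
  expect_equal(v$ci_upper, 2 + qt(0.975, 1) * sqrt(3), tolerance = 1e-9)

  # fallback branch: variance = s2_total / (BM) = (5/3)/4
  g <- estimate_grid(matrix(c(1, 2, 3, 4), 2), "bootstrap_major")
  expect_equal(von_hippel_inference(g)$variance, 5 / 12,
               tolerance = 1e-12)
})

test_that("ANOVA components match the brute-force oracle on random grids", {
  set.seed(41)
  for (i in 1:15) {
    B <- sample(2:10, 1); M <- sample(2:6, 1)
    g <- estimate_grid(matrix(rnorm(B * M), B, M), "bootstrap_major")
    vc <- anova_components(g)
    o <- oracle_anova(unclass(g))
    expect_equal(vc$MSB, o$MSB, tolerance = 1e-12)
    expect_equal(vc$MSW, o$MSW, tolerance = 1e-12)
    # components always non-negative, fallback consistent
    expect_gte(vc$sigma2_inf, 0)
    expect_gte(vc$sigma2_btw, 0)
    expect_identical(vc$fallback_used, vc$MSB < vc$MSW)
    if (!vc$fallback_used)
      expect_equal(vc$sigma2_inf, (vc$MSB - vc$MSW) / M, tolerance = 1e-12)
  }
})

test_that("the two displayed variance forms agree algebraically", {
  set.seed(42)
  for (i in 1:25) {
    B <- sample(2:30, 1); M <- sample(2:8, 1)
    g <- estimate_grid(matrix(rnorm(B * M, sd = runif(1, 0.1, 5)), B, M),
                       "bootstrap_major")
    vc <- anova_components(g)
    v <- von_hippel_inference(g)
    if (!vc$fallback_used) {
      lhs <- (1 + 1 / B) * (vc$MSB - vc$MSW) / M + vc$MSW / (B * M)
      rhs <- ((B + 1) / (B * M)) * vc$MSB - vc$MSW / M
      expect_equal(lhs, rhs, tolerance = 1e-12)
      expect_equal(v$variance, rhs, tolerance = 1e-12)
    }
    expect_gte(v$variance, 0)  # fallback guarantees non-negativity
  }
})

test_that("MSW = 0 gives Satterthwaite df of exactly B - 1", {
  for (B in c(2, 5, 20)) {
    for (M in c(2, 4)) {
      vals <- matrix(rep(rnorm(B), M), B, M)  # constant within replicate
      v <- von_hippel_inference(estimate_grid(vals, "bootstrap_major"))
      expect_equal(v$df, B - 1, tolerance = 1e-9)
    }
  }
})

test_that("variance of the grand mean follows the two-level formula", {
  # simulate the variance-components model directly with known
  # sigma2_inf and sigma2_btw and compare the empirical variance of the
  # grand mean with (1 + 1/B) s2_inf + s2_btw / (BM)
  set.seed(43)
  B <- 25; M <- 2
  s2_inf <- 1; s2_btw <- 2
  # the dataset-level centre varies with variance s2_inf across
  # replications; the bootstrap replicate effects add s2_inf / B
  means <- replicate(4000, mean(two_level_grid(B, M, s2_inf, s2_btw,
                                               mu = rnorm(1, 0, sqrt(s2_inf)))))
  expected <- (1 + 1 / B) * s2_inf + s2_btw / (B * M)
  expect_lt(abs(var(means) - expected) / expected, 0.1)
})

test_that("ANOVA estimators recover known variance components", {
  set.seed(44)
  g <- two_level_grid(B = 2000, M = 2, s2_inf = 1, s2_btw = 0.5)
  vc <- anova_components(g)
  expect_lt(abs(vc$sigma2_inf - 1), 0.1)
  expect_lt(abs(vc$sigma2_btw - 0.5) / 0.5, 0.1)
})

test_that("percentile interval of replicate means follows the quantile rule", {
  g <- estimate_grid(matrix(1:5, 5, 1), "bootstrap_major")
  r <- boot_mi_percentile(g, alpha = 0.4)  # 20% and 80% percentiles
  expect_equal(r$ci_lower, 1.8, tolerance = 1e-12)
  expect_equal(r$ci_upper, 4.2, tolerance = 1e-12)
  expect_equal(r$estimate, 3, tolerance = 1e-12)

  # all replicate means equal -> degenerate interval
  g <- estimate_grid(matrix(c(1, 2, 3, 3, 2, 1), 3, 2), "bootstrap_major")
  r <- boot_mi_percentile(g)
  expect_equal(c(r$ci_lower, r$ci_upper), c(2, 2), tolerance = 1e-12)

  # permutation invariance in b
  g <- estimate_grid(matrix(rnorm(40), 20, 2), "bootstrap_major")
  gp <- estimate_grid(unclass(g)[sample(20), ], "bootstrap_major")
  expect_equal(boot_mi_percentile(g)$ci_lower,
               boot_mi_percentile(gp)$ci_lower, tolerance = 1e-12)
})

test_that("complete data with no imputation noise give MSW = 0", {
  d <- tiny_trial(n = 60, miss = 0)
  imp <- imputation_spec("y", c("x", "z"), M = 3)
  ana <- analysis_spec("y", c("x", "z"), target = "z")
  g <- boot_mi_estimates(d, imp, ana, B = 20, seed = 51)
  expect_equal(attr(g, "layout"), "bootstrap_major")
  # all M estimates identical within each replicate
  expect_equal(anova_components(g)$MSW, 0, tolerance = 1e-20)
})

test_that("boot-then-MI grids are reproducible and well shaped", {
  d <- tiny_trial(n = 60, miss = 0.4)
  imp <- imputation_spec("y", c("x", "z"), M = 3)
  ana <- analysis_spec("y", c("x", "z"), target = "z")
  g1 <- boot_mi_estimates(d, imp, ana, B = 25, seed = 52)
  g2 <- boot_mi_estimates(d, imp, ana, B = 25, seed = 52)
  expect_identical(unclass(g1), unclass(g2))
  expect_identical(dim(g1), c(25L, 3L))
})

test_that("the grid mean is consistent for the full-data MI estimate", {
  d <- tiny_trial(n = 150, miss = 0.4, seed = 53)
  imp <- imputation_spec("y", c("x", "z"), M = 2)
  ana <- analysis_spec("y", c("x", "z"), target = "z")
  g <- boot_mi_estimates(d, imp, ana, B = 2000, seed = 54)
  # reference: many-imputation Rubin point estimate on the original data
  set.seed(55)
  completed <- impute_missing(d, imputation_spec("y", c("x", "z"), M = 400))
  ref <- mean(vapply(completed, function(cc) fit_ols(cc, ana)$estimate, 0))
  expect_lt(abs(mean(g) - ref), 0.02)
})

test_that("single-imputation grids refuse ANOVA components", {
  g <- estimate_grid(matrix(rnorm(10), 10, 1), "bootstrap_major")
  expect_error(anova_components(g), "M >= 2")
  expect_silent(boot_mi_percentile(g))
})

test_that("grid CSV round trip preserves the (b, m) indexing", {
  g <- estimate_grid(matrix(rnorm(12), 4, 3), "bootstrap_major")
  path <- withr::local_tempfile(fileext = ".csv")
  write_estimate_grid(g, path)
  back <- read_estimate_grid(path)
  expect_equal(unclass(back), unclass(g), tolerance = 1e-12,
               ignore_attr = TRUE)
})
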
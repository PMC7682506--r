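# Shared fixtures and independent oracles used across test files.

# Small incomplete trial-like dataset built in code.
tiny_trial <- function(n = 80, effect = 0.2, miss = 0.4, seed = 101) {
  set.seed(seed)
  z <- rep(c(0, 1), length.out = n)
  x <- rnorm(n, 2, 0.6)
  y <- 2 + effect * z + 0.5 * (x - 2) + rnorm(n, 0, 0.55)
  y[runif(n) < miss] <- NA
  data.frame(x = x, y = y, z = z)
}

# Naive Rubin pooling written independently of pool_rubin().
oracle_rubin <- function(est, wv, alpha = 0.05) {
  M <- length(est)
  qbar <- sum(est) / M
  bm <- sum((est - qbar)^2) / (M - 1)
  wbar <- sum(wv) / M
  total <- wbar + (1 + 1 / M) * bm
  df <- if (bm == 0) Inf else (M - 1) * (1 + wbar / ((1 + 1 / M) * bm))^2
  list(estimate = qbar, variance = total, df = df,
       half = qt(1 - alpha / 2, df) * sqrt(total))
}

# Brute-force one-way ANOVA sums of squares, elementwise loops.
oracle_anova <- function(vals) {
  B <- nrow(vals); M <- ncol(vals)
  gb <- numeric(B)
  for (b in seq_len(B)) gb[b] <- sum(vals[b, ]) / M
  gm <- sum(vals) / (B * M)
  ssb <- 0; ssw <- 0
  for (b in seq_len(B)) {
    ssb <- ssb + (gb[b] - gm)^2
    for (m in seq_len(M)) ssw <- ssw + (vals[b, m] - gb[b])^2
  }
  list(MSB = M * ssb / (B - 1), MSW = ssw / (B * (M - 1)))
}

# Two-pass within+between decomposition of the pooled grid variance.
oracle_pooled_var <- function(vals) {
  M <- nrow(vals); B <- ncol(vals)
  gm <- mean(vals)
  mmeans <- rowMeans(vals)
  ssw <- sum((vals - mmeans)^2)
  ssb <- B * sum((mmeans - gm)^2)
  (ssw + ssb) / (M * B)
}

# Grid drawn from the two-level variance-components model:
# theta_bm = mu + c_b + d_bm.
two_level_grid <- function(B, M, s2_inf, s2_btw, mu = 0) {
  cb <- rnorm(B, 0, sqrt(s2_inf))
  vals <- mu + cb + matrix(rnorm(B * M, 0, sqrt(s2_btw)), B, M)
  estimate_grid(vals, layout = "bootstrap_major")
}
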
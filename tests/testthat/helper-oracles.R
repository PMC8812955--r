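# Independent oracles used across the test files. Everything here is written
# directly from the textbook formulas and kept free of the package's own
# computational paths (no calls into estimator internals).

# Literal evaluation of the general moment-estimator form with explicit
# weights: (sum w (g - thw)^2 - sum w v + sum w^2 v / sum w) /
#          (sum w - sum w^2 / sum w), truncated at zero.
oracle_moment_tau2 <- function(g, v, w) {
  thw <- sum(w * g) / sum(w)
  num <- sum(w * (g - thw)^2) - sum(w * v) + sum(w^2 * v) / sum(w)
  den <- sum(w) - sum(w^2) / sum(w)
  max(0, num / den)
}

# DL via the Q-statistic form (Q - (k-1)) / (sum w - sum w^2 / sum w).
oracle_dl_qform <- function(g, v) {
  k <- length(g)
  w <- 1 / v
  thw <- sum(w * g) / sum(w)
  q <- sum(w * (g - thw)^2)
  max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

# Profile log-likelihood of tau^2 (pooled effect profiled out).
oracle_ml_loglik <- function(tau2, g, v) {
  w <- 1 / (v + tau2)
  th <- sum(w * g) / sum(w)
  -0.5 * sum(log(v + tau2)) - 0.5 * sum(w * (g - th)^2)
}

# Restricted log-likelihood adds the -0.5 log(sum w) term.
oracle_reml_loglik <- function(tau2, g, v) {
  w <- 1 / (v + tau2)
  oracle_ml_loglik(tau2, g, v) - 0.5 * log(sum(w))
}

# Brute-force likelihood maximization over a tau^2 grid on [0, upper].
oracle_grid_max <- function(g, v, loglik, upper = 1, n_grid = 100001L) {
  grid <- seq(0, upper, length.out = n_grid)
  ll <- vapply(grid, loglik, numeric(1), g = g, v = v)
  grid[which.max(ll)]
}

# Generalized Q statistic, written independently of the package.
oracle_gen_q <- function(tau2, g, v) {
  w <- 1 / (v + tau2)
  th <- sum(w * g) / sum(w)
  sum(w * (g - th)^2)
}

# Random meta-analytic sample with heterogeneous variances.
random_meta_sample <- function(k, tau = 0.3) {
  v <- runif(k, 0.01, 0.2)
  g <- rnorm(k, 0.3, sqrt(tau^2 + v))
  list(g = g, v = v)
}

# Textbook evaluation of the Hedges-corrected SMD analysis on two vectors:
# pooled SD, small-sample correction, large-sample variance, pooled t-test.
oracle_smd <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2))
  d <- (mean(x2) - mean(x1)) / sp
  j <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- j * d
  v <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  tt <- t.test(x2, x1, var.equal = TRUE)
  list(g = g, v = v, p = tt$p.value)
}
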
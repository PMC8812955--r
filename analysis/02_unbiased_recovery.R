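#!/usr/bin/env Rscript
# Step 2: estimator performance in unbiased literatures.
#
# With no p-hacking and no censoring, the five heterogeneity estimators are
# fitted to the same simulated literatures across the tau x k grid. This
# reproduces, at desk scale, the unbiased-world findings: DL, PM and REML are
# nearly unbiased for tau; HS (and to a lesser degree ML) underestimate at
# high heterogeneity; and the tau levels translate into the familiar I^2
# ladder.

library(hetbias)

seed <- 20260920
reps <- 400          # meta-analyses per (tau, k) cell

dir.create("results", showWarnings = FALSE)

rows <- list()
for (tau in c(0, 0.11, 0.22, 0.33, 0.44)) {
  for (k in c(9, 18, 36, 72)) {
    rows[[length(rows) + 1]] <- run_cell(
      "none", "none", 0, tau, 0.5, k, reps = reps,
      seed = seed + round(tau * 1000) * 10 + k)
  }
}
cells <- do.call(rbind, rows)
write.csv(cells, "results/unbiased_cells.csv", row.names = FALSE)

cat("Mean T bias by estimator and tau (averaged over k):\n")
bias_tab <- round(tapply(cells$T_bias, cells[, c("estimator", "tau")], mean), 4)
print(bias_tab)

cat(sprintf(
  "\nMean |T bias| over nonzero-tau cells: DL %.4f, PM %.4f, REML %.4f\n",
  mean(abs(cells$T_bias[cells$estimator == "DL" & cells$tau > 0])),
  mean(abs(cells$T_bias[cells$estimator == "PM" & cells$tau > 0])),
  mean(abs(cells$T_bias[cells$estimator == "REML" & cells$tau > 0]))))
cat("The zero-tau row is overestimated by construction (estimates are >= 0);\n")
cat("HS shows the strongest underestimation at tau = 0.44.\n")

cat("\nT RMSE by estimator (averaged over all cells):\n")
print(round(tapply(cells$T_rmse, cells$estimator, mean), 4))

cat("\nCoverage of the Q-profile interval for tau (all cells pooled):\n")
print(round(tapply(cells$coverage_tau, cells$estimator, mean), 3))

# I^2 translation of the tau ladder, theta and k mixed across levels
sm <- sample_size_model()
env <- hacking_environment("none")
reg <- bias_regime("none")
ks <- c(9, 18, 36, 72)
thetas <- c(0, 0.2, 0.5, 0.8)
set.seed(seed)
i2 <- lapply(c(0, 0.11, 0.22, 0.33, 0.44), function(tau) {
  vapply(1:1500, function(i) {
    lit <- sample_published_literature(ks[(i - 1) %% 4 + 1],
                                       thetas[((i - 1) %/% 4) %% 4 + 1],
                                       tau, env, reg, sm)
    i_squared(lit$g, lit$v)
  }, numeric(1))
})
i2_tab <- data.frame(tau = c(0, 0.11, 0.22, 0.33, 0.44),
                     mean_i2 = sapply(i2, mean),
                     median_i2 = sapply(i2, median))
write.csv(i2_tab, "results/i2_translation.csv", row.names = FALSE)
cat("\nI^2 translation of the heterogeneity ladder:\n")
print(round(i2_tab, 1))
cat("\nMedians rise from 0% at tau = 0 through the 30/60/80% range; the\n")
cat("exact means sit a few points below the original study's because I^2\n")
cat("responds to the full shape of the sample-size distribution, of which\n")
cat("only three summaries are recoverable.\n")
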
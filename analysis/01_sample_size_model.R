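#!/usr/bin/env Rscript
# Step 1: the synthetic sample-size model.
#
# Studies' total sample sizes are drawn from a capped lognormal calibrated to
# the printed summaries of the empirical per-study N distribution aggregated
# over 150 psychology meta-analyses: median 100, IQR 176, mean 123. This
# script draws from the model, confirms the calibration, and records the
# summaries used by later steps.

library(hetbias)

seed <- 20260920
n_draws <- 1e5

dir.create("results", showWarnings = FALSE)
set.seed(seed)

model <- sample_size_model()
print(model)

n <- draw_sample_size(model, n_draws)
summary_tab <- data.frame(
  statistic = c("median", "iqr", "mean", "min", "max", "prop_at_cap",
                "prop_below_30", "prop_at_least_200"),
  value = c(median(n), IQR(n), mean(n), min(n), max(n),
            mean(n == model$cap), mean(n < 30), mean(n >= 200)),
  target = c(100, 176, 123, NA, NA, NA, NA, NA)
)
write.csv(summary_tab, "results/sample_size_summary.csv", row.names = FALSE)
print(summary_tab, digits = 4)

cat(sprintf(
  "\nCalibration check on %d draws: median %.0f (target 100), IQR %.0f\n",
  n_draws, median(n), IQR(n)))
cat(sprintf("(target 176), mean %.1f (target 123). All draws even, within\n",
            mean(n)))
cat(sprintf("[%d, %d]. %.0f%% of studies sit at the cap, reflecting the\n",
            min(n), max(n), 100 * mean(n == model$cap)))
cat("compressed right tail needed to hold the mean at 123 alongside the\n")
cat("wide IQR; the optional-stopping ceiling of 200 makes the exact tail\n")
cat("shape above 200 immaterial for the p-hacking machinery.\n")
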
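#!/usr/bin/env Rscript
# Step 3: what publication bias and p-hacking do to published literatures.
#
# Three questions at desk scale: how much do the hacking environments shift
# the sample sizes of published studies; how badly is the pooled effect
# inflated when no true effect exists; and does the Knapp-Hartung test keep
# its nominal type-1 error under the two censoring regimes.

library(hetbias)

seed <- 20260920
dir.create("results", showWarnings = FALSE)
sm <- sample_size_model()

## -- published sample sizes under the hacking environments ------------------
set.seed(seed)
mean_n <- function(label, reps = 15) {
  env <- hacking_environment(label)
  acc <- c(analyzed = 0, collected = 0, studies = 0)
  for (tail in c("one", "two")) for (strength in c(0, 0.4, 0.8)) {
    reg <- bias_regime(tail, strength)
    for (theta in c(0, 0.2, 0.5, 0.8)) for (tau in c(0, 0.22, 0.44)) {
      for (r in seq_len(reps)) {
        lit <- sample_published_literature(9, theta, tau, env, reg, sm)
        acc <- acc + c(sum(lit$n), sum(lit$n_collected), lit$k)
      }
    }
  }
  c(analyzed = acc[[1]] / acc[[3]], collected = acc[[2]] / acc[[3]])
}
n_tab <- rbind(none = mean_n("none"), medium = mean_n("medium"),
               high = mean_n("high"))
write.csv(data.frame(hacking = rownames(n_tab), n_tab),
          "results/published_n.csv", row.names = FALSE)
cat("Mean published study size (both groups) by hacking environment:\n")
print(round(n_tab, 1))
cat("\nOptional stopping drags sample sizes up under medium hacking; under\n")
cat("high hacking the 12-analysis searchers find significance earlier, so\n")
cat("the analyzed-N mean falls back between the two.\n\n")

## -- effect-size inflation at theta = 0 -------------------------------------
set.seed(seed + 1)
cells <- list()
for (h in c("none", "medium", "high")) {
  for (strength in c(0, 0.4, 0.8)) {
    cells[[length(cells) + 1]] <-
      run_cell(h, "one", strength, 0.22, 0, 18, reps = 120,
               seed = seed + nchar(h) * 100 + strength * 10,
               estimators = "DL", tau_interval = FALSE)
  }
}
dsum <- do.call(rbind, cells)
write.csv(dsum, "results/effect_inflation.csv", row.names = FALSE)
cat("Mean pooled effect at theta = 0 under 1-tailed bias (DL):\n")
print(round(
  tapply(dsum$d_mean, dsum[, c("hacking", "pb_strength")], mean), 3)[
    c("none", "medium", "high"), ])
cat("\nBoth levers inflate the estimate; combined they push a true zero\n")
cat("effect beyond d = 0.3. The corresponding type-1 error of the\n")
cat("Knapp-Hartung test:\n")
print(round(
  tapply(dsum$rejection_rate, dsum[, c("hacking", "pb_strength")], mean), 2)[
    c("none", "medium", "high"), ])

## -- type-1 error under 2-tailed censoring stays nominal --------------------
set.seed(seed + 2)
rej <- unlist(lapply(c("none", "medium", "high"), function(h) {
  env <- hacking_environment(h)
  unlist(lapply(c(0.4, 0.8), function(strength) {
    reg <- bias_regime("two", strength)
    vapply(1:150, function(i) {
      lit <- sample_published_literature(18, 0, 0.22, env, reg, sm)
      kh_inference(lit$g, lit$v, tau2_dl(lit$g, lit$v))$p < 0.05
    }, logical(1))
  }))
}))
cat(sprintf("\nUnder 2-tailed censoring the type-1 error is %.1f%% (n = %d),\n",
            100 * mean(rej), length(rej)))
cat("close to the nominal 5%: symmetric censoring inflates spread, not the\n")
cat("mean, and the Knapp-Hartung variance absorbs the extra dispersion.\n")
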
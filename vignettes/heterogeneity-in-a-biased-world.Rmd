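---
title: "Evaluating heterogeneity estimators in biased literatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating heterogeneity estimators in biased literatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetbias)
```

## The problem

Random-effects meta-analysis of standardized mean differences (SMDs) models
the true effect of study $i$ as $\theta_i = \theta + \delta_i$ with
$\delta_i \sim N(0, \tau^2)$, and the observed effect as
$\hat\theta_i = \theta_i + \varepsilon_i$ with
$\varepsilon_i \sim N(0, \sigma_i^2)$. The heterogeneity SD $\tau$ is of
direct scientific interest: it says whether an effect is stable across
contexts. Simulation evaluations of $\tau^2$ estimators almost always assume
the meta-analysed studies are an unbiased sample of all studies run. Real
literatures are filtered by statistical significance (publication bias) and
distorted by analytic flexibility in the primary studies (p-hacking). This
package simulates that filtering at the participant level and asks how five
classical $\tau^2$ estimators — DerSimonian-Laird (DL), Hunter-Schmidt (HS),
maximum likelihood (ML), Paule-Mandel (PM) and restricted maximum likelihood
(REML) — hold up, for both heterogeneity and pooled-effect estimation.

## The generative model

Each simulated study is a two-group between-subjects experiment:

* a realized true effect `theta_i ~ N(theta, tau^2)` (`draw_true_effect()`);
* a total sample size from the calibrated model below, split equally;
* per participant, two outcome variables with within-group SD 1, population
  correlation $\rho = 0.8$, group-2 means shifted by `theta_i` on both, and a
  sex label assigned with probability 0.5 (`simulate_participants()`);
* the analysis (`analyze_two_groups()`) computes Hedges' $g$ with
  $J = 1 - 3/(4\,\mathrm{df} - 1)$, the large-sample variance
  $v = (n_1+n_2)/(n_1 n_2) + g^2 / (2(n_1+n_2))$, and the two-tailed
  pooled-variance t-test. Pooled (Student) rather than Welch was chosen
  because it is the convention behind the SMD variance formula above; the
  two coincide here anyway since group sizes and variances are equal by
  design.

### The sample-size model

The study sizes of real meta-analysed experiments are summarized by three
published numbers: median 100, interquartile range 176, mean 123 (totals
over both groups). No parametric family was stated, so `sample_size_model()`
uses a three-parameter stand-in: a lognormal, conditioned on $N \ge 10$ and
*capped* at 244 (draws above the cap are set to the cap), rounded to the
nearest even integer. The three parameters (meanlog 4.5583, sdlog 1.2082,
cap 244) were solved once so that all three published summaries are matched;
a rejection-truncated lognormal cannot do this, because discarding the right
tail that makes the mean 123 also compresses the IQR below 176. The price of
capping is a point mass (about 23% of draws) at 244. Two considerations make
this acceptable: the optional-stopping machinery tops out at $N = 200$
anyway, so the shape of the tail above 200 never interacts with p-hacking;
and about 28% of draws lie at or above 200, a plausible figure for a
distribution with this median and IQR. `empirical_size_model()` and
`read_sample_sizes()` accept a real list of even totals when one is
available, which replaces the stand-in entirely.

What the stand-in cannot guarantee is the *full shape* of the
sampling-variance distribution, and one downstream quantity is visibly
sensitive to it: the translation of $\tau$ levels into $I^2$. Our calibrated
model reproduces the medians (0% at $\tau = 0$, rising through the 30/60/80%
range) and the ordering of the means, but the mean $I^2$ at $\tau = 0.33$
computes to about 70% where the original distribution gave 78%. We report
this as is rather than reshaping the generator, since the shape is not
recoverable from the three published summaries.

## P-hacking

Four questionable research practices are implemented
(`researcher_profile()`), following their common stylized definitions:

* **optional dependent variables** — analyse both outcomes (they are
  correlated 0.8, so this is two dependent looks);
* **optional stopping** — after the starting sample, keep adding 10% of the
  starting total (rounded to the nearest even integer, at least 2) until
  significance or the ceiling of $\min(5 \times N_\text{start}, 200)$; when
  the starting total already exceeds 200 no extension is possible;
* **optional moderators** — analyse everyone, females only, males only;
* **optional outlier removal** — re-analyse after a single-pass removal of
  values with within-group $|z| \ge 2$.

A researcher using all four runs $2 \times 3 \times 2 = 12$ analyses per
peek (`enumerate_analyses()`). Research environments are archetype mixtures:
none (100% clean), medium (30% clean, 50% using optional DVs + stopping,
20% using all four) and high (10/40/50%).

Selection among analyses uses a *selection score* (`modified_p()`): under a
one-tailed regime the p-value for expected-direction results and
$1 + (1 - p)$ for wrong-direction results, so wrong-direction significance
is penalized rather than rewarded; under a two-tailed regime the raw
p-value. Three choices the stylized description leaves open were fixed as
follows:

* stopping triggers on a selection score below .05, so under the one-tailed
  regime a significant wrong-direction result does **not** stop collection
  (consistent with the score's purpose);
* if nothing is significant at the ceiling, the analysis with the smallest
  selection score is submitted anyway;
* ties are broken by a fixed enumeration order (dv1 before dv2, all before
  F before M, raw before outlier-removed), making runs deterministic under
  a seed;
* the published study's sample size is that of the *analysed* subset — what
  a meta-analyst would code from the paper — not the number collected; both
  are recorded (`n` and `n_collected` in the literature object).

A small arithmetical point worth knowing: with a sample-SD $z$ threshold of
2, no group of fewer than six values can ever lose a point, because the
maximum attainable $|z|$ is $(n-1)/\sqrt{n}$. Outlier removal therefore only
bites in the moderator subsets once they are reasonably large.

## Publication bias

`bias_regime()` censors submitted studies on significance
(`publish_decision()`): one-tailed — significant expected-direction results
always publish, significant wrong-direction results never publish,
non-significant results publish with probability $1 - \text{strength}$;
two-tailed — significant results publish regardless of sign. Strengths 0,
0.4 and 0.8 are the grid levels. A separate `"none"` regime publishes
everything: the one-tailed regime at strength 0 still censors
wrong-direction significance, so the bias-free baseline needs its own
setting. Censoring decisions are independent Bernoulli draws;
`sample_published_literature()` regenerates studies until exactly $k$
survive.

## The estimator layer

The five $\tau^2$ estimators are implemented from their defining equations
(`tau2_dl()`, `tau2_hs()`, `tau2_pm()`, `tau2_ml()`, `tau2_reml()`), all
truncating negative solutions to zero. Numerical choices:

* **PM** solves the generalized-$Q$ equation
  $\sum (g_i - \hat\theta(\tau^2))^2 / (v_i + \tau^2) = k - 1$ by bracketed
  root search (the statistic is strictly decreasing in $\tau^2$), tolerance
  1e-10, with the bracket expanded geometrically until it straddles the
  root; the estimate is 0 when the statistic at $\tau^2 = 0$ is already
  below $k - 1$. Convergence is guaranteed.
* **ML/REML** use the standard fixed-point iterations with the pooled
  effect re-estimated under weights $1/(v_i + \tau^2)$ each cycle,
  numerator $(g_i - \hat\theta)^2 - v_i$ (the minus sign is the form whose
  fixed point is a stationary point of the stated likelihoods; the tests
  adjudicate this against brute-force grid maximization), tolerance 1e-8 on
  successive values, 100 iterations. Non-convergence is a reported state;
  the Monte-Carlo engine replaces such replicates and counts them.
* **Knapp-Hartung** inference uses
  $\widehat{\mathrm{Var}}(\hat\theta) = \sum w_i (g_i - \hat\theta)^2 /
  ((k-1) \sum w_i)$ with a $t_{k-1}$ reference, *without* truncating the
  adjustment factor at 1.
* The $\tau$ interval is the Q-profile interval (bounds where the
  generalized $Q$ equals the $\chi^2_{k-1}$ 0.025/0.975 quantiles,
  truncated at 0) for every estimator; $I^2 = \max(0, (Q - (k-1))/Q)$.

A degenerate corner: on a zero-dispersion sample the Knapp-Hartung standard
error is 0; the p-value is defined as 1 when the pooled estimate is 0 and 0
otherwise (an infinitely precise nonzero estimate).

## The Monte-Carlo engine

`build_grid()` fully crosses hacking environment, bias tail, bias strength,
$\tau \in \{0, .11, .22, .33, .44\}$, $\theta \in \{0, .2, .5, .8\}$ and
$k \in \{9, 18, 36, 72\}$ — 1,440 cells at full scale. `run_cell()` fits all
five estimators to the *same* literatures (a paired design; replicates are
replaced wholesale when ML or REML fails to converge), and summarizes
$T$ bias, SD and RMSE, pooled-effect bias, interval coverages, the
Knapp-Hartung rejection rate and the Monte-Carlo error $\mathrm{SD}(T) /
\sqrt{\text{reps}}$. Seeds are derived deterministically per cell and per
replicate, so any single meta-analysis is reproducible in isolation and
identical seeds give identical output bytes.

`factorial_ss()` decomposes per-cell means over a balanced grid into main
effects, 2-way and 3-way interaction sums of squares via the classical
orthogonal decomposition (computed with `stats::aov`; a hand
mean-contrast oracle checks it in the tests), pooling all higher orders
into Error. Using the 1,440 cell means as observations is the reading under
which the published Error terms (~0.03–0.08) are consistent with the listed
sums; the decomposition is refused on unbalanced or incomplete grids rather
than approximated.

## Problem sizes

The original experiment (1,440 cells × 1,000 replicates with
participant-level p-hacking) is cluster-scale. The analysis scripts and
tests run desk-scale versions, chosen as the package's own defaults: 400–500
replicates per cell for unbiased-recovery summaries (Monte-Carlo error on
mean $T$ about 0.003), 2,000 meta-analyses for $I^2$ and type-1-error
summaries, and a reduced fully crossed grid (3 × 2 × 3 × 3 × 3 × 2 = 324
cells, replicates 10) for the ANOVA, which preserves balance and the full
range of every factor. At these sizes the estimator-volatility ordering and
the additivity of hacking and censoring are stable across seeds; cell-level
values carry visible Monte-Carlo noise.

## What the generator does and does not emulate

It emulates: significance-contingent selection at the study level, analytic
multiplicity with realistically correlated looks, sequential sampling with
a hard ceiling, direction-sensitive selection, and a realistic spread of
study sizes. It does not emulate: effect-size-contingent censoring,
researcher learning across studies, covariate or transformation hacking,
unequal group allocation, binary outcomes, or correlation between the
censoring fates of related studies. Passing tests therefore speak to the
behaviour of heterogeneity estimators under *this* bias mechanism, not to
any particular empirical literature.

## Known limitations

* The sample-size stand-in reproduces three summaries of the empirical
  distribution, not its shape; $I^2$ means inherit a few points of
  downward shift (see above), and published-$N$ means land within about
  ten participants of the original study's values rather than on them.
* The ML/REML fixed point is linearly convergent; near-degenerate samples
  at the truncation boundary can exhaust the iteration cap and are then
  replaced, mirroring the original procedure but at a slightly different
  (unreported) rate.
* One-CPU execution: cells are independent and `run_experiment()` resumes
  from per-cell files, but no parallel backend is wired in.
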
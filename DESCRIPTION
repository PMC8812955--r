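Package: hetbias
Title: Heterogeneity Estimation in Meta-Analysis of Biased Literatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo machinery for evaluating random-effects heterogeneity
    estimators when the published literature is distorted by publication bias
    and p-hacking. Simulates participant-level two-group experiments with
    standardized mean difference outcomes, applies four questionable research
    practices (optional dependent variables, optional stopping, optional
    moderators, optional outlier removal) mixed over researcher archetypes,
    censors submissions under one- or two-tailed significance-contingent
    publication bias, and fits the random-effects model from scratch with five
    tau-squared estimators (DerSimonian-Laird, Hunter-Schmidt, maximum
    likelihood, Paule-Mandel, restricted maximum likelihood), Knapp-Hartung
    inference, Q-profile heterogeneity intervals and I-squared. A factorial
    simulation engine summarises estimator bias, root mean square error,
    coverage and type-1 error over the crossed design and decomposes the
    results by balanced six-factor ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
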
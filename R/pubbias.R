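#' Publication-bias regimes
#'
#' Censoring of submitted studies is contingent on statistical significance
#' (two-tailed testing at alpha = .05). Under the one-tailed regime,
#' significant results in the expected (positive) direction are always
#' published, significant wrong-direction results are always censored, and
#' non-significant results are censored with probability `strength`. Under
#' the two-tailed regime significant results are published regardless of
#' sign and non-significant results are censored with probability
#' `strength`. The `"none"` regime publishes everything and represents the
#' bias-free baseline.
#'
#' @param tail `"one"`, `"two"`, or `"none"` (publish everything).
#' @param strength Proportion of non-significant studies censored, in
#'   `[0, 1]`.
#' @param alpha Significance threshold, default 0.05.
#' @return An object of class `bias_regime`.
#' @export
bias_regime <- function(tail = c("none", "one", "two"), strength = 0,
                        alpha = 0.05) {
  tail <- match.arg(tail)
  stopifnot(strength >= 0, strength <= 1)
  structure(list(tail = tail, strength = strength, alpha = alpha),
            class = "bias_regime")
}

#' Decide whether a submitted study is published
#'
#' @param result A `study_result` (needs fields `p` and `direction`).
#' @param regime A [bias_regime()].
#' @return Logical.
#' @export
publish_decision <- function(result, regime) {
  stopifnot(inherits(regime, "bias_regime"))
  if (regime$tail == "none") return(TRUE)
  significant <- result$p < regime$alpha
  if (regime$tail == "one") {
    if (significant && result$direction > 0) return(TRUE)
    if (significant) return(FALSE)  # wrong-direction significant
    return(stats::runif(1) >= regime$strength)
  }
  # two-tailed
  if (significant) return(TRUE)
  stats::runif(1) >= regime$strength
}

#' Assemble the published literature feeding one meta-analysis
#'
#' Repeatedly generates researcher -> study -> submission -> publication
#' decision until exactly `k` published studies accumulate. Each study draws
#' its own realized true effect, starting sample size and researcher
#' archetype.
#'
#' @param k Number of published studies required (`>= 2`).
#' @param theta Average true effect.
#' @param tau True heterogeneity SD.
#' @param environment A [hacking_environment()].
#' @param regime A [bias_regime()].
#' @param size_model A [sample_size_model()].
#' @param rho Population correlation of the two outcomes.
#' @return A list of class `published_literature` with vectors `g`, `v`,
#'   `n` (analysed total), `n_collected`, `p`, plus counters `k`,
#'   `n_generated` (studies run, published or not) and `n_invalid`
#'   (regenerated degenerate studies).
#' @export
sample_published_literature <- function(k, theta, tau, environment, regime,
                                        size_model = sample_size_model(),
                                        rho = 0.8) {
  stopifnot(k >= 2,
            inherits(environment, "hacking_environment"),
            inherits(regime, "bias_regime"),
            inherits(size_model, "sample_size_model"))
  one_tailed <- regime$tail != "two"   # selection score under "none" too
  weights <- environment$weights
  empirical <- size_model$mode == "empirical-list"
  if (!empirical) {
    p_lo <- stats::plnorm(size_model$min_n, size_model$meanlog,
                          size_model$sdlog)
  }
  alpha <- regime$alpha
  censor_none <- regime$tail == "none"
  strength <- regime$strength
  g <- v <- p <- numeric(k)
  n <- n_coll <- integer(k)
  got <- 0L
  generated <- 0L
  invalid <- 0L
  while (got < k) {
    arch <- sample.int(3L, 1L, prob = weights)  # 1 none, 2 dv+stop, 3 all-four
    theta_i <- if (tau == 0) theta else stats::rnorm(1L, theta, tau)
    n0 <- if (empirical) {
      size_model$n[sample.int(length(size_model$n), 1L)]
    } else {
      u <- stats::runif(1L, p_lo, 1)
      max(size_model$min_n,
          as.integer(2 * round(min(stats::qlnorm(u, size_model$meanlog,
                                                 size_model$sdlog),
                                   size_model$cap) / 2)))
    }
    res <- .run_study_fast(
      theta_i,
      use_dvs = arch >= 2L, use_stop = arch >= 2L,
      use_mods = arch == 3L, use_outs = arch == 3L,
      start_n = n0,
      increment = max(2L, as.integer(2 * round(0.1 * n0 / 2))),
      max_n = max(min(5L * n0, 200L), n0),
      one_tailed = one_tailed, rho = rho)
    if (is.null(res)) {
      invalid <- invalid + 1L
      next
    }
    generated <- generated + 1L
    published <- if (censor_none) {
      TRUE
    } else if (res$p < alpha) {
      regime$tail == "two" || res$direction > 0
    } else {
      stats::runif(1L) >= strength
    }
    if (published) {
      got <- got + 1L
      g[got] <- res$g
      v[got] <- res$v
      p[got] <- res$p
      n[got] <- res$n1 + res$n2
      n_coll[got] <- res$n_collected
    }
  }
  structure(list(g = g, v = v, p = p, n = n, n_collected = n_coll, k = k,
                 n_generated = generated, n_invalid = invalid),
            class = "published_literature")
}

#' @export
print.published_literature <- function(x, ...) {
  cat(sprintf(
    "Published literature: k = %d studies (from %d generated), mean g = %.3f\n",
    x$k, x$n_generated, mean(x$g)))
  invisible(x)
}
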
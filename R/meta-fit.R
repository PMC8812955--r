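#' Pool study effects under random-effects weights
#'
#' @param g,v Study effects and sampling variances.
#' @param tau2 Heterogeneity variance estimate (`>= 0`).
#' @return List with `theta_hat` and the weights `w = 1/(v + tau2)`.
#' @export
pool_effect <- function(g, v, tau2) {
  check_meta_sample(g, v)
  stopifnot(tau2 >= 0)
  w <- 1 / (v + tau2)
  list(theta_hat = sum(w * g) / sum(w), w = w)
}

#' Knapp-Hartung inference for the pooled effect
#'
#' Uses the weighted-deviation variance estimator
#' `Var = sum(w (g - theta)^2) / ((k - 1) sum(w))` and a t reference
#' distribution with `k - 1` degrees of freedom. The adjustment factor is not
#' truncated at 1. With a degenerate zero-dispersion sample the standard
#' error is zero: the p-value is then 1 when the pooled estimate is 0 and 0
#' otherwise.
#'
#' @param g,v Study effects and sampling variances.
#' @param tau2 Heterogeneity variance estimate.
#' @param alpha Two-sided level for the confidence interval.
#' @return List with `theta_hat`, `se`, `t`, `p`, `ci` (length 2), `df`.
#' @export
kh_inference <- function(g, v, tau2, alpha = 0.05) {
  k <- check_meta_sample(g, v)
  fit <- pool_effect(g, v, tau2)
  w <- fit$w
  theta <- fit$theta_hat
  df <- k - 1
  var_kh <- sum(w * (g - theta)^2) / (df * sum(w))
  se <- sqrt(var_kh)
  if (se == 0) {
    tstat <- if (theta == 0) 0 else Inf * sign(theta)
    p <- if (theta == 0) 1 else 0
    ci <- c(theta, theta)
  } else {
    tstat <- theta / se
    p <- 2 * stats::pt(-abs(tstat), df)
    crit <- stats::qt(1 - alpha / 2, df)
    ci <- theta + c(-1, 1) * crit * se
  }
  list(theta_hat = theta, se = se, t = tstat, p = p, ci = ci, df = df)
}

#' Q-profile confidence interval for tau
#'
#' Bounds are the tau^2 values at which the generalized Q statistic equals
#' the chi-square (k-1) quantiles 0.975 (lower bound) and 0.025 (upper
#' bound); bounds where the equation has no non-negative solution are
#' truncated at 0. Returned on the tau (SD) scale.
#'
#' @param g,v Study effects and sampling variances.
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)` for tau.
#' @export
tau_ci <- function(g, v, level = 0.95) {
  k <- check_meta_sample(g, v)
  a <- (1 - level) / 2
  q_hi <- stats::qchisq(1 - a, k - 1)  # defines the lower bound
  q_lo <- stats::qchisq(a, k - 1)      # defines the upper bound
  bound <- function(target) {
    if (gen_q(0, g, v) <= target) return(0)
    hi <- 10
    while (gen_q(hi, g, v) > target) hi <- hi * 2
    stats::uniroot(function(t2) gen_q(t2, g, v) - target,
                   lower = 0, upper = hi, tol = 1e-10)$root
  }
  sqrt(c(bound(q_hi), bound(q_lo)))
}

#' I-squared heterogeneity percentage
#'
#' Computed from the fixed-effect-weights Q statistic as
#' `max(0, (Q - (k - 1)) / Q) * 100`; defined as 0 when `Q = 0`.
#'
#' @param g,v Study effects and sampling variances.
#' @return Percentage in `[0, 100]`.
#' @export
i_squared <- function(g, v) {
  k <- check_meta_sample(g, v)
  w <- 1 / v
  theta_fe <- sum(w * g) / sum(w)
  q <- sum(w * (g - theta_fe)^2)
  if (q <= 0) return(0)
  max(0, (q - (k - 1)) / q) * 100
}

#' Fit a random-effects meta-analysis
#'
#' Full fit with a chosen heterogeneity estimator: tau^2, random-effects
#' pooled estimate, Knapp-Hartung test and confidence interval, Q-profile
#' interval for tau, and I-squared.
#'
#' @param g,v Study effects and sampling variances.
#' @param estimator One of `"DL"`, `"HS"`, `"ML"`, `"PM"`, `"REML"`.
#' @param alpha Two-sided level for the pooled-effect interval.
#' @param tau_interval Compute the Q-profile interval for tau? (Skipping it
#'   saves two root searches per fit in large simulations.)
#' @return An object of class `refit`.
#' @examples
#' g <- c(0.1, 0.5, 0.9); v <- rep(0.04, 3)
#' rema(g, v, "REML")
#' @export
rema <- function(g, v, estimator = c("DL", "HS", "ML", "PM", "REML"),
                 alpha = 0.05, tau_interval = TRUE) {
  estimator <- match.arg(estimator)
  k <- check_meta_sample(g, v)
  est <- estimate_tau2(g, v, estimator)
  kh <- kh_inference(g, v, est$tau2, alpha)
  w <- 1 / v
  theta_fe <- sum(w * g) / sum(w)
  structure(list(
    estimator = estimator,
    k = k,
    tau2_hat = est$tau2,
    tau_hat = sqrt(est$tau2),
    theta_hat = kh$theta_hat,
    kh_se = kh$se,
    kh_t = kh$t,
    kh_p = kh$p,
    kh_ci = kh$ci,
    tau_ci = if (tau_interval) tau_ci(g, v) else c(NA_real_, NA_real_),
    q_statistic = sum(w * (g - theta_fe)^2),
    i_squared = i_squared(g, v),
    converged = est$converged,
    iterations = est$iterations
  ), class = "refit")
}

#' @export
print.refit <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis (%s), k = %d\n", x$estimator, x$k))
  cat(sprintf("  pooled effect: %.4f [%.4f, %.4f], KH p = %.4g\n",
              x$theta_hat, x$kh_ci[1], x$kh_ci[2], x$kh_p))
  cat(sprintf("  tau^2 = %.4f (tau = %.4f, 95%% CI [%.4f, %.4f])\n",
              x$tau2_hat, x$tau_hat, x$tau_ci[1], x$tau_ci[2]))
  cat(sprintf("  Q = %.3f, I^2 = %.1f%%%s\n", x$q_statistic, x$i_squared,
              if (!x$converged) "  [estimator did not converge]" else ""))
  invisible(x)
}

#' Read or write a study table (effect, variance per row)
#'
#' CSV with columns `effect`, `variance` and optionally `n1`, `n2`, so the
#' estimator layer can be used standalone on real meta-analytic data.
#'
#' @param path File path.
#' @return `read_study_table()`: a data frame. `write_study_table()`: the
#'   path, invisibly.
#' @export
read_study_table <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("effect", "variance") %in% names(d))) {
    stop("study table needs columns 'effect' and 'variance'")
  }
  if (any(d$variance <= 0)) stop("all variances must be > 0")
  d
}

#' @rdname read_study_table
#' @param table Data frame with at least `effect` and `variance` columns.
#' @export
write_study_table <- function(table, path) {
  stopifnot(all(c("effect", "variance") %in% names(table)))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
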
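#' Heterogeneity variance estimators for random-effects meta-analysis
#'
#' Five classical estimators of the between-study variance tau^2 of the
#' random-effects model, all truncating negative solutions to zero:
#'
#' * `tau2_dl()` — DerSimonian-Laird, the moment estimator with
#'   fixed-effect weights `1/v`;
#' * `tau2_hs()` — Hunter-Schmidt, `(Q - k) / sum(w)` with fixed-effect
#'   weights;
#' * `tau2_pm()` — Paule-Mandel, the moment estimator with random-effects
#'   weights `1/(v + tau^2)`, found by solving the generalized Q equation
#'   `Q_gen(tau^2) = k - 1` (monotone in tau^2, so the root is bracketed);
#' * `tau2_ml()` — maximum likelihood, via the standard fixed-point
#'   iteration with jointly re-estimated pooled effect;
#' * `tau2_reml()` — restricted maximum likelihood, the same iteration with
#'   the degrees-of-freedom correction term `1/sum(w)`.
#'
#' @param g Study effect estimates (e.g. Hedges g).
#' @param v Study sampling variances, all `> 0`.
#' @param tol Convergence tolerance (successive tau^2 values for ML/REML,
#'   root residual for PM).
#' @param max_iter Iteration cap for ML/REML.
#' @return `tau2_dl` and `tau2_hs` return a single number. `tau2_pm`,
#'   `tau2_ml` and `tau2_reml` return a list with `tau2`, `converged`, and
#'   `iterations`.
#' @examples
#' g <- c(0.1, 0.5, 0.9); v <- rep(0.04, 3)
#' tau2_dl(g, v)
#' tau2_reml(g, v)$tau2
#' @name tau2-estimators
NULL

check_meta_sample <- function(g, v) {
  if (length(g) != length(v)) stop("g and v must have equal length")
  if (length(g) < 2L) stop("need at least k = 2 studies")
  if (any(v <= 0)) stop("all sampling variances must be > 0")
  invisible(length(g))
}

#' @rdname tau2-estimators
#' @export
tau2_dl <- function(g, v) {
  k <- check_meta_sample(g, v)
  w <- 1 / v
  theta_fe <- sum(w * g) / sum(w)
  q <- sum(w * (g - theta_fe)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (k - 1)) / denom)
}

#' @rdname tau2-estimators
#' @export
tau2_hs <- function(g, v) {
  k <- check_meta_sample(g, v)
  w <- 1 / v
  theta_fe <- sum(w * g) / sum(w)
  q <- sum(w * (g - theta_fe)^2)
  max(0, (q - k) / sum(w))
}

# Generalized Q statistic at a trial value of tau^2: weighted squared
# deviations from the pooled effect under weights 1/(v + tau^2).
gen_q <- function(tau2, g, v) {
  w <- 1 / (v + tau2)
  theta <- sum(w * g) / sum(w)
  sum(w * (g - theta)^2)
}

#' @rdname tau2-estimators
#' @export
tau2_pm <- function(g, v, tol = 1e-10, max_iter = 100L) {
  k <- check_meta_sample(g, v)
  target <- k - 1
  if (gen_q(0, g, v) <= target) {
    return(list(tau2 = 0, converged = TRUE, iterations = 0L))
  }
  # gen_q is strictly decreasing in tau^2; expand the bracket until it
  # straddles the target (gen_q -> 0 as tau^2 -> Inf, so this terminates)
  hi <- 10
  while (gen_q(hi, g, v) > target) hi <- hi * 2
  root <- stats::uniroot(function(t2) gen_q(t2, g, v) - target,
                         lower = 0, upper = hi, tol = tol)
  list(tau2 = root$root, converged = TRUE, iterations = root$iter)
}

# Shared ML/REML fixed-point driver; `restricted` adds the 1/sum(w) term.
fixed_point_tau2 <- function(g, v, restricted, tol, max_iter) {
  tau2 <- max(0, tau2_dl(g, v))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- 1 / (v + tau2)
    theta <- sum(w * g) / sum(w)
    adj <- if (restricted) 1 / sum(w) else 0
    new <- sum(w^2 * ((g - theta)^2 - v)) / sum(w^2) + adj
    new <- max(0, new)
    if (abs(new - tau2) < tol) {
      tau2 <- new
      converged <- TRUE
      break
    }
    tau2 <- new
  }
  list(tau2 = tau2, converged = converged, iterations = iter)
}

#' @rdname tau2-estimators
#' @export
tau2_ml <- function(g, v, tol = 1e-8, max_iter = 100L) {
  check_meta_sample(g, v)
  fixed_point_tau2(g, v, restricted = FALSE, tol = tol, max_iter = max_iter)
}

#' @rdname tau2-estimators
#' @export
tau2_reml <- function(g, v, tol = 1e-8, max_iter = 100L) {
  check_meta_sample(g, v)
  fixed_point_tau2(g, v, restricted = TRUE, tol = tol, max_iter = max_iter)
}

#' Estimate tau^2 by name
#'
#' @param g,v Study effects and sampling variances.
#' @param estimator One of `"DL"`, `"HS"`, `"ML"`, `"PM"`, `"REML"`.
#' @param ... Passed to the iterative estimators.
#' @return List with `tau2`, `converged`, `iterations`.
#' @export
estimate_tau2 <- function(g, v, estimator = c("DL", "HS", "ML", "PM", "REML"),
                          ...) {
  estimator <- match.arg(estimator)
  switch(estimator,
    DL   = list(tau2 = tau2_dl(g, v), converged = TRUE, iterations = 0L),
    HS   = list(tau2 = tau2_hs(g, v), converged = TRUE, iterations = 0L),
    PM   = tau2_pm(g, v, ...),
    ML   = tau2_ml(g, v, ...),
    REML = tau2_reml(g, v, ...))
}
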
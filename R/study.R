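#' Draw realized per-study true effects under the random-effects model
#'
#' The random-effects model places the true effect of study *i* at
#' \eqn{\theta_i = \theta + \delta_i} with \eqn{\delta_i \sim N(0, \tau^2)}.
#'
#' @param theta Average true effect (SMD units).
#' @param tau True heterogeneity SD (SMD units), `tau >= 0`.
#' @param size Number of studies.
#' @return Numeric vector of realized true effects; exactly `theta` when
#'   `tau = 0`.
#' @export
draw_true_effect <- function(theta, tau, size = 1L) {
  if (tau < 0) stop("tau must be >= 0")
  if (tau == 0) return(rep(theta, size))
  stats::rnorm(size, theta, tau)
}

#' Simulate participants of a two-group experiment
#'
#' Generates a between-subjects experiment with two equally sized groups and
#' two continuous outcomes. Within each group both outcomes have population
#' SD 1 and correlation rho; group 2 means exceed group 1 means by `theta_i`
#' population SDs on both outcomes. Participant sex is assigned independently
#' with probability 0.5, so that sex-based subgroup analyses are slices of
#' pure noise.
#'
#' @param theta_i Realized true effect of this study (SMD units).
#' @param n_total Total sample size, an even integer `>= 4`; split equally
#'   between groups.
#' @param rho Population correlation between the two outcomes.
#' @return A data frame with columns `group` (1/2), `sex` ("F"/"M"), `dv1`,
#'   `dv2`.
#' @examples
#' d <- simulate_participants(0.5, 100)
#' tapply(d$dv1, d$group, mean)
#' @export
simulate_participants <- function(theta_i, n_total, rho = 0.8) {
  if (n_total %% 2 != 0 || n_total < 4) {
    stop("n_total must be an even integer >= 4")
  }
  half <- n_total / 2L
  group <- rep(c(1L, 2L), each = half)
  shift <- (group - 1L) * theta_i
  z1 <- stats::rnorm(n_total)
  z2 <- stats::rnorm(n_total)
  dv1 <- shift + z1
  dv2 <- shift + rho * z1 + sqrt(1 - rho^2) * z2
  sex <- ifelse(stats::runif(n_total) < 0.5, "F", "M")
  data.frame(group = group, sex = sex, dv1 = dv1, dv2 = dv2,
             stringsAsFactors = FALSE)
}

#' Append newly collected participants to an experiment
#'
#' Used by optional stopping: the original rows are unchanged and `increment`
#' new participants are drawn from the same population, split equally
#' between the groups.
#'
#' @param table Data frame from [simulate_participants()].
#' @param increment Even integer `>= 2`, number of new participants.
#' @param theta_i Realized true effect of the study.
#' @param rho Population correlation between the two outcomes.
#' @return The grown participant table.
#' @export
add_participants <- function(table, increment, theta_i, rho = 0.8) {
  if (increment %% 2 != 0 || increment < 2) {
    stop("increment must be an even integer >= 2")
  }
  if (increment >= 4L) {
    new <- simulate_participants(theta_i, increment, rho)
  } else {
    # two-participant block, same draw order as larger blocks
    z1 <- stats::rnorm(2)
    z2 <- stats::rnorm(2)
    sF <- stats::runif(2) < 0.5
    shift <- c(0, theta_i)
    new <- data.frame(group = c(1L, 2L),
                      sex = ifelse(sF, "F", "M"),
                      dv1 = shift + z1,
                      dv2 = shift + rho * z1 + sqrt(1 - rho^2) * z2,
                      stringsAsFactors = FALSE)
  }
  rbind(table, new)
}

#' Analyze a two-group comparison as a standardized mean difference
#'
#' Computes the bias-corrected SMD (Hedges g), its large-sample sampling
#' variance, and the two-tailed p-value of the pooled-variance two-sample
#' t-test. The correction factor is J = 1 - 3/(4 df - 1) with
#' df = n1 + n2 - 2, and the variance is
#' (n1+n2)/(n1 n2) + g^2 / (2 (n1+n2)).
#'
#' @param x1,x2 Numeric outcome vectors for group 1 and group 2 (at least two
#'   values each).
#' @return A list of class `study_result` with elements `g`, `v`, `p`,
#'   `direction` (sign of mean(x2) - mean(x1)), `n1`, `n2`, `valid`
#'   (FALSE when the pooled variance is zero, in which case `g`, `v`, `p`
#'   are `NA`).
#' @examples
#' analyze_two_groups(rnorm(50), rnorm(50, 0.5))
#' @export
analyze_two_groups <- function(x1, x2) {
  n1 <- length(x1)
  n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 values per group")
  m1 <- sum(x1) / n1
  m2 <- sum(x2) / n2
  ss1 <- sum((x1 - m1)^2)
  ss2 <- sum((x2 - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  diff <- m2 - m1
  if (sp2 <= 0) {
    return(structure(list(g = NA_real_, v = NA_real_, p = NA_real_,
                          direction = sign(diff), n1 = n1, n2 = n2,
                          valid = FALSE),
                     class = "study_result"))
  }
  sp <- sqrt(sp2)
  d <- diff / sp
  j <- 1 - 3 / (4 * df - 1)
  g <- j * d
  ntot <- n1 + n2
  v <- ntot / (n1 * n2) + g^2 / (2 * ntot)
  tstat <- diff / (sp * sqrt(1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(g = g, v = v, p = p, direction = sign(diff),
                 n1 = n1, n2 = n2, valid = TRUE),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("SMD study result: g = %.4f (v = %.4f), p = %.4g, n = %d + %d\n",
              x$g, x$v, x$p, x$n1, x$n2))
  invisible(x)
}
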
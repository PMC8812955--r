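#' Researcher profiles and p-hacking environments
#'
#' A researcher profile records which of the four questionable research
#' practices a simulated researcher uses: optional dependent variables (two
#' correlated outcomes analysed instead of one), optional stopping (repeated
#' peeking with incremental data collection), optional moderators (analysing
#' females only and males only in addition to the full sample), and optional
#' outlier removal (re-analysis after dropping |z| >= 2 values).
#'
#' Three archetypes occur in the simulated research environments:
#' `"none"` (no practice used), `"dv+stop"` (optional DVs and optional
#' stopping), and `"all-four"`.
#'
#' @param archetype One of `"none"`, `"dv+stop"`, `"all-four"`.
#' @return A list of class `researcher_profile` with logical fields
#'   `uses_optional_dvs`, `uses_optional_stopping`,
#'   `uses_optional_moderators`, `uses_optional_outliers`.
#' @export
researcher_profile <- function(archetype = c("none", "dv+stop", "all-four")) {
  archetype <- match.arg(archetype)
  flags <- switch(archetype,
    "none"     = c(FALSE, FALSE, FALSE, FALSE),
    "dv+stop"  = c(TRUE,  TRUE,  FALSE, FALSE),
    "all-four" = c(TRUE,  TRUE,  TRUE,  TRUE))
  structure(list(archetype = archetype,
                 uses_optional_dvs = flags[1],
                 uses_optional_stopping = flags[2],
                 uses_optional_moderators = flags[3],
                 uses_optional_outliers = flags[4]),
            class = "researcher_profile")
}

#' @describeIn researcher_profile Mixture of archetypes in a research
#'   environment: `"none"` publishes only unhacked studies; `"medium"` mixes
#'   30% none / 50% dv+stop / 20% all-four; `"high"` mixes 10% / 40% / 50%.
#' @param label One of `"none"`, `"medium"`, `"high"`.
#' @export
hacking_environment <- function(label = c("none", "medium", "high")) {
  label <- match.arg(label)
  w <- switch(label,
    none   = c(1.0, 0.0, 0.0),
    medium = c(0.30, 0.50, 0.20),
    high   = c(0.10, 0.40, 0.50))
  structure(list(label = label,
                 archetypes = c("none", "dv+stop", "all-four"),
                 weights = w),
            class = "hacking_environment")
}

#' Draw a researcher archetype from an environment
#'
#' @param environment A [hacking_environment()].
#' @return A `researcher_profile`.
#' @export
draw_researcher <- function(environment) {
  stopifnot(inherits(environment, "hacking_environment"))
  a <- sample(environment$archetypes, 1L, prob = environment$weights)
  researcher_profile(a)
}

#' Optional-stopping rule derived from the starting sample size
#'
#' Data collection proceeds in increments of 10% of the starting total
#' (rounded to the nearest even integer, at least 2) up to a maximum of five
#' times the starting total or 200, whichever is lower. When the starting
#' total already exceeds that maximum, no extension is possible.
#'
#' @param start_n Starting total sample size (even integer `>= 4`).
#' @return A list of class `stopping_rule` with `start_n`, `increment`,
#'   `max_n`.
#' @export
stopping_rule <- function(start_n) {
  stopifnot(start_n %% 2 == 0, start_n >= 4)
  increment <- max(2L, as.integer(2 * round(0.1 * start_n / 2)))
  max_n <- max(min(5L * start_n, 200L), start_n)
  structure(list(start_n = as.integer(start_n), increment = increment,
                 max_n = as.integer(max_n)),
            class = "stopping_rule")
}

#' Single-pass outlier removal within a group
#'
#' Removes values whose unsigned within-group z score is `>= threshold`.
#' With zero group SD no value has a finite z, so nothing is removed.
#'
#' @param x Numeric vector (one group's values on the analysed outcome).
#' @param threshold Unsigned z cutoff, default 2.
#' @return The vector with outliers removed (single pass, not iterated).
#' @export
remove_outliers <- function(x, threshold = 2) {
  if (length(x) < 2L) stop("need at least 2 values")
  .drop_outliers(x, threshold)
}

#' Selection score used to pick among hacked analyses
#'
#' Under a one-tailed regime the score equals the p-value for results in the
#' expected (positive) direction and `1 + (1 - p)` for wrong-direction
#' results, so stronger wrong-direction effects are penalised harder. Under a
#' two-tailed regime the score is the p-value regardless of sign.
#'
#' @param p Two-tailed p-value in (0, 1].
#' @param direction Sign of the observed mean difference (+1/0/-1).
#' @param tail One of `"one"`, `"two"`.
#' @return The selection score (not a probability under `"one"`).
#' @export
modified_p <- function(p, direction, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (tail == "two") return(p)
  ifelse(direction < 0, 1 + (1 - p), p)
}

#' Enumerate all analyses a researcher's profile licenses
#'
#' The analysis set is the Cartesian product of outcome choice (dv1, and dv2
#' if optional DVs), participant subset (all, and females only / males only
#' if optional moderators) and outlier handling (raw, and outliers removed if
#' optional outlier removal). An all-four profile therefore yields 12
#' analyses per peek. Analyses whose subsets leave fewer than two
#' participants in either group, or whose pooled variance is zero, are
#' dropped as invalid.
#'
#' @param table Participant data frame from [simulate_participants()].
#' @param profile A [researcher_profile()].
#' @return List of `study_result` objects, each augmented with descriptor
#'   fields `dv`, `subset`, `outliers_removed`, in the fixed enumeration
#'   order dv1 < dv2, all < F < M, raw < removed (used for tie-breaking).
#' @export
enumerate_analyses <- function(table, profile) {
  stopifnot(nrow(table) > 0, inherits(profile, "researcher_profile"))
  g1 <- table$group == 1L
  dvs <- if (profile$uses_optional_dvs) c("dv1", "dv2") else "dv1"
  subsets <- if (profile$uses_optional_moderators) c("all", "F", "M") else "all"
  outs <- if (profile$uses_optional_outliers) c(FALSE, TRUE) else FALSE
  res <- vector("list", length(dvs) * length(subsets) * length(outs))
  i <- 0L
  for (dv in dvs) {
    y <- table[[dv]]
    for (ss in subsets) {
      keep <- if (ss == "all") rep(TRUE, nrow(table)) else table$sex == ss
      x1 <- y[g1 & keep]
      x2 <- y[!g1 & keep]
      for (out in outs) {
        i <- i + 1L
        if (length(x1) < 2L || length(x2) < 2L) next
        a1 <- if (out) remove_outliers(x1) else x1
        a2 <- if (out) remove_outliers(x2) else x2
        if (length(a1) < 2L || length(a2) < 2L) next
        r <- analyze_two_groups(a1, a2)
        if (!r$valid) next
        r$dv <- dv
        r$subset <- ss
        r$outliers_removed <- out
        res[[i]] <- r
      }
    }
  }
  res[!vapply(res, is.null, logical(1))]
}

#' Run one (possibly p-hacked) study and pick the submitted result
#'
#' Simulates the starting sample, enumerates the licensed analyses, and —
#' for researchers who use optional stopping — keeps adding the increment
#' and re-running all analyses until one is "significant" or the maximum
#' sample size is reached. Significance for stopping means selection score
#' < 0.05: under a one-tailed regime a wrong-direction result never stops
#' collection, under two-tailed any p < .05 does. At termination the analysis
#' with the smallest selection score among the final peek's analyses is
#' submitted; its analysed group sizes are the study's reported sample sizes.
#'
#' @param theta_i Realized true effect of the study.
#' @param profile A [researcher_profile()].
#' @param stopping A [stopping_rule()]; ignored for profiles without optional
#'   stopping.
#' @param tail Publication-bias tail regime, `"one"` or `"two"` (drives the
#'   selection score).
#' @param rho Population correlation of the two outcomes.
#' @return The selected `study_result` with descriptor fields plus
#'   `peek_index` (1 = starting sample) and `n_collected` (participants
#'   gathered, as opposed to analysed), or `NULL` when every analysis at
#'   termination was invalid (the caller regenerates such studies).
#' @export
run_hacked_study <- function(theta_i, profile, stopping, tail = c("one", "two"),
                             rho = 0.8) {
  tail <- match.arg(tail)
  stopifnot(inherits(profile, "researcher_profile"),
            inherits(stopping, "stopping_rule"))
  .run_study_fast(theta_i,
                  profile$uses_optional_dvs,
                  profile$uses_optional_stopping,
                  profile$uses_optional_moderators,
                  profile$uses_optional_outliers,
                  stopping$start_n, stopping$increment, stopping$max_n,
                  one_tailed = tail == "one", rho = rho)
}
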
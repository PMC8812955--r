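# Internal fast path for the participant-level simulation loop.
#
# The exported functions (simulate_participants, enumerate_analyses,
# analyze_two_groups, ...) are the documented surface; the Monte-Carlo engine
# routes each simulated study through the helpers below, which keep the two
# groups as plain vectors and avoid per-analysis object construction. RNG
# draw order (z1, z2, sex) and all floating-point expressions match the
# exported implementations, so a none-profile hacked study is seed-for-seed
# identical to simulate_participants() + analyze_two_groups().

# Single-pass within-group outlier drop; zero variance means no finite z.
.drop_outliers <- function(x, threshold = 2) {
  n <- length(x)
  m <- sum(x) / n
  dev <- x - m
  s2 <- sum(dev^2) / (n - 1)
  if (!is.finite(s2) || s2 <= 0) return(x)
  x[abs(dev) / sqrt(s2) < threshold]
}

# One (possibly p-hacked) study. Returns a study_result or NULL when every
# analysis at termination is invalid. `one_tailed` selects the modified-p
# selection score.
.run_study_fast <- function(theta_i, use_dvs, use_stop, use_mods, use_outs,
                            start_n, increment, max_n, one_tailed,
                            rho = 0.8) {
  sq <- sqrt(1 - rho^2)
  g1_dv1 <- g1_dv2 <- g2_dv1 <- g2_dv2 <- numeric(0)
  g1_F <- g2_F <- logical(0)
  append_block <- function(n_add) {
    z1 <- stats::rnorm(n_add)
    z2 <- stats::rnorm(n_add)
    sF <- stats::runif(n_add) < 0.5
    d1 <- z1
    d2 <- rho * z1 + sq * z2
    h <- n_add %/% 2L
    i1 <- seq_len(h)
    i2 <- (h + 1L):n_add
    g1_dv1 <<- c(g1_dv1, d1[i1])
    g1_dv2 <<- c(g1_dv2, d2[i1])
    g2_dv1 <<- c(g2_dv1, d1[i2] + theta_i)
    g2_dv2 <<- c(g2_dv2, d2[i2] + theta_i)
    g1_F <<- c(g1_F, sF[i1])
    g2_F <<- c(g2_F, sF[i2])
  }
  append_block(start_n)
  ndv <- if (use_dvs) 2L else 1L
  subsets <- if (use_mods) 1L:3L else 1L       # all, F only, M only
  outs <- if (use_outs) c(FALSE, TRUE) else FALSE
  peek <- 1L
  repeat {
    best <- NULL
    best_score <- Inf
    for (dvi in seq_len(ndv)) {
      y1 <- if (dvi == 1L) g1_dv1 else g1_dv2
      y2 <- if (dvi == 1L) g2_dv1 else g2_dv2
      for (ss in subsets) {
        x1 <- switch(ss, y1, y1[g1_F], y1[!g1_F])
        x2 <- switch(ss, y2, y2[g2_F], y2[!g2_F])
        for (out in outs) {
          a1 <- if (out) .drop_outliers(x1) else x1
          a2 <- if (out) .drop_outliers(x2) else x2
          n1 <- length(a1)
          n2 <- length(a2)
          if (n1 < 2L || n2 < 2L) next
          m1 <- sum(a1) / n1
          m2 <- sum(a2) / n2
          ss1 <- sum((a1 - m1)^2)
          ss2 <- sum((a2 - m2)^2)
          df <- n1 + n2 - 2L
          sp2 <- (ss1 + ss2) / df
          if (sp2 <= 0) next
          sp <- sqrt(sp2)
          diff <- m2 - m1
          j <- 1 - 3 / (4 * df - 1)
          gval <- j * (diff / sp)
          ntot <- n1 + n2
          vval <- ntot / (n1 * n2) + gval^2 / (2 * ntot)
          tstat <- diff / (sp * sqrt(1 / n1 + 1 / n2))
          p <- 2 * stats::pt(-abs(tstat), df)
          dir <- sign(diff)
          score <- if (one_tailed && dir < 0) 1 + (1 - p) else p
          if (score < best_score) {  # strict: ties keep enumeration order
            best_score <- score
            best <- list(g = gval, v = vval, p = p, direction = dir,
                         n1 = n1, n2 = n2, valid = TRUE,
                         dv = c("dv1", "dv2")[dvi],
                         subset = c("all", "F", "M")[ss],
                         outliers_removed = out)
          }
        }
      }
    }
    n_now <- length(g1_dv1) + length(g2_dv1)
    if ((!is.null(best) && best_score < 0.05) || !use_stop ||
        n_now >= max_n) {
      if (is.null(best)) return(NULL)
      best$peek_index <- peek
      best$n_collected <- n_now
      best$selection_score <- best_score
      class(best) <- "study_result"
      return(best)
    }
    append_block(min(increment, max_n - n_now))
    peek <- peek + 1L
  }
}
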
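#' Build the factorial simulation grid
#'
#' Fully crosses the six manipulated factors. The default levels are the
#' study conditions: three p-hacking environments, two publication-bias
#' tails, three censoring strengths, five heterogeneity levels, four true
#' effect sizes and four meta-analysis sizes — 1,440 cells in all. Subsets of
#' levels give balanced scaled-down designs; a filter selects cells for
#' partial runs.
#'
#' @param hacking,tail,pb_strength,tau,theta,k Factor levels (subsets of the
#'   canonical levels).
#' @param filter Optional predicate `function(grid) -> logical` used to keep
#'   a subset of cells.
#' @return Data frame with one row per design cell and a `cell` index.
#' @examples
#' nrow(build_grid())  # 1440
#' @export
build_grid <- function(hacking = c("none", "medium", "high"),
                       tail = c("one", "two"),
                       pb_strength = c(0, 0.4, 0.8),
                       tau = c(0, 0.11, 0.22, 0.33, 0.44),
                       theta = c(0, 0.2, 0.5, 0.8),
                       k = c(9, 18, 36, 72),
                       filter = NULL) {
  check_levels <- function(x, allowed, name) {
    if (length(x) == 0 || !all(x %in% allowed)) {
      stop("unknown ", name, " level: ",
           paste(setdiff(x, allowed), collapse = ", "))
    }
  }
  check_levels(hacking, c("none", "medium", "high"), "hacking")
  check_levels(tail, c("one", "two", "none"), "tail")
  check_levels(pb_strength, c(0, 0.4, 0.8), "pb_strength")
  check_levels(tau, c(0, 0.11, 0.22, 0.33, 0.44), "tau")
  check_levels(theta, c(0, 0.2, 0.5, 0.8), "theta")
  check_levels(k, c(9, 18, 36, 72), "k")
  grid <- expand.grid(k = k, theta = theta, tau = tau,
                      pb_strength = pb_strength, tail = tail,
                      hacking = hacking,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("hacking", "tail", "pb_strength", "tau", "theta", "k")]
  if (!is.null(filter)) grid <- grid[filter(grid), , drop = FALSE]
  grid$cell <- seq_len(nrow(grid))
  rownames(grid) <- NULL
  grid
}

# Deterministic per-cell / per-replicate seed streams below 2^31.
derive_seed <- function(root, index) {
  s <- (as.double(root) %% 2147483647 + as.double(index) * 1000003) %% 2147483647
  as.integer(s) + 1L
}

#' Monte-Carlo standard error of a cell summary
#'
#' @param sd Standard deviation of the per-replicate estimates in a cell.
#' @param reps Number of replicates.
#' @return `sd / sqrt(reps)`.
#' @export
mc_error <- function(sd, reps) {
  stopifnot(reps >= 1)
  sd / sqrt(reps)
}

#' Verbal label for unsigned bias in heterogeneity estimates
#'
#' Thresholds 0.05 / 0.10 / 0.20 on the absolute value (the tau metric is in
#' SMD units, so these are anchored to the typical heterogeneity of 0.33
#' observed across psychology meta-analyses).
#'
#' @param value Numeric vector of bias values (sign ignored).
#' @return Factor with levels negligible, small, medium, large.
#' @export
bias_label <- function(value) {
  cut(abs(value), breaks = c(-Inf, 0.05, 0.10, 0.20, Inf),
      labels = c("negligible", "small", "medium", "large"), right = FALSE)
}

#' Run the Monte-Carlo evaluation of one design cell
#'
#' For each replicate a published literature of `k` studies is assembled
#' under the cell's p-hacking environment and publication-bias regime, and
#' all requested heterogeneity estimators are fitted to the same literature
#' (paired comparison). Replicates in which ML or REML fails to converge are
#' regenerated until `reps` complete replicates accumulate. Per-replicate
#' seeds are derived deterministically from `seed`, so any single replicate
#' is reproducible in isolation.
#'
#' @param hacking P-hacking environment label (`"none"`, `"medium"`,
#'   `"high"`).
#' @param tail Publication-bias tail (`"one"`, `"two"`, or `"none"` for the
#'   publish-everything baseline).
#' @param pb_strength Proportion of non-significant studies censored.
#' @param tau,theta True heterogeneity SD and average effect.
#' @param k Studies per meta-analysis.
#' @param reps Number of Monte-Carlo replicates (`>= 2`).
#' @param seed Root seed of the cell.
#' @param size_model Sample-size model for the simulated studies.
#' @param estimators Character vector of estimators to fit.
#' @param rho Population correlation of the two outcomes.
#' @param tau_interval Compute Q-profile coverage for tau (two extra root
#'   searches per fit)?
#' @param alpha Test level for Knapp-Hartung rejection and intervals.
#' @return Data frame with one row per estimator: mean heterogeneity
#'   estimate `T_mean`, `T_bias`, `T_sd`, `T_rmse`, `mc_error`, pooled-effect
#'   summaries `d_mean` and `d_bias`, coverage of theta and tau, the
#'   Knapp-Hartung rejection rate, mean reported study size `n_mean`, mean
#'   generated-study count `n_generated_mean`, and `replicates_replaced`.
#' @export
run_cell <- function(hacking, tail, pb_strength, tau, theta, k,
                     reps, seed, size_model = sample_size_model(),
                     estimators = c("DL", "HS", "ML", "PM", "REML"),
                     rho = 0.8, tau_interval = TRUE, alpha = 0.05) {
  stopifnot(reps >= 2)
  env <- hacking_environment(hacking)
  regime <- if (tail == "none") bias_regime("none") else
    bias_regime(tail, pb_strength)
  ne <- length(estimators)
  T_hat <- d_hat <- matrix(NA_real_, reps, ne, dimnames = list(NULL, estimators))
  cover_theta <- reject <- cover_tau <- matrix(NA, reps, ne)
  n_mean_rep <- n_gen_rep <- numeric(reps)
  replaced <- 0L
  done <- 0L
  attempt <- 0L
  iterative <- intersect(estimators, c("ML", "REML"))
  while (done < reps) {
    attempt <- attempt + 1L
    if (attempt > 10L * reps) {
      stop("replicate replacement did not terminate (", replaced,
           " non-convergent replicates)")
    }
    set.seed(derive_seed(seed, attempt))
    lit <- sample_published_literature(k, theta, tau, env, regime, size_model,
                                       rho)
    fits <- lapply(estimators, function(e) {
      est <- estimate_tau2(lit$g, lit$v, e)
      est
    })
    names(fits) <- estimators
    if (length(iterative) &&
        !all(vapply(fits[iterative], `[[`, logical(1), "converged"))) {
      replaced <- replaced + 1L
      next
    }
    done <- done + 1L
    for (j in seq_len(ne)) {
      tau2 <- fits[[j]]$tau2
      kh <- kh_inference(lit$g, lit$v, tau2, alpha)
      T_hat[done, j] <- sqrt(tau2)
      d_hat[done, j] <- kh$theta_hat
      cover_theta[done, j] <- kh$ci[1] <= theta && theta <= kh$ci[2]
      reject[done, j] <- kh$p < alpha
    }
    if (tau_interval) {
      ci <- tau_ci(lit$g, lit$v)  # estimator-free Q-profile interval
      cover_tau[done, ] <- ci[1] <= tau && tau <= ci[2]
    }
    n_mean_rep[done] <- mean(lit$n)
    n_gen_rep[done] <- lit$n_generated
  }
  T_bias <- colMeans(T_hat) - tau
  T_sd <- apply(T_hat, 2, stats::sd)
  out <- data.frame(
    hacking = hacking, tail = tail, pb_strength = pb_strength,
    tau = tau, theta = theta, k = k,
    estimator = estimators, reps = reps,
    T_mean = colMeans(T_hat),
    T_bias = T_bias,
    T_sd = T_sd,
    T_rmse = sqrt(colMeans((T_hat - tau)^2)),
    mc_error = mc_error(T_sd, reps),
    d_mean = colMeans(d_hat),
    d_bias = colMeans(d_hat) - theta,
    coverage_theta = colMeans(cover_theta),
    coverage_tau = if (tau_interval) colMeans(cover_tau) else NA_real_,
    rejection_rate = colMeans(reject),
    n_mean = mean(n_mean_rep),
    n_generated_mean = mean(n_gen_rep),
    replicates_replaced = replaced,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Run a factorial simulation experiment
#'
#' Loops [run_cell()] over a design grid with per-cell seeds derived from a
#' root seed. When `out_dir` is given, per-cell summaries are written as
#' `cell_<index>.csv` files and existing files are reused, so an interrupted
#' run resumes where it stopped; the combined table is written to
#' `cells.csv` and a short `run.log` records replacement counts.
#'
#' @param grid Design grid from [build_grid()].
#' @param reps Replicates per cell.
#' @param seed Root seed of the experiment.
#' @param size_model Sample-size model.
#' @param estimators Estimators to fit in every cell.
#' @param out_dir Optional output directory.
#' @param tau_interval Compute tau-interval coverage per replicate?
#' @param verbose Print one line per completed cell?
#' @return Combined cell-summary data frame (one row per cell x estimator).
#' @export
run_experiment <- function(grid, reps, seed,
                           size_model = sample_size_model(),
                           estimators = c("DL", "HS", "ML", "PM", "REML"),
                           out_dir = NULL, tau_interval = TRUE,
                           verbose = FALSE) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  cell_dir <- NULL
  if (!is.null(out_dir)) {
    cell_dir <- file.path(out_dir, "cells")
    dir.create(cell_dir, recursive = TRUE, showWarnings = FALSE)
  }
  summaries <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    path <- if (!is.null(cell_dir)) {
      file.path(cell_dir, sprintf("cell_%05d.csv", cell$cell))
    }
    if (!is.null(path) && file.exists(path)) {
      summaries[[i]] <- utils::read.csv(path, stringsAsFactors = FALSE)
    } else {
      s <- run_cell(cell$hacking, cell$tail, cell$pb_strength, cell$tau,
                    cell$theta, cell$k, reps = reps,
                    seed = derive_seed(seed, cell$cell),
                    size_model = size_model, estimators = estimators,
                    tau_interval = tau_interval)
      s$cell <- cell$cell
      if (!is.null(path)) utils::write.csv(s, path, row.names = FALSE)
      summaries[[i]] <- s
    }
    if (verbose) {
      message(sprintf("cell %d/%d done", i, nrow(grid)))
    }
  }
  cells <- do.call(rbind, summaries)
  if (!is.null(out_dir)) {
    utils::write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
    writeLines(c(
      sprintf("cells: %d  reps: %d  seed: %d", nrow(grid), reps, seed),
      sprintf("replicates replaced (ML/REML non-convergence): %d",
              sum(cells$replicates_replaced[!duplicated(cells$cell)])),
      sprintf("mean studies generated per meta-analysis: %.1f",
              mean(cells$n_generated_mean))
    ), file.path(out_dir, "run.log"))
  }
  cells
}
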
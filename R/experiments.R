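#' Simulation experiment design
#'
#' Describes one simulation experiment. The `agreement` regime mirrors the
#' estimator-agreement study: every replicate draws fresh binormal parameters
#' and fresh bounds, simulates one dataset and evaluates the trimmed
#' Mann-Whitney and the fast trapezoid estimators on it. The `bias` regime
#' mirrors the bias study: each run draws binormal parameters and, for every
#' cell of a fixed sensitivity/specificity grid, computes the exact tpAUC by
#' quadrature, simulates `datasets_per_run` datasets, and records the mean
#' estimate minus the truth per estimator.
#'
#' @param n_x,n_y class sizes per simulated dataset.
#' @param replications number of replicates (agreement) or runs (bias).
#' @param regime `"agreement"` or `"bias"`.
#' @param threshold_grid data frame with columns `b_se`, `b_sp` (bias regime);
#'   defaults to the 16-cell grid \{0.2, 0.4, 0.6, 0.8\}^2.
#' @param datasets_per_run number of datasets per (run, grid cell) in the bias
#'   regime (the K of the bias average); default 200.
#' @param seed integer seed; all experiment output is a deterministic function
#'   of the design including this seed.
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design(50, 50, replications = 10, regime = "agreement", seed = 1)
#' @export
experiment_design <- function(n_x, n_y, replications,
                              regime = c("agreement", "bias"),
                              threshold_grid = NULL,
                              datasets_per_run = 200, seed = 1) {
  regime <- match.arg(regime)
  if (n_x < 1 || n_y < 1) stop("class sizes must be positive", call. = FALSE)
  if (replications < 1) stop("need at least one replication", call. = FALSE)
  if (is.null(threshold_grid)) {
    threshold_grid <- expand.grid(b_se = c(0.2, 0.4, 0.6, 0.8),
                                  b_sp = c(0.2, 0.4, 0.6, 0.8),
                                  KEEP.OUT.ATTRS = FALSE)
  }
  if (!all(c("b_se", "b_sp") %in% names(threshold_grid)) ||
      any(threshold_grid$b_se <= 0 | threshold_grid$b_se >= 1) ||
      any(threshold_grid$b_sp <= 0 | threshold_grid$b_sp >= 1)) {
    stop("threshold_grid needs b_se, b_sp columns with values in (0, 1)",
         call. = FALSE)
  }
  if (regime == "bias" && datasets_per_run < 1) {
    stop("datasets_per_run must be positive", call. = FALSE)
  }
  structure(
    list(n_x = as.integer(n_x), n_y = as.integer(n_y),
         replications = as.integer(replications), regime = regime,
         threshold_grid = threshold_grid,
         datasets_per_run = as.integer(datasets_per_run),
         seed = as.integer(seed)),
    class = "experiment_design"
  )
}

#' Draw binormal parameters (and bounds) for a simulation regime
#'
#' The agreement regime samples `mu_y ~ U(0, 2)`, `mu_x = mu_y + U(0.1, 1.1)`
#' (so the positive class always scores higher on average),
#' `sigma_x, sigma_y ~ U(0.5, 1.5)`, and bounds `b_se, b_sp ~ U(0.2, 0.8)`.
#' The bias regime samples `mu_x ~ U(2, 3)`, `sigma_x ~ U(1, 2)`,
#' `mu_y ~ U(0, 1)`, `sigma_y ~ U(1, 2)` and returns no bounds (the bias study
#' evaluates a fixed threshold grid instead).
#'
#' @param regime `"agreement"` or `"bias"`.
#' @param rng_seed optional integer seed; `NULL` draws from the current RNG
#'   stream (as the experiment drivers do).
#' @return A list with `params` (a [binormal_params()]) and `bounds` (a
#'   [tpauc_bounds()] or `NULL`).
#' @examples
#' sample_design_parameters("agreement", rng_seed = 1)
#' @export
sample_design_parameters <- function(regime = c("agreement", "bias"),
                                     rng_seed = NULL) {
  regime <- match.arg(regime)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (regime == "agreement") {
    mu_y <- stats::runif(1, 0, 2)
    mu_x <- mu_y + stats::runif(1, 0.1, 1.1)
    sigma_y <- stats::runif(1, 0.5, 1.5)
    sigma_x <- stats::runif(1, 0.5, 1.5)
    bounds <- tpauc_bounds(stats::runif(1, 0.2, 0.8),
                           stats::runif(1, 0.2, 0.8))
  } else {
    mu_x <- stats::runif(1, 2, 3)
    sigma_x <- stats::runif(1, 1, 2)
    mu_y <- stats::runif(1, 0, 1)
    sigma_y <- stats::runif(1, 1, 2)
    bounds <- NULL
  }
  list(params = binormal_params(mu_x, sigma_x, mu_y, sigma_y),
       bounds = bounds)
}

#' Run an estimator-agreement experiment
#'
#' For each replicate: draw fresh binormal parameters and bounds
#' ([sample_design_parameters()], agreement regime), simulate one dataset of
#' `(n_x, n_y)` scores, and evaluate both the trimmed Mann-Whitney estimator
#' and the fast trapezoid estimator on it. The scatter of `tpauc_o` against
#' `tpauc_p` across replicates shows how the two estimators converge as the
#' sample size grows.
#'
#' @param design an [experiment_design()] with `regime = "agreement"`.
#' @return A data frame with one row per replicate: `replicate`, the drawn
#'   `mu_x`, `sigma_x`, `mu_y`, `sigma_y`, `b_se`, `b_sp`, and the estimates
#'   `tpauc_o` (trimmed Mann-Whitney) and `tpauc_p` (trapezoid-based).
#' @examples
#' d <- experiment_design(50, 50, replications = 5, regime = "agreement", seed = 1)
#' run_agreement_experiment(d)
#' @export
run_agreement_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (design$regime != "agreement") {
    stop("design regime must be 'agreement'", call. = FALSE)
  }
  set.seed(design$seed)
  reps <- design$replications
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    drawn <- sample_design_parameters("agreement")
    p <- drawn$params
    b <- drawn$bounds
    s <- sample_binormal(p, design$n_x, design$n_y)
    out[[r]] <- data.frame(
      replicate = r,
      mu_x = p$mu_x, sigma_x = p$sigma_x, mu_y = p$mu_y, sigma_y = p$sigma_y,
      b_se = b$b_se, b_sp = b$b_sp,
      tpauc_o = tpauc_trimmed_mw(s, b),
      tpauc_p = tpauc_value(s$x_scores, s$y_scores, b$b_se, b$b_sp)
    )
  }
  do.call(rbind, out)
}

#' Run an estimator-bias experiment
#'
#' For each run: draw binormal parameters (bias regime); for every cell of the
#' threshold grid compute the exact tpAUC by quadrature, simulate
#' `datasets_per_run` datasets, estimate the tpAUC on each with both the
#' trimmed Mann-Whitney and the trapezoid estimator, and record the mean
#' estimate minus the truth (the Monte-Carlo bias) per estimator.
#'
#' @param design an [experiment_design()] with `regime = "bias"`.
#' @return A data frame of class `bias_result`, one row per (run, grid cell):
#'   `run`, `b_se`, `b_sp`, `true_tpauc`, `mean_estimate_o`,
#'   `mean_estimate_p`, `bias_o`, `bias_p`.
#' @examples
#' d <- experiment_design(50, 50, replications = 2, regime = "bias",
#'                        datasets_per_run = 20, seed = 1)
#' head(run_bias_experiment(d))
#' @export
run_bias_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (design$regime != "bias") {
    stop("design regime must be 'bias'", call. = FALSE)
  }
  set.seed(design$seed)
  grid <- design$threshold_grid
  n_cell <- nrow(grid)
  K <- design$datasets_per_run
  out <- vector("list", design$replications * n_cell)
  row <- 0L
  for (r in seq_len(design$replications)) {
    p <- sample_design_parameters("bias")$params
    for (g in seq_len(n_cell)) {
      b_se <- grid$b_se[g]
      b_sp <- grid$b_sp[g]
      truth <- true_tpauc(p, tpauc_bounds(b_se, b_sp))
      est_o <- numeric(K)
      est_p <- numeric(K)
      for (k in seq_len(K)) {
        x <- stats::rnorm(design$n_x, p$mu_x, p$sigma_x)
        y <- stats::rnorm(design$n_y, p$mu_y, p$sigma_y)
        est_o[k] <- trimmed_mw_value(x, y, b_se, b_sp)
        est_p[k] <- tpauc_value(x, y, b_se, b_sp)
      }
      row <- row + 1L
      out[[row]] <- data.frame(
        run = r, b_se = b_se, b_sp = b_sp, true_tpauc = truth,
        mean_estimate_o = mean(est_o), mean_estimate_p = mean(est_p),
        bias_o = mean(est_o) - truth, bias_p = mean(est_p) - truth
      )
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("bias_result", "data.frame")
  res
}

# lean trimmed-MW path for the simulation loops
trimmed_mw_value <- function(x, y, b_se, b_sp) {
  x_cut <- empirical_inverse_survival(x, b_se)
  y_cut <- empirical_inverse_survival(y, 1 - b_sp)
  count_concordant(x[x <= x_cut], y[y >= y_cut]) / (length(x) * length(y))
}

#' Summarise a bias experiment per grid cell
#'
#' Mean absolute Monte-Carlo bias of each estimator per threshold-grid cell,
#' aggregated over runs.
#'
#' @param result a [run_bias_experiment()] result.
#' @return Data frame with one row per grid cell: `b_se`, `b_sp`,
#'   `mean_abs_bias_o`, `mean_abs_bias_p`.
#' @export
summarise_bias <- function(result) {
  stopifnot(inherits(result, "bias_result"))
  agg <- stats::aggregate(cbind(abs_o = abs(result$bias_o),
                                abs_p = abs(result$bias_p)),
                          by = list(b_se = result$b_se, b_sp = result$b_sp),
                          FUN = mean)
  names(agg)[names(agg) == "abs_o"] <- "mean_abs_bias_o"
  names(agg)[names(agg) == "abs_p"] <- "mean_abs_bias_p"
  agg
}
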
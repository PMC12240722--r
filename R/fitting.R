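# Grid-search fitting of (beta_conf, cost) on normalized summary statistics:
# choice accuracy (theoretical maximum 1) and median RT (maximum 5 s).

#' Squared-error loss on normalized summary statistics
#'
#' Accuracy and median RT are put on a common scale by dividing by their
#' theoretical maxima (1 for accuracy, 5000 ms for RT); the loss is the sum
#' of squared differences between model and target.
#'
#' @param model_stats,target_stats Lists with `accuracy` and `median_rt_ms`.
#' @return Non-negative scalar loss.
#' @export
fit_loss <- function(model_stats, target_stats) {
  (model_stats$accuracy - target_stats$accuracy)^2 +
    ((model_stats$median_rt_ms - target_stats$median_rt_ms) / 5000)^2
}

#' Logarithmically spaced parameter grid
#'
#' @param n_per_dim Grid resolution per parameter (default 30).
#' @param low,high Inclusive endpoints of the (log-spaced) range, default
#'   `(0.001, 0.1)` for both `beta_conf` and `cost`.
#' @return Data frame with columns `beta_conf` and `cost`, one row per cell
#'   (full Cartesian product, `n_per_dim^2` rows).
#' @export
make_grid <- function(n_per_dim = 30, low = 0.001, high = 0.1) {
  stopifnot(n_per_dim >= 1, low > 0, low < high)
  v <- exp(seq(log(low), log(high), length.out = n_per_dim))
  v[1] <- low
  v[n_per_dim] <- high  # endpoints exact despite exp/log round-trip
  expand.grid(beta_conf = v, cost = v, KEEP.OUT.ATTRS = FALSE)
}

#' Grid search over (beta_conf, cost)
#'
#' Simulates the experiment at every grid cell with shared random substreams
#' (the same per-trial, per-repetition seeds in every cell, which removes
#' simulation noise from between-cell comparisons) and returns the cell
#' minimizing [fit_loss()] against the target statistics. Ties are broken
#' by grid order. Cells in which all trials abort get infinite loss; if
#' every cell does, the fit fails.
#'
#' @param specs List of [trial_spec()] objects.
#' @param prior A [fit_prior()] object.
#' @param target_stats List with `accuracy` and `median_rt_ms` (the
#'   statistics to match).
#' @param params_template [model_params()] supplying all non-fitted fields.
#' @param grid Data frame from [make_grid()].
#' @param n_reps Repetitions per trial per cell.
#' @param seed Root seed shared across cells.
#' @return An object of class `fit_result` with the `grid`, per-cell
#'   `losses`, `best` (row of the best cell), `best_params`,
#'   `target_stats` and `achieved_stats`.
#' @export
grid_search <- function(specs, prior, target_stats, params_template = model_params(),
                        grid = make_grid(), n_reps = 30, seed = 1L) {
  stopifnot(nrow(grid) >= 1)
  losses <- numeric(nrow(grid))
  stats <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- params_template
    p$beta_conf <- grid$beta_conf[g]
    p$cost <- grid$cost[g]
    tab <- simulate_experiment(specs, prior, p, n_reps = n_reps, seed = seed)
    st <- tryCatch(summary_stats(tab), error = function(e) NULL)
    stats[[g]] <- st
    losses[g] <- if (is.null(st)) Inf else fit_loss(st, target_stats)
  }
  if (all(!is.finite(losses)))
    stop("fit failure: every grid cell produced insufficient data")
  best <- which.min(losses)  # first minimum in grid order
  structure(list(
    grid = grid, losses = losses, best_index = best,
    best = grid[best, , drop = FALSE],
    best_params = list(beta_conf = grid$beta_conf[best], cost = grid$cost[best]),
    target_stats = target_stats,
    achieved_stats = stats[[best]]
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Grid search over %d cells\n", nrow(x$grid)))
  cat(sprintf("  best: beta_conf = %.5g, cost = %.5g (loss %.5g)\n",
              x$best_params$beta_conf, x$best_params$cost,
              x$losses[x$best_index]))
  cat(sprintf("  target   accuracy %.3f, median RT %.0f ms\n",
              x$target_stats$accuracy, x$target_stats$median_rt_ms))
  cat(sprintf("  achieved accuracy %.3f, median RT %.0f ms\n",
              x$achieved_stats$accuracy, x$achieved_stats$median_rt_ms))
  invisible(x)
}
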
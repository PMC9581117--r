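#' Hyperparameter configuration for transfer gradient boosting
#'
#' Collects every tunable of the TrGB engine and of the plain-GBM baselines
#' that share it. Defaults are conventional gradient-boosting practice for
#' small clinical feature tables.
#'
#' @param n_iterations number of boosting iterations `T`.
#' @param max_tree_depth maximum depth of each regression-tree base learner
#'   (root = depth 0).
#' @param min_leaf_count minimum number of training instances per leaf.
#' @param learning_rate shrinkage factor in (0, 1] applied to every
#'   iteration's leaf steps.
#' @param residual_clamp_eps epsilon in (0, 0.5) used to clamp the average
#'   target residual before the learner-strength log-odds transform, so a
#'   perfect (or hopeless) learner yields a large finite strength instead of
#'   an infinity.
#' @param lambda_clamp_nonnegative if `TRUE`, a negative learner strength is
#'   floored at 0, disabling transfer weight updates from weak learners. The
#'   default `FALSE` follows the literal weighting formula.
#' @param weight_mode `"cumulative"` multiplies each iteration's weight
#'   factors into the running weights (renormalized to mean 1), so the
#'   influence of repeatedly misclassified source instances fades
#'   geometrically; `"per_iteration"` recomputes weights from the current
#'   residuals alone.
#' @param weight_floor lower clip for instance weights (keeps numerically
#'   dead instances from degenerating the tree fit).
#' @param weight_ceiling upper clip for instance weights, or `NULL` for none.
#' @param loss_tolerance early-stopping threshold: boosting stops once the
#'   weighted normalized training deviance falls below this value. The
#'   default 0 runs all `n_iterations`.
#' @param seed integer seed controlling every stochastic element of a fit
#'   (the default trees are deterministic, so fits are exactly reproducible).
#'
#' @return an object of class `trgb_config`.
#' @export
#' @examples
#' cfg <- trgb_config(n_iterations = 50, learning_rate = 0.2)
#' cfg$n_iterations
trgb_config <- function(n_iterations = 100L,
                        max_tree_depth = 3L,
                        min_leaf_count = 5L,
                        learning_rate = 0.1,
                        residual_clamp_eps = 1e-4,
                        lambda_clamp_nonnegative = FALSE,
                        weight_mode = c("cumulative", "per_iteration"),
                        weight_floor = 1e-8,
                        weight_ceiling = NULL,
                        loss_tolerance = 0,
                        seed = 1L) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(
    "n_iterations must be a positive integer" =
      is.numeric(n_iterations) && length(n_iterations) == 1 && n_iterations >= 1,
    "max_tree_depth must be a positive integer" =
      is.numeric(max_tree_depth) && max_tree_depth >= 1,
    "min_leaf_count must be a positive integer" =
      is.numeric(min_leaf_count) && min_leaf_count >= 1,
    "learning_rate must be in (0, 1]" =
      is.numeric(learning_rate) && learning_rate > 0 && learning_rate <= 1,
    "residual_clamp_eps must be in (0, 0.5)" =
      is.numeric(residual_clamp_eps) && residual_clamp_eps > 0 &&
        residual_clamp_eps < 0.5,
    "weight_floor must be non-negative" =
      is.numeric(weight_floor) && weight_floor >= 0,
    "loss_tolerance must be non-negative" =
      is.numeric(loss_tolerance) && loss_tolerance >= 0,
    "seed must be a single integer" = is.numeric(seed) && length(seed) == 1
  )
  if (!is.null(weight_ceiling)) {
    stopifnot(
      "weight_ceiling must be positive" =
        is.numeric(weight_ceiling) && weight_ceiling > 0,
      "weight_floor must be below weight_ceiling" =
        weight_floor < weight_ceiling
    )
  }
  structure(
    list(
      n_iterations = as.integer(n_iterations),
      max_tree_depth = as.integer(max_tree_depth),
      min_leaf_count = as.integer(min_leaf_count),
      learning_rate = learning_rate,
      residual_clamp_eps = residual_clamp_eps,
      lambda_clamp_nonnegative = isTRUE(lambda_clamp_nonnegative),
      weight_mode = weight_mode,
      weight_floor = weight_floor,
      weight_ceiling = weight_ceiling,
      loss_tolerance = loss_tolerance,
      seed = as.integer(seed)
    ),
    class = "trgb_config"
  )
}

#' @export
print.trgb_config <- function(x, ...) {
  cat("TrGB configuration\n")
  cat(sprintf("  iterations: %d, tree depth: %d, min leaf: %d, learning rate: %g\n",
              x$n_iterations, x$max_tree_depth, x$min_leaf_count, x$learning_rate))
  cat(sprintf("  weight mode: %s, lambda floor at 0: %s, residual clamp eps: %g\n",
              x$weight_mode, x$lambda_clamp_nonnegative, x$residual_clamp_eps))
  cat(sprintf("  weight clip: [%g, %s], loss tolerance: %g, seed: %d\n",
              x$weight_floor,
              if (is.null(x$weight_ceiling)) "none" else format(x$weight_ceiling),
              x$loss_tolerance, x$seed))
  invisible(x)
}
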
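# Residual-driven instance weighting: the transfer-specific part of TrGB.
#
# The strength of the current learner is judged on the target domain only,
# as the half log-odds of the mean absolute target residual; the weight of
# every training instance is then an exponential in its own residual and
# that strength, with opposite signs for source and target instances.

#' Learner strength from target-domain residuals
#'
#' Maps the mean absolute residual of the target instances, `r_avg`, to the
#' strength `lambda = 0.5 * log((1 - r_avg) / r_avg)`. A learner that is
#' right on average (`r_avg < 0.5`) has positive strength; one that is worse
#' than chance has negative strength. Source residuals are never included:
#' strength measures usefulness *for the target domain*.
#'
#' `r_avg` is clamped into `[clamp_eps, 1 - clamp_eps]` first, so a perfect
#' learner yields the maximal finite strength rather than an infinity.
#'
#' @param target_residual_magnitudes numeric vector of absolute residuals
#'   `|y - p|` of the target instances, each in `[0, 1]`.
#' @param clamp_eps clamping epsilon in (0, 0.5).
#' @param nonnegative if `TRUE`, floor a negative strength at 0 (disables
#'   transfer updates from weak learners).
#' @return a single numeric strength value.
#' @export
#' @examples
#' learner_strength(c(0.1, 0.1))        # 0.5 * log(9)
#' learner_strength(0.5)                # 0: a chance-level learner
learner_strength <- function(target_residual_magnitudes,
                             clamp_eps = 1e-4,
                             nonnegative = FALSE) {
  if (length(target_residual_magnitudes) == 0)
    stop("learner strength is undefined without target-domain residuals")
  if (any(!is.finite(target_residual_magnitudes)))
    stop("target residual magnitudes must be finite")
  if (any(target_residual_magnitudes < 0 | target_residual_magnitudes > 1))
    stop("target residual magnitudes must lie in [0, 1]")
  stopifnot(clamp_eps > 0, clamp_eps < 0.5)
  r_avg <- mean(target_residual_magnitudes)
  r_avg <- min(max(r_avg, clamp_eps), 1 - clamp_eps)
  lam <- 0.5 * log((1 - r_avg) / r_avg)
  if (nonnegative) lam <- max(lam, 0)
  lam
}

#' Asymmetric instance weight from residual and learner strength
#'
#' One training instance's boosting weight factor. When `(1/2 - r) * lambda`
#' is positive — a strong learner that classifies the instance well, or a
#' weak learner that misclassifies it — the weight is left at 1. Otherwise
#' the weight is exponential in the residual: `exp(-2 * (r - 1/2) * lambda)`
#' for source instances and `exp(+2 * (r - 1/2) * lambda)` for target
#' instances. Under a strong learner (`lambda > 0`) a misclassified source
#' instance (residual above 1/2) is therefore down-weighted — it likely follows a
#' distribution unlike the target — while a misclassified target instance
#' is up-weighted so the next learner concentrates on it.
#'
#' Vectorized over `residual_magnitude` (and `domain`, recycled as usual).
#'
#' @param residual_magnitude absolute residual(s) `|y - p|` in `[0, 1]`.
#' @param lambda_value learner strength.
#' @param domain `"source"` or `"target"` (vector or scalar).
#' @return positive weight factor(s), same length as `residual_magnitude`.
#' @export
#' @examples
#' instance_weight(0.9, 1, "source")  # exp(-0.8): down-weighted
#' instance_weight(0.9, 1, "target")  # exp(+0.8): up-weighted
#' instance_weight(0.2, 1, "source")  # 1: well-classified, untouched
instance_weight <- function(residual_magnitude, lambda_value, domain) {
  if (any(!is.finite(residual_magnitude)) || !is.finite(lambda_value))
    stop("instance_weight inputs must be finite")
  domain <- match_domain(domain, length(residual_magnitude))
  guard <- (0.5 - residual_magnitude) * lambda_value
  sign_dom <- ifelse(domain == "source", -1, 1)
  w <- ifelse(guard >= 0, 1,
              exp(sign_dom * 2 * (residual_magnitude - 0.5) * lambda_value))
  as.numeric(w)
}

match_domain <- function(domain, n) {
  domain <- as.character(domain)
  if (!all(domain %in% c("source", "target")))
    stop("domain must be 'source' or 'target'")
  if (length(domain) == 1) domain <- rep(domain, n)
  if (length(domain) != n)
    stop("domain has length ", length(domain), ", expected ", n)
  domain
}

#' Weight-update step for one boosting iteration
#'
#' Computes the per-instance weight factors for the current iteration and
#' applies them to the running weights. In `"cumulative"` mode (the default
#' engine setting) the factors multiply the existing weights and the result
#' is renormalized to mean 1 over all instances, so the influence of an
#' instance that keeps being down-weighted fades geometrically across
#' iterations. In `"per_iteration"` mode the factors replace the running
#' weights: each iteration's weights depend on that iteration's residuals
#' alone.
#'
#' @param current_weights positive numeric vector of running weights.
#' @param update numeric vector of weight factors, as produced by
#'   [instance_weight()] (same length).
#' @param mode `"cumulative"` or `"per_iteration"`.
#' @param renormalize in cumulative mode, rescale the result to mean 1.
#' @param floor,ceiling optional clipping bounds applied after the update.
#' @return positive numeric vector of updated weights.
#' @export
apply_weight_update <- function(current_weights, update,
                                mode = c("cumulative", "per_iteration"),
                                renormalize = TRUE,
                                floor = 0, ceiling = NULL) {
  mode <- match.arg(mode)
  if (length(current_weights) != length(update))
    stop("current_weights and update differ in length (",
         length(current_weights), " vs ", length(update), ")")
  w <- switch(mode,
              cumulative = current_weights * update,
              per_iteration = update)
  if (mode == "cumulative" && renormalize && length(w) > 0) w <- w / mean(w)
  if (floor > 0) w <- pmax(w, floor)
  if (!is.null(ceiling)) w <- pmin(w, ceiling)
  w
}
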
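# The TrGB boosting engine: gradient boosting with log-likelihood loss in
# which source-domain instances are re-weighted every iteration by an
# exponential in their residual and the current learner's strength on the
# target domain. With an empty source set the weighting is inactive and the
# engine is a plain gradient boosting machine.

#' Initial log-odds score for boosting
#'
#' The constant score minimizing the negative log-likelihood over the
#' training labels: `log(pbar / (1 - pbar))` with `pbar` the mean of the
#' 0/1 labels.
#'
#' @param labels numeric vector of 0/1 labels over all training instances.
#' @return the initial log-odds score.
#' @export
#' @examples
#' initialize_score(c(0, 1, 0, 1))   # 0
#' initialize_score(c(1, 1, 1, 0))   # log(3)
initialize_score <- function(labels) {
  if (length(labels) == 0) stop("cannot initialize from an empty label vector")
  if (!all(labels %in% c(0, 1))) stop("labels must be coded 0/1")
  pbar <- mean(labels)
  if (pbar == 0 || pbar == 1)
    stop("all training labels belong to one class; the initial log-odds ",
         "score would be infinite")
  log(pbar / (1 - pbar))
}

#' Pseudo-residuals for the log-likelihood loss
#'
#' The negative gradient of the loss with respect to the log-odds score:
#' `y - p` per instance.
#'
#' @param labels numeric 0/1 vector.
#' @param probabilities predicted probabilities in (0, 1), same length.
#' @return signed residual vector; magnitudes never exceed 1.
#' @export
pseudo_residuals <- function(labels, probabilities) {
  if (length(labels) != length(probabilities))
    stop("labels and probabilities differ in length (",
         length(labels), " vs ", length(probabilities), ")")
  labels - probabilities
}

#' Fit a transfer gradient boosting classifier
#'
#' Trains a binary TrGB model from a (possibly empty) labeled source-domain
#' table and a labeled target-domain table. Each boosting iteration computes
#' pseudo-residuals for all instances under the current model, judges the
#' model's strength on the target instances alone ([learner_strength()]),
#' re-weights every instance ([instance_weight()]), fits a depth-limited
#' regression tree to the pseudo-residuals under those weights, and takes a
#' Newton step per leaf. Source instances that the model keeps getting wrong
#' — the part of the source data whose distribution differs from the target
#' — lose weight and fade from the fit.
#'
#' @param source data.frame of source-domain instances (features + label
#'   column), or `NULL` for none. With no source instances all weights stay
#'   at 1 and the fit is a plain gradient boosting machine.
#' @param target data.frame of labeled target-domain instances.
#' @param config a [trgb_config()].
#' @param label name of the label column in both tables.
#' @param keep_history keep per-iteration residual and weight vectors in the
#'   model (useful for diagnostics; dropped from serialization).
#' @return an object of class `trgb`: initial score, per-iteration states
#'   (node tables, learner strengths, weight summaries, training loss),
#'   label codec and config.
#' @seealso [predict.trgb()], [write_trgb()], [fit_baseline()]
#' @export
#' @examples
#' pair <- generate_domain_pair(transfer_scenario(seed = 1))
#' fit <- trgb(pair$source, pair$target_labeled,
#'             config = trgb_config(n_iterations = 20))
#' head(predict(fit, pair$target_test, type = "prob"))
trgb <- function(source, target, config = trgb_config(), label = "label",
                 keep_history = TRUE) {
  tgt <- prepare_samples(target, label, what = "target")
  if (nrow(tgt$x) == 0) stop("target domain is empty; TrGB requires labeled target instances")
  levels_ <- tgt$levels
  if (length(levels_) < 2)
    stop("target domain contains a single class ('", levels_,
         "'); learner strength is undefined")
  if (length(levels_) > 2)
    stop("more than two classes in the target domain; use trgb_multiclass()")
  src <- prepare_samples(source, label, what = "source", levels = levels_)
  if (!is.null(src) && !identical(colnames(src$x), colnames(tgt$x)))
    stop("source and target feature columns differ")

  m <- if (is.null(src)) 0L else nrow(src$x)
  x <- if (m > 0) rbind(src$x, tgt$x) else tgt$x
  y <- c(if (m > 0) src$y, tgt$y)
  n <- nrow(x)
  domain <- c(rep("source", m), rep("target", n - m))
  target_idx <- which(domain == "target")

  f0 <- initialize_score(y)
  f_cur <- rep(f0, n)
  w <- rep(1, n)
  iters <- vector("list", config$n_iterations)
  n_used <- 0L

  for (t in seq_len(config$n_iterations)) {
    p <- clamp_prob(sigmoid(f_cur))
    r_signed <- pseudo_residuals(y, p)
    r_mag <- abs(r_signed)
    lam <- learner_strength(r_mag[target_idx],
                            clamp_eps = config$residual_clamp_eps,
                            nonnegative = config$lambda_clamp_nonnegative)
    if (m > 0) {
      factors <- instance_weight(r_mag, lam, domain)
      w <- apply_weight_update(w, factors, mode = config$weight_mode,
                               renormalize = TRUE,
                               floor = config$weight_floor,
                               ceiling = config$weight_ceiling)
    }
    tree_fit <- fit_residual_tree(x, r_signed, w, config)
    leaf_ids <- train_leaf_ids(tree_fit)
    steps <- newton_leaf_steps(leaf_ids, r_signed, p * (1 - p), w)
    nodes <- tree_nodes(tree_fit, leaf_values = steps)
    f_cur <- f_cur + config$learning_rate * as.numeric(steps[as.character(leaf_ids)])
    loss <- mean_deviance(y, sigmoid(f_cur), w)
    st <- list(
      lambda = lam,
      target_avg_residual = mean(r_mag[target_idx]),
      train_loss = loss,
      nodes = nodes,
      weight_summary = weight_summary(w, domain)
    )
    if (keep_history) {
      st$pseudo_residuals <- r_signed
      st$residual_magnitudes <- r_mag
      st$weights <- w
    }
    iters[[t]] <- st
    n_used <- t
    if (loss < config$loss_tolerance) break
  }

  structure(
    list(
      init_score = f0,
      iterations = iters[seq_len(n_used)],
      label_levels = levels_,
      feature_names = colnames(x),
      config = config,
      n_source = m,
      n_target = n - m
    ),
    class = "trgb"
  )
}

# per-domain min/median/max weight record for the training log
weight_summary <- function(w, domain) {
  out <- lapply(split(w, domain), function(v)
    c(min = min(v), median = stats::median(v), max = max(v)))
  out
}

# coerce a data.frame (or NULL) into a feature matrix + 0/1 label codes
prepare_samples <- function(data, label, what, levels = NULL) {
  if (is.null(data) || NROW(data) == 0) {
    if (what == "target" && is.null(data))
      stop("target data must be supplied")
    return(if (what == "source") NULL
           else list(x = matrix(numeric(0), 0, 0), y = numeric(0), levels = character(0)))
  }
  data <- as.data.frame(data)
  if (!label %in% colnames(data))
    stop("no '", label, "' column in the ", what, " table")
  lab <- data[[label]]
  feat_cols <- setdiff(colnames(data), c(label, "domain"))
  xm <- as.matrix(data[feat_cols])
  if (!is.numeric(xm)) stop("non-numeric feature columns in the ", what, " table")
  if (any(!is.finite(xm)))
    stop("non-finite feature values in the ", what, " table")
  if (is.null(levels)) {
    levels <- if (is.factor(lab)) levels(droplevels(lab)) else sort(unique(as.character(lab)))
    y <- as.numeric(factor(as.character(lab), levels = levels)) - 1
  } else {
    lab <- as.character(lab)
    bad <- setdiff(unique(lab), levels)
    if (length(bad) > 0)
      stop(what, " labels outside the target label space: ",
           paste(bad, collapse = ", "),
           " (map the label space first, see map_label_space())")
    y <- as.numeric(factor(lab, levels = levels)) - 1
  }
  list(x = xm, y = y, levels = levels)
}

# feature matrix from new data, checked against the training schema
newdata_matrix <- function(object, newdata) {
  if (is.data.frame(newdata)) {
    missing_cols <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing_cols) > 0)
      stop("newdata lacks feature columns: ", paste(missing_cols, collapse = ", "))
    xm <- as.matrix(as.data.frame(newdata)[object$feature_names])
  } else {
    xm <- as.matrix(newdata)
    if (ncol(xm) != length(object$feature_names))
      stop("newdata has ", ncol(xm), " columns; the model was trained on ",
           length(object$feature_names), " features")
    colnames(xm) <- object$feature_names
  }
  if (!is.numeric(xm) || any(!is.finite(xm)))
    stop("newdata features must be numeric and finite")
  xm
}

# additive log-odds scores after the first k iterations
trgb_scores <- function(object, x, n_iterations = NULL) {
  k <- n_iterations %||% length(object$iterations)
  if (k > length(object$iterations))
    stop("model has only ", length(object$iterations), " iterations")
  s <- rep(object$init_score, nrow(x))
  for (t in seq_len(k)) {
    s <- s + object$config$learning_rate *
      predict_tree_nodes(object$iterations[[t]]$nodes, x)
  }
  s
}

#' Predict from a TrGB model
#'
#' @param object a fitted [trgb()] model.
#' @param newdata data.frame or numeric matrix of features.
#' @param type `"prob"` for a two-column probability matrix (columns named
#'   by class, rows summing to 1), `"class"` for predicted labels, `"link"`
#'   for raw additive log-odds scores.
#' @param n_iterations score with only the first `n_iterations` trees
#'   (default: all). With 0, every input receives the initial score.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.trgb <- function(object, newdata,
                         type = c("prob", "class", "link"),
                         n_iterations = NULL, ...) {
  type <- match.arg(type)
  x <- newdata_matrix(object, newdata)
  s <- trgb_scores(object, x, n_iterations)
  if (type == "link") return(s)
  p1 <- clamp_prob(sigmoid(s))
  if (type == "class")
    return(factor(object$label_levels[(p1 >= 0.5) + 1L],
                  levels = object$label_levels))
  pm <- cbind(1 - p1, p1)
  colnames(pm) <- object$label_levels
  pm
}

#' @export
print.trgb <- function(x, ...) {
  cat("TrGB transfer gradient boosting model\n")
  cat(sprintf("  classes: %s (positive: %s)\n",
              paste(x$label_levels, collapse = " vs "), x$label_levels[2]))
  cat(sprintf("  training instances: %d source + %d target\n",
              x$n_source, x$n_target))
  cat(sprintf("  iterations: %d (depth %d, learning rate %g, weight mode %s)\n",
              length(x$iterations), x$config$max_tree_depth,
              x$config$learning_rate, x$config$weight_mode))
  last <- x$iterations[[length(x$iterations)]]
  cat(sprintf("  final: lambda %.4f, target avg |residual| %.4f, train loss %.4f\n",
              last$lambda, last$target_avg_residual, last$train_loss))
  invisible(x)
}

#' Per-iteration training log of a TrGB fit
#'
#' @param model a fitted [trgb()] model.
#' @return data.frame with one row per boosting iteration: learner strength,
#'   mean absolute target residual, weighted training loss, and min / median
#'   / max instance weight by domain — the diagnostic trace for spotting
#'   negative transfer.
#' @export
training_log <- function(model) {
  stopifnot(inherits(model, "trgb"))
  rows <- lapply(seq_along(model$iterations), function(t) {
    it <- model$iterations[[t]]
    ws <- it$weight_summary
    src <- ws$source %||% c(min = 1, median = 1, max = 1)
    tgt <- ws$target
    data.frame(
      iteration = t, lambda = it$lambda,
      target_avg_residual = it$target_avg_residual,
      train_loss = it$train_loss,
      source_w_min = src[["min"]], source_w_median = src[["median"]],
      source_w_max = src[["max"]],
      target_w_min = tgt[["min"]], target_w_median = tgt[["median"]],
      target_w_max = tgt[["max"]]
    )
  })
  do.call(rbind, rows)
}
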
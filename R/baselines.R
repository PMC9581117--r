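# Comparison arms for the transfer experiments. All baselines share the
# same rpart tree builder, config and seed handling as TrGB, so method
# comparisons isolate the weighting scheme:
#   target_only  - plain GBM on the labeled target data alone
#   source_only  - plain GBM on the source data, tested on target
#   pooled       - plain GBM on source + target concatenated, unit weights
#                  (the control separating "transfer helps" from "more
#                  data helps")
#   tradaboost   - the classic boosting-for-transfer weight update with the
#                  same tree base learner

#' Fit a comparison baseline
#'
#' @param method one of `"target_only"`, `"source_only"`, `"pooled"`,
#'   `"tradaboost"`.
#' @param source source-domain data.frame (or `NULL`; required by every
#'   method except `target_only`).
#' @param target labeled target-domain data.frame (required by every method
#'   except `source_only`).
#' @param config a [trgb_config()]; tree depth, leaf size, iteration count
#'   and learning rate are shared with TrGB.
#' @param label label column name.
#' @return a classifier with a `predict` method (`type = "prob"` /
#'   `"class"`). The plain-GBM baselines are [trgb()] models fitted with an
#'   empty source set, in which every boosting weight stays at 1.
#' @export
#' @examples
#' pair <- generate_domain_pair(transfer_scenario(seed = 1))
#' base <- fit_baseline("target_only", NULL, pair$target_labeled,
#'                      config = trgb_config(n_iterations = 10))
#' mean(predict(base, pair$target_test, type = "class") == pair$target_test$label)
fit_baseline <- function(method = c("target_only", "source_only", "pooled",
                                    "tradaboost"),
                         source, target, config = trgb_config(),
                         label = "label") {
  method <- match.arg(method)
  need_source <- method != "target_only"
  need_target <- method != "source_only"
  if (need_source && (is.null(source) || NROW(source) == 0))
    stop("method '", method, "' requires source-domain data")
  if (need_target && (is.null(target) || NROW(target) == 0))
    stop("method '", method, "' requires target-domain data")
  switch(method,
    target_only = trgb(NULL, target, config = config, label = label),
    source_only = trgb(NULL, source, config = config, label = label),
    pooled = {
      src <- as.data.frame(source)
      tgt <- as.data.frame(target)
      common <- intersect(colnames(src), colnames(tgt))
      trgb(NULL, rbind(src[common], tgt[common]), config = config, label = label)
    },
    tradaboost = tradaboost(source, target, config = config, label = label)
  )
}

#' TrAdaBoost transfer classifier
#'
#' The cited boosting-for-transfer construction: a weighted-majority update
#' in which a misclassified target instance is up-weighted by the
#' iteration's error ratio while a misclassified source instance is
#' down-weighted by the fixed factor `beta = 1 / (1 + sqrt(2 ln m / N))`
#' (`m` source instances, `N` iterations). Classification is by weighted
#' vote of the later half of the learners. The base learner is a
#' depth-limited classification tree built with the same controls as the
#' TrGB regression trees.
#'
#' @inheritParams fit_baseline
#' @return an object of class `tradaboost`.
#' @export
tradaboost <- function(source, target, config = trgb_config(), label = "label") {
  tgt <- prepare_samples(target, label, what = "target")
  if (nrow(tgt$x) == 0 || length(tgt$levels) != 2)
    stop("tradaboost requires a binary, non-empty target domain")
  src <- prepare_samples(source, label, what = "source", levels = tgt$levels)
  if (is.null(src) || nrow(src$x) == 0)
    stop("tradaboost requires source-domain data")

  x <- rbind(src$x, tgt$x)
  y <- c(src$y, tgt$y)
  m <- nrow(src$x)
  n <- nrow(x)
  is_target <- seq_len(n) > m
  n_iter <- config$n_iterations
  beta_src <- 1 / (1 + sqrt(2 * log(m) / n_iter))

  w <- rep(1 / n, n)
  learners <- vector("list", n_iter)
  beta_t <- numeric(n_iter)
  weight_trace <- matrix(NA_real_, n_iter, n)
  df <- as.data.frame(x)

  for (t in seq_len(n_iter)) {
    p <- w / sum(w)
    fit <- fit_class_stump(df, y, p, config)
    h <- fit$pred
    err_vec <- abs(h - y)
    eps <- sum(p[is_target] * err_vec[is_target]) / sum(p[is_target])
    eps <- min(max(eps, 1e-10), 0.499) # weighted-majority update needs eps < 1/2
    bt <- eps / (1 - eps)
    # source errors shrink by the fixed beta, target errors grow by 1/beta_t
    w[!is_target] <- w[!is_target] * beta_src^(err_vec[!is_target])
    w[is_target] <- w[is_target] * bt^(-err_vec[is_target])
    learners[[t]] <- fit$nodes
    beta_t[t] <- bt
    weight_trace[t, ] <- w
  }

  structure(
    list(
      learners = learners, beta_t = beta_t,
      vote_start = ceiling(n_iter / 2),
      label_levels = tgt$levels,
      feature_names = colnames(x),
      n_source = m, n_target = n - m,
      weight_trace = weight_trace,
      config = config
    ),
    class = "tradaboost"
  )
}

# weighted 0/1 classification tree, returned as a node table whose leaf
# value is the hard class vote (0 or 1)
fit_class_stump <- function(df, y, w, config) {
  d <- df
  d$..r <- y
  d$..w <- w
  f <- stats::reformulate(setdiff(colnames(df), c("..r", "..w")), response = "..r")
  environment(f) <- environment()
  fit <- rpart::rpart(
    f, data = d, weights = ..w, method = "anova",
    control = rpart::rpart.control(
      maxdepth = config$max_tree_depth,
      minbucket = config$min_leaf_count,
      minsplit = 2L * config$min_leaf_count,
      cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0, usesurrogate = 0
    )
  )
  nodes <- tree_nodes(fit)
  nodes$value <- as.numeric(nodes$value >= 0.5) # weighted leaf mean -> hard vote
  leaf_ids <- train_leaf_ids(fit)
  pred <- nodes$value[match(leaf_ids, nodes$id)]
  list(nodes = nodes, pred = pred)
}

#' @export
predict.tradaboost <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- newdata_matrix(object, newdata)
  idx <- seq(object$vote_start, length(object$learners))
  lw <- -log(pmax(object$beta_t[idx], 1e-10)) # vote weight per learner
  votes <- matrix(0, nrow(x), length(idx))
  for (j in seq_along(idx)) {
    votes[, j] <- predict_tree_nodes(object$learners[[idx[j]]], x)
  }
  # weighted vote of the later half: predict 1 iff sum lw * h >= sum lw / 2
  score <- votes %*% lw
  frac <- as.numeric(score / sum(lw))
  if (type == "prob") {
    pm <- cbind(1 - frac, frac)
    colnames(pm) <- object$label_levels
    return(pm)
  }
  factor(object$label_levels[(frac >= 0.5) + 1L], levels = object$label_levels)
}

#' @export
print.tradaboost <- function(x, ...) {
  cat("TrAdaBoost transfer classifier\n")
  cat(sprintf("  classes: %s; %d source + %d target instances\n",
              paste(x$label_levels, collapse = " vs "), x$n_source, x$n_target))
  cat(sprintf("  learners: %d (voting over %d..%d)\n",
              length(x$learners), x$vote_start, length(x$learners)))
  invisible(x)
}
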
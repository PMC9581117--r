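# Regression-tree base learner backed by rpart (anova method: weighted
# squared error on pseudo-residuals). Each fitted tree is converted at once
# into a plain node table — node id in heap order (children of k are 2k,
# 2k+1), split variable, threshold, direction, and the Newton leaf step —
# so prediction and JSON serialization share one representation and no
# rpart objects are kept in the model.

fit_residual_tree <- function(x, residuals, weights, config) {
  df <- as.data.frame(x)
  df$..r <- residuals
  df$..w <- weights
  f <- stats::reformulate(colnames(x), response = "..r")
  environment(f) <- environment()
  rpart::rpart(
    f, data = df, weights = ..w, method = "anova",
    control = rpart::rpart.control(
      maxdepth = config$max_tree_depth,
      minbucket = config$min_leaf_count,
      minsplit = 2L * config$min_leaf_count,
      cp = 0, xval = 0,
      maxcompete = 0, maxsurrogate = 0, usesurrogate = 0
    )
  )
}

# rpart frame/splits -> node table. With competitors and surrogates
# disabled, the k-th non-leaf row of frame corresponds to the k-th row of
# the splits matrix; ncat < 0 sends x < threshold to the left child.
tree_nodes <- function(fit, leaf_values = NULL) {
  fr <- fit$frame
  ids <- as.integer(rownames(fr))
  is_leaf <- fr$var == "<leaf>"
  nodes <- data.frame(
    id = ids,
    leaf = is_leaf,
    var = ifelse(is_leaf, NA_character_, as.character(fr$var)),
    threshold = NA_real_,
    less_goes_left = NA,
    value = fr$yval,
    stringsAsFactors = FALSE
  )
  if (any(!is_leaf)) {
    sp <- fit$splits
    nodes$threshold[!is_leaf] <- sp[seq_len(sum(!is_leaf)), "index"]
    nodes$less_goes_left[!is_leaf] <- sp[seq_len(sum(!is_leaf)), "ncat"] < 0
  }
  if (!is.null(leaf_values)) {
    stopifnot(all(names(leaf_values) %in% as.character(nodes$id[nodes$leaf])))
    nodes$value[match(as.integer(names(leaf_values)), nodes$id)] <- leaf_values
  }
  nodes
}

# leaf node id for each training observation
train_leaf_ids <- function(fit) {
  as.integer(rownames(fit$frame))[fit$where]
}

# route rows of x through a node table; returns the leaf value per row
predict_tree_nodes <- function(nodes, x) {
  out <- numeric(nrow(x))
  route <- function(idx, id) {
    if (length(idx) == 0) return(invisible(NULL))
    row <- nodes[nodes$id == id, ]
    if (row$leaf) {
      out[idx] <<- row$value
      return(invisible(NULL))
    }
    less <- x[idx, row$var] < row$threshold
    if (row$less_goes_left) {
      route(idx[less], 2L * id)
      route(idx[!less], 2L * id + 1L)
    } else {
      route(idx[!less], 2L * id)
      route(idx[less], 2L * id + 1L)
    }
  }
  route(seq_len(nrow(x)), 1L)
  out
}

# per-leaf Newton step for the log-likelihood loss: for each leaf,
# sum(w * (y - p)) / sum(w * p * (1 - p)) over the instances in it
newton_leaf_steps <- function(leaf_ids, residuals, hessians, weights) {
  num <- tapply(weights * residuals, leaf_ids, sum)
  den <- tapply(weights * hessians, leaf_ids, sum)
  den <- pmax(den, 1e-12)
  steps <- num / den
  names(steps) <- names(num)
  steps
}
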
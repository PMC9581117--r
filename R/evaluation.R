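# Experimental protocol: stratified k-fold cross-validation over the
# target domain (the source joins every training fold and never a test
# fold), imbalance-aware metrics (accuracy + macro precision/recall/F1,
# in percent), and the multi-method comparison matrix. Every method sees
# identical folds and seeds so comparisons isolate the weighting scheme.

#' Stratified fold assignment over the target domain
#'
#' Partitions the target instances into `n_folds` folds with per-class
#' counts differing by at most one across folds. Only target instances are
#' ever assigned to folds: source data joins every training fold whole.
#'
#' @param labels class label vector of the target instances.
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed; the assignment is deterministic given it.
#' @return integer vector of fold ids in `1:n_folds`, one per instance.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 1L) {
  labels <- as.character(labels)
  if (n_folds < 2) stop("n_folds must be at least 2")
  tab <- table(labels)
  small <- names(tab)[tab < n_folds]
  if (length(small) > 0)
    stop("class smaller than n_folds: ", paste(small, collapse = ", "))
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Classification metrics (accuracy + macro precision / recall / F1)
#'
#' Accuracy is the fraction correct; precision, recall and F1 are computed
#' per class and macro-averaged (unweighted mean over classes, the
#' imbalance-sensitive convention). All values are in percent. A class
#' with no predicted positives has precision 0; a class with precision +
#' recall = 0 has F1 0.
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param class_list the label space; every observed label must be in it.
#' @return a list: `accuracy`, `precision`, `recall`, `f1` (macro, percent)
#'   and `per_class`, a data.frame of per-class precision / recall / F1.
#' @export
#' @examples
#' # 2-class confusion with TP=3, FP=1, FN=1, TN=5
#' truth <- c(rep("pos", 4), rep("neg", 6))
#' pred  <- c(rep("pos", 3), "neg", "pos", rep("neg", 5))
#' compute_metrics(truth, pred, c("neg", "pos"))$accuracy  # 80
compute_metrics <- function(true_labels, predicted_labels, class_list) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  unseen <- setdiff(unique(c(true_labels, predicted_labels)), class_list)
  if (length(unseen) > 0)
    stop("labels outside class_list: ", paste(unseen, collapse = ", "))
  acc <- 100 * mean(true_labels == predicted_labels)
  per <- lapply(class_list, function(cl) {
    tp <- sum(true_labels == cl & predicted_labels == cl)
    fp <- sum(true_labels != cl & predicted_labels == cl)
    fn <- sum(true_labels == cl & predicted_labels != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, precision = 100 * prec, recall = 100 * rec,
               f1 = 100 * f1, support = tp + fn, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(
    accuracy = acc,
    precision = mean(per$precision),
    recall = mean(per$recall),
    f1 = mean(per$f1),
    per_class = per
  )
}

#' Experiment plan for the method comparison matrix
#'
#' @param methods methods to compare; any of `"target_only"`,
#'   `"source_only"`, `"pooled"`, `"tradaboost"`, `"trgb"`.
#' @param protocol `"holdout"` trains on the full labeled target set (plus
#'   source) and evaluates on the generated target test set;
#'   `"cv"` runs stratified `n_folds`-fold cross-validation over the
#'   labeled target set, the source joining every training fold.
#' @param n_folds folds for the CV protocol.
#' @param n_seeds number of independent replicate runs (fresh generator
#'   draw and fold split per replicate).
#' @param config shared [trgb_config()] for all methods.
#' @return an object of class `experiment_plan`.
#' @export
experiment_plan <- function(methods = c("target_only", "source_only",
                                        "pooled", "trgb"),
                            protocol = c("holdout", "cv"),
                            n_folds = 5L,
                            n_seeds = 25L,
                            config = trgb_config()) {
  protocol <- match.arg(protocol)
  known <- c("target_only", "source_only", "pooled", "tradaboost", "trgb")
  bad <- setdiff(methods, known)
  if (length(bad) > 0)
    stop("unknown method: ", paste(bad, collapse = ", "))
  if (n_folds < 2) stop("n_folds must be at least 2")
  structure(
    list(methods = methods, protocol = protocol, n_folds = as.integer(n_folds),
         n_seeds = as.integer(n_seeds), config = config),
    class = "experiment_plan"
  )
}

# fit one comparison method; multiclass targets route through the
# one-vs-rest wrapper for trgb and the plain-GBM baselines
fit_method_any <- function(method, source, target, config, label = "label") {
  K <- length(unique(as.character(target[[label]])))
  if (K <= 2) {
    return(if (method == "trgb")
      trgb(source, target, config = config, label = label,
           keep_history = FALSE)
      else fit_baseline(method, source, target, config = config, label = label))
  }
  switch(method,
    trgb = trgb_multiclass(source, target, config = config, label = label),
    target_only = trgb_multiclass(NULL, target, config = config, label = label),
    source_only = trgb_multiclass(NULL, source, config = config, label = label),
    pooled = {
      src <- as.data.frame(source); tgt <- as.data.frame(target)
      common <- intersect(colnames(src), colnames(tgt))
      trgb_multiclass(NULL, rbind(src[common], tgt[common]), config = config,
                      label = label)
    },
    stop("method '", method, "' does not support more than two classes")
  )
}

#' Run the method comparison experiment
#'
#' For each replicate seed: generate a fresh domain pair from the
#' scenario, fit every method on identical training data, and score it on
#' identical held-out target data (holdout protocol) or identical
#' stratified CV folds (cv protocol). The fold assignment fingerprint is
#' recorded per replicate so shared-fold comparisons are verifiable.
#'
#' @param plan an [experiment_plan()].
#' @param scenario a [scenario_spec()], or a function `(seed) ->
#'   domain_pair` for custom generators (e.g.
#'   `function(s) make_emci_lmci_scenario(cross_label_scenario(seed = s))`).
#' @param base_seed replicate `i` uses seed `base_seed + i - 1`.
#' @return an object of class `score_table`: `summary` (mean and sd of
#'   each metric per method, percent), `detail` (per replicate / fold /
#'   method rows) and the plan.
#' @export
run_experiment <- function(plan, scenario, base_seed = 1L) {
  stopifnot(inherits(plan, "experiment_plan"))
  make_pair <- if (inherits(scenario, "scenario_spec")) {
    function(s) {
      sp <- scenario
      sp$seed <- as.integer(s)
      generate_domain_pair(sp)
    }
  } else if (is.function(scenario)) {
    scenario
  } else {
    stop("scenario must be a scenario_spec or a function of the seed")
  }

  detail <- list()
  for (i in seq_len(plan$n_seeds)) {
    seed_i <- as.integer(base_seed + i - 1)
    pair <- make_pair(seed_i)
    source <- pair$source
    if (!is.null(pair$label_map))
      source <- map_label_space(source, pair$label_map)
    class_list <- levels(pair$target_labeled$label)

    if (plan$protocol == "holdout") {
      eval_sets <- list(list(
        train_target = pair$target_labeled,
        test = pair$target_test,
        fold = NA_integer_,
        fold_fp = NA_character_
      ))
    } else {
      folds <- stratified_folds(pair$target_labeled$label, plan$n_folds,
                                seed = seed_i)
      fp <- fingerprint(folds)
      eval_sets <- lapply(seq_len(plan$n_folds), function(k) list(
        train_target = pair$target_labeled[folds != k, , drop = FALSE],
        test = pair$target_labeled[folds == k, , drop = FALSE],
        fold = k,
        fold_fp = fp
      ))
    }

    for (es in eval_sets) {
      for (method in plan$methods) {
        fit <- fit_method_any(method, source, es$train_target, plan$config)
        pred <- predict(fit, es$test, type = "class")
        mt <- compute_metrics(es$test$label, pred, class_list)
        detail[[length(detail) + 1]] <- data.frame(
          replicate = i, seed = seed_i, fold = es$fold, method = method,
          accuracy = mt$accuracy, precision = mt$precision,
          recall = mt$recall, f1 = mt$f1,
          fold_fingerprint = es$fold_fp %||% NA_character_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  detail <- do.call(rbind, detail)

  metrics <- c("accuracy", "precision", "recall", "f1")
  summ <- do.call(rbind, lapply(metrics, function(mn) {
    do.call(rbind, lapply(plan$methods, function(me) {
      v <- detail[[mn]][detail$method == me]
      data.frame(metric = mn, method = me, mean = mean(v), sd = stats::sd(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(summary = summ, detail = detail, plan = plan),
            class = "score_table")
}

#' @export
print.score_table <- function(x, digits = 1, ...) {
  cat("Score table (mean over", max(x$detail$replicate), "replicates,",
      x$plan$protocol, "protocol; percent)\n")
  wide <- stats::reshape(
    x$summary[c("metric", "method", "mean")],
    idvar = "metric", timevar = "method", direction = "wide"
  )
  colnames(wide) <- sub("^mean\\.", "", colnames(wide))
  print(format(wide, digits = digits, nsmall = digits), row.names = FALSE)
  invisible(x)
}

#' Extract the mean of one metric per method
#'
#' @param score a `score_table` from [run_experiment()].
#' @param metric one of `"accuracy"`, `"precision"`, `"recall"`, `"f1"`.
#' @return named numeric vector of means (percent) by method.
#' @export
score_means <- function(score, metric = "accuracy") {
  s <- score$summary[score$summary$metric == metric, ]
  stats::setNames(s$mean, s$method)
}

#' Grouped-bar F1 comparison figure
#'
#' @param score a `score_table`.
#' @param metric metric to plot (default `"f1"`).
#' @return a ggplot object: one bar per method with an error bar of one
#'   standard deviation across replicates.
#' @export
plot_score_table <- function(score, metric = "f1") {
  s <- score$summary[score$summary$metric == metric, ]
  s$method <- factor(s$method, levels = score$plan$methods)
  ggplot2::ggplot(s, ggplot2::aes(x = method, y = mean, fill = method)) +
    ggplot2::geom_col(width = 0.7, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sd, ymax = mean + sd),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = paste0(metric, " (%)"),
                  title = paste("Method comparison:", metric)) +
    ggplot2::theme_minimal()
}

#' Write a score table to CSV and JSON
#'
#' @param score a `score_table`.
#' @param path_csv,path_json output paths (`NULL` to skip either).
#' @param path_detail optional JSON-lines path for the per-fold detail log.
#' @return invisibly, the list of paths written.
#' @export
write_score_table <- function(score, path_csv = NULL, path_json = NULL,
                              path_detail = NULL) {
  written <- list()
  if (!is.null(path_csv)) {
    utils::write.csv(score$summary, path_csv, row.names = FALSE)
    written$csv <- path_csv
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(summary = score$summary,
           config_fingerprint = fingerprint(unclass(score$plan$config))),
      path_json, dataframe = "rows", auto_unbox = TRUE, digits = NA)
    written$json <- path_json
  }
  if (!is.null(path_detail)) {
    con <- file(path_detail, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(score$detail))) {
      writeLines(jsonlite::toJSON(as.list(score$detail[i, ]),
                                  auto_unbox = TRUE, digits = NA, na = "null"),
                 con)
    }
    written$detail <- path_detail
  }
  invisible(written)
}
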
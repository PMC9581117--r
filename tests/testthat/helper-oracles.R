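# Independent oracles, kept on separate code paths from the implementation.

# metrics recomputed from an explicit confusion matrix (classes x classes,
# rows = truth, cols = prediction); the implementation works from label
# vectors and never builds this table
oracle_metrics_from_confusion <- function(cm) {
  classes <- rownames(cm)
  acc <- sum(diag(cm)) / sum(cm)
  prec <- rec <- f1 <- numeric(length(classes))
  for (i in seq_along(classes)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    prec[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[i] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[i] <- if (prec[i] + rec[i] == 0) 0 else
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
  }
  list(accuracy = 100 * acc, precision = 100 * mean(prec),
       recall = 100 * mean(rec), f1 = 100 * mean(f1))
}

# expand a confusion matrix into label vectors
labels_from_confusion <- function(cm) {
  classes <- rownames(cm)
  truth <- pred <- character(0)
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    k <- cm[i, j]
    if (k > 0) {
      truth <- c(truth, rep(classes[i], k))
      pred <- c(pred, rep(classes[j], k))
    }
  }
  list(truth = truth, pred = pred)
}

random_confusion <- function(k, max_count = 30) {
  cm <- matrix(sample(0:max_count, k * k, replace = TRUE), k, k)
  # ensure at least one observation
  if (sum(cm) == 0) cm[1, 1] <- 1
  rownames(cm) <- colnames(cm) <- paste0("c", seq_len(k))
  cm
}

# python + scikit-learn, used as a fully external reference where a test
# calls for one; skipped silently is not allowed, so callers only use it
# for checks the environment supports
run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  out <- system2("python", f, stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("python oracle failed: ", paste(out, collapse = "\n"))
  out
}
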
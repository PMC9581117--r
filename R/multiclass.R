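# One-vs-rest extension of binary TrGB to K classes. Each class gets its
# own binary submodel (class vs rest) with the full transfer weighting
# machinery; per-class sigmoid scores are normalized to a probability
# simplex. The scalar residual magnitude |y - p| that drives the weighting
# stays well-defined inside every submodel, which is why one-vs-rest is
# used rather than a multinomial extension.

#' Fit a multiclass transfer gradient boosting classifier
#'
#' Trains one binary [trgb()] submodel per class (one-vs-rest). With
#' exactly two classes this collapses to a single binary model, so
#' predictions are identical to [trgb()] on the same data and seed.
#'
#' @param source source-domain data.frame (or `NULL`). Source labels must
#'   lie inside the target label space; map them first with
#'   [map_label_space()] if the label spaces differ.
#' @param target labeled target-domain data.frame; must contain at least
#'   two classes, and every class used.
#' @param config a [trgb_config()] shared by all submodels.
#' @param label label column name.
#' @param class_labels optional explicit class ordering; defaults to the
#'   sorted target classes. Every listed class must be present in the
#'   target data.
#' @return an object of class `trgb_multiclass`.
#' @export
trgb_multiclass <- function(source, target, config = trgb_config(),
                            label = "label", class_labels = NULL) {
  target <- as.data.frame(target)
  if (!label %in% colnames(target))
    stop("no '", label, "' column in the target table")
  tgt_lab <- as.character(target[[label]])
  present <- if (is.factor(target[[label]]))
    levels(droplevels(target[[label]])) else sort(unique(tgt_lab))
  class_labels <- as.character(class_labels %||% present)
  absent <- setdiff(class_labels, present)
  if (length(absent) > 0)
    stop("class absent from the target domain: ", paste(absent, collapse = ", "))
  if (length(class_labels) < 2) stop("need at least two classes")

  if (!is.null(source)) {
    src_lab <- as.character(as.data.frame(source)[[label]])
    bad <- setdiff(unique(src_lab), class_labels)
    if (length(bad) > 0)
      stop("source labels outside the target label space: ",
           paste(bad, collapse = ", "),
           " (map the label space first, see map_label_space())")
  }

  if (length(class_labels) == 2) {
    # exact collapse to the binary model
    relevel2 <- function(d) {
      if (is.null(d)) return(NULL)
      d <- as.data.frame(d)
      d[[label]] <- factor(as.character(d[[label]]), levels = class_labels)
      d
    }
    fit <- trgb(relevel2(source), relevel2(target), config = config, label = label)
    models <- list(fit)
    names(models) <- class_labels[2]
  } else {
    models <- lapply(class_labels, function(cl) {
      one_vs_rest <- function(d) {
        if (is.null(d)) return(NULL)
        d <- as.data.frame(d)
        d[[label]] <- factor(ifelse(as.character(d[[label]]) == cl, cl, ".rest"),
                             levels = c(".rest", cl))
        d
      }
      trgb(one_vs_rest(source), one_vs_rest(target), config = config,
           label = label, keep_history = FALSE)
    })
    names(models) <- class_labels
  }

  structure(
    list(class_labels = class_labels, strategy = "one_vs_rest", models = models),
    class = "trgb_multiclass"
  )
}

#' Predict from a multiclass TrGB model
#'
#' Per-class sigmoid scores are normalized to sum to 1 per row; the
#' predicted label is the argmax, with ties broken toward the class listed
#' first in `class_labels`.
#'
#' @param object a [trgb_multiclass()] model.
#' @param newdata data.frame or matrix of features.
#' @param type `"prob"` for the K-column probability matrix, `"class"` for
#'   predicted labels.
#' @param ... unused.
#' @export
predict.trgb_multiclass <- function(object, newdata,
                                    type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (length(object$class_labels) == 2) {
    pm <- predict(object$models[[1]], newdata, type = "prob")
    pm <- pm[, object$class_labels, drop = FALSE]
  } else {
    raw <- vapply(object$class_labels, function(cl) {
      predict(object$models[[cl]], newdata, type = "prob")[, cl]
    }, numeric(NROW(newdata)))
    raw <- matrix(raw, ncol = length(object$class_labels),
                  dimnames = list(NULL, object$class_labels))
    pm <- raw / rowSums(raw)
  }
  if (type == "prob") return(pm)
  # first-listed class wins ties
  idx <- apply(pm, 1, which.max)
  factor(object$class_labels[idx], levels = object$class_labels)
}

#' @export
print.trgb_multiclass <- function(x, ...) {
  cat("TrGB multiclass model (", x$strategy, ")\n", sep = "")
  cat("  classes:", paste(x$class_labels, collapse = ", "), "\n")
  cat("  submodels:", length(x$models), "\n")
  invisible(x)
}
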
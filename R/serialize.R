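# Versioned JSON serialization of fitted models. A binary model document
# stores the init score, config, label codec and each iteration's node
# table (nested split records + leaf steps); a multiclass model stores the
# class list plus one embedded binary document per class.

MODEL_FORMAT_BINARY <- "trgb-model/1"
MODEL_FORMAT_MULTICLASS <- "trgb-multiclass-model/1"

model_to_list <- function(model) {
  stopifnot(inherits(model, "trgb"))
  list(
    format = MODEL_FORMAT_BINARY,
    init_score = model$init_score,
    label_levels = as.list(model$label_levels),
    feature_names = as.list(model$feature_names),
    n_source = model$n_source,
    n_target = model$n_target,
    config = unclass(model$config),
    config_fingerprint = fingerprint(unclass(model$config)),
    iterations = lapply(model$iterations, function(it) {
      list(
        lambda = it$lambda,
        target_avg_residual = it$target_avg_residual,
        train_loss = it$train_loss,
        nodes = lapply(seq_len(nrow(it$nodes)), function(i) {
          nd <- it$nodes[i, ]
          list(id = nd$id, leaf = nd$leaf,
               var = if (nd$leaf) NULL else nd$var,
               threshold = if (nd$leaf) NULL else nd$threshold,
               less_goes_left = if (nd$leaf) NULL else nd$less_goes_left,
               value = nd$value)
        })
      )
    })
  )
}

list_to_model <- function(doc) {
  if (!identical(doc$format, MODEL_FORMAT_BINARY))
    stop("not a TrGB binary model document (format: ",
         doc$format %||% "missing", ")")
  cfg <- do.call(trgb_config, doc$config)
  iters <- lapply(doc$iterations, function(it) {
    nodes <- do.call(rbind, lapply(it$nodes, function(nd) {
      data.frame(
        id = as.integer(nd$id),
        leaf = as.logical(nd$leaf),
        var = as.character(nd$var %||% NA_character_),
        threshold = as.numeric(nd$threshold %||% NA_real_),
        less_goes_left = as.logical(nd$less_goes_left %||% NA),
        value = as.numeric(nd$value),
        stringsAsFactors = FALSE
      )
    }))
    list(
      lambda = it$lambda,
      target_avg_residual = it$target_avg_residual,
      train_loss = it$train_loss,
      nodes = nodes
    )
  })
  structure(
    list(
      init_score = doc$init_score,
      iterations = iters,
      label_levels = as.character(unlist(doc$label_levels)),
      feature_names = as.character(unlist(doc$feature_names)),
      config = cfg,
      n_source = doc$n_source,
      n_target = doc$n_target
    ),
    class = "trgb"
  )
}

#' Write a fitted model to a JSON document
#'
#' Binary models serialize as a single versioned document (init score,
#' config with fingerprint, label codec, per-iteration tree structure as
#' nested split records with leaf steps); multiclass models as the class
#' list plus one binary document per class. Per-iteration residual and
#' weight histories are not serialized.
#'
#' @param model a [trgb()] or [trgb_multiclass()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trgb <- function(model, path) {
  doc <- if (inherits(model, "trgb_multiclass")) {
    list(
      format = MODEL_FORMAT_MULTICLASS,
      class_labels = as.list(model$class_labels),
      strategy = model$strategy,
      models = lapply(model$models, model_to_list)
    )
  } else {
    model_to_list(model)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a fitted model back from a JSON document
#'
#' @param path path written by [write_trgb()].
#' @return a `trgb` or `trgb_multiclass` model; predictions from the
#'   restored model match the original to the 15-significant-digit
#'   precision of the JSON text.
#' @export
read_trgb <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  # drop JSON nulls so %||% defaults apply downstream
  if (identical(doc$format, MODEL_FORMAT_MULTICLASS)) {
    models <- lapply(doc$models, list_to_model)
    labels <- as.character(unlist(doc$class_labels))
    names(models) <- labels
    return(structure(
      list(class_labels = labels, strategy = doc$strategy, models = models),
      class = "trgb_multiclass"
    ))
  }
  list_to_model(doc)
}
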
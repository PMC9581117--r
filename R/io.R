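# Tabular I/O for clinical feature tables: delimited text with a header
# (comma, dot decimal, UTF-8), strict validation (no silent imputation —
# a non-numeric or missing feature cell is a located, hard error), a JSON
# provenance sidecar carrying the seed and config fingerprint, and the
# label-space mapping needed for cross-label transfer.

#' Construct a validated feature table
#'
#' @param data data.frame of numeric feature columns plus a label column
#'   (and optionally a domain column with values `source` / `target`).
#' @param label_column name of the label column.
#' @param domain_column optional name of the domain column.
#' @param provenance free-form list recorded with the table (seeds,
#'   generating spec, audit trail).
#' @return an object of class `feature_table` (a data.frame subclass with
#'   metadata attributes).
#' @export
feature_table <- function(data, label_column = "label",
                          domain_column = NULL, provenance = list()) {
  data <- as.data.frame(data)
  nms <- colnames(data)
  dup <- nms[duplicated(nms)]
  if (length(dup) > 0)
    stop("duplicate header names: ", paste(unique(dup), collapse = ", "))
  if (!label_column %in% nms)
    stop("missing label column '", label_column, "'")
  if (any(is.na(data[[label_column]])) || any(data[[label_column]] == ""))
    stop("label column '", label_column, "' has empty entries")
  if (!is.null(domain_column)) {
    if (!domain_column %in% nms)
      stop("missing domain column '", domain_column, "'")
    bad <- setdiff(unique(as.character(data[[domain_column]])),
                   c("source", "target"))
    if (length(bad) > 0)
      stop("domain column has values other than source/target: ",
           paste(bad, collapse = ", "))
  }
  feat_cols <- setdiff(nms, c(label_column, domain_column))
  for (cl in feat_cols) {
    v <- data[[cl]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(as.character(v)))
      bad_rows <- which(is.na(num) & !is.na(v))
      if (length(bad_rows) > 0)
        stop("non-numeric feature cell at row ", bad_rows[1],
             ", column '", cl, "'")
      v <- num
    }
    bad_rows <- which(!is.finite(v))
    if (length(bad_rows) > 0)
      stop("missing or non-finite feature cell at row ", bad_rows[1],
           ", column '", cl, "' (missing values are not imputed)")
    data[[cl]] <- v
  }
  structure(data,
            label_column = label_column,
            domain_column = domain_column,
            provenance = provenance,
            class = c("feature_table", "data.frame"))
}

#' Read a feature table from delimited text
#'
#' Reads a CSV (comma separator, dot decimal, UTF-8, header row) and
#' validates it: unique header names, a present label column, and numeric,
#' finite feature cells — any violation is an error naming the row and
#' column. If a JSON provenance sidecar (`<path>.provenance.json`) exists
#' it is attached.
#'
#' @param path CSV file path.
#' @inheritParams feature_table
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, label_column = "label",
                               domain_column = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (is.null(domain_column) && "domain" %in% colnames(df))
    domain_column <- "domain"
  prov <- list()
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar))
    prov <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  feature_table(df, label_column = label_column,
                domain_column = domain_column, provenance = prov)
}

#' Write a feature table to delimited text (plus provenance sidecar)
#'
#' Numbers are written with full precision (up to 15 significant digits),
#' so a write-then-read round trip reproduces the table. The provenance
#' (seed record, spec, label-map audits) goes to a JSON sidecar at
#' `<path>.provenance.json`.
#'
#' @param table a [feature_table()] or plain data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (!inherits(table, "feature_table")) table <- feature_table(table)
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  prov <- attr(table, "provenance")
  if (length(prov) > 0)
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Map a table's labels into a different label space
#'
#' Rewrites the label column through a mapping such as `c(CN = "EMCI",
#' AD = "LMCI")`, the step that lets a source cohort labeled with disease
#' extremes train a target task over intermediate stages. Labels without a
#' mapping entry are dropped (`policy = "drop"`) or raise an error naming
#' the label (`policy = "error"`). A mapping audit is appended to the
#' table's provenance.
#'
#' @param table a [feature_table()] or data.frame with a label column.
#' @param map named character vector: `names(map)` are the current labels,
#'   values the new ones.
#' @param policy what to do with unmapped labels.
#' @param label_column label column name (defaults to the table's
#'   metadata, else `"label"`).
#' @return the relabeled table (a `feature_table`).
#' @export
map_label_space <- function(table, map, policy = c("error", "drop"),
                            label_column = NULL) {
  policy <- match.arg(policy)
  label_column <- label_column %||% attr(table, "label_column") %||% "label"
  domain_column <- attr(table, "domain_column")
  df <- as.data.frame(table)
  if (is.null(domain_column) && "domain" %in% colnames(df))
    domain_column <- "domain"
  if (!label_column %in% colnames(df))
    stop("missing label column '", label_column, "'")
  lab <- as.character(df[[label_column]])
  unmapped <- setdiff(unique(lab), names(map))
  n_before <- nrow(df)
  if (length(unmapped) > 0) {
    if (policy == "error")
      stop("unmapped label: ", paste(unmapped, collapse = ", "))
    keep <- lab %in% names(map)
    df <- df[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  new_levels <- unique(unname(map))
  df[[label_column]] <- factor(unname(map[lab]), levels = new_levels)
  rownames(df) <- NULL
  prov <- attr(table, "provenance") %||% list()
  prov$label_map_audit <- c(prov$label_map_audit, list(list(
    map = as.list(map), policy = policy,
    rows_before = n_before, rows_after = nrow(df)
  )))
  feature_table(df, label_column = label_column,
                domain_column = domain_column,
                provenance = prov)
}

#' Write a generated domain pair to a directory
#'
#' Writes `source.csv`, `target_labeled.csv` and `target_test.csv` plus a
#' `scenario.json` sidecar recording the full generating spec (the ground
#' truth for parameter-recovery checks).
#'
#' @param pair a `domain_pair` from [generate_domain_pair()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_domain_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "domain_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(seed = pair$spec$seed,
               spec_fingerprint = fingerprint(unclass(pair$spec)))
  for (part in c("source", "target_labeled", "target_test")) {
    tab <- feature_table(pair[[part]], domain_column = "domain",
                         provenance = c(prov, list(part = part)))
    write_feature_table(tab, file.path(dir, paste0(part, ".csv")))
  }
  spec_out <- unclass(pair$spec)
  spec_out$class_means <- if (is.null(spec_out$class_means)) NULL else
    as.data.frame(spec_out$class_means)
  jsonlite::write_json(spec_out, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
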
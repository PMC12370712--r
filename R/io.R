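#' Read delimited modality feature tables and label files
#'
#' Feature tables are comma- or tab-delimited text (autodetected from the
#' header line) with a header row and `node_id` as the first column; all
#' remaining columns must be numeric. Label files carry columns
#' `node_id,label` and optionally `split`.
#'
#' @param path file path.
#' @param modality_name label attached to the table (defaults to the file
#'   name without extension).
#' @return `read_modality_table()` returns a [modality_table()];
#'   `read_labels()` a data frame with `node_id`, integer `label`, and
#'   `split`.
#' @export
read_modality_table <- function(path, modality_name = NULL) {
  sep <- detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"node_id" %in% names(df)) names(df)[1] <- "node_id"
  ids <- as.character(df$node_id)
  feat <- as.matrix(df[setdiff(names(df), "node_id")])
  if (!is.numeric(feat)) stopf("%s: non-numeric feature column(s)", path)
  if (is.null(modality_name)) {
    modality_name <- sub("\\.[^.]*$", "", basename(path))
  }
  modality_table(modality_name, ids, feat)
}

#' @rdname read_modality_table
#' @export
read_labels <- function(path) {
  sep <- detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep,
                   stringsAsFactors = FALSE)
  if (!all(c("node_id", "label") %in% names(df))) {
    stopf("%s: label file needs 'node_id' and 'label' columns", path)
  }
  df$node_id <- as.character(df$node_id)
  df$label <- as.integer(df$label)
  if (!"split" %in% names(df)) df$split <- "train"
  df
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Load a cohort from disk
#'
#' Reads one or more modality tables plus a label file and aligns them into
#' a [multimodal_dataset()]; the label file's node order is authoritative.
#'
#' @param table_paths character vector of feature-table paths.
#' @param labels_path path to the label file.
#' @return A [multimodal_dataset()].
#' @export
read_cohort <- function(table_paths, labels_path) {
  lab <- read_labels(labels_path)
  tables <- lapply(table_paths, function(p) {
    tb <- read_modality_table(p)
    idx <- match(lab$node_id, tb$node_ids)
    if (anyNA(idx)) {
      stopf("%s: missing node id(s): %s", p,
            paste(lab$node_id[is.na(idx)], collapse = ", "))
    }
    modality_table(tb$modality_name, lab$node_id,
                   tb$features[idx, , drop = FALSE])
  })
  multimodal_dataset(tables, lab$label, lab$split)
}
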
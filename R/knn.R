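#' Aligned multimodal dataset
#'
#' Holds the per-modality feature tables for one cohort, the class label of
#' every subject, and the train/test split mask used by the transductive
#' classifier. All tables must share the same subject ids in the same order.
#'
#' @param tables list of [modality_table()]s with identical `node_ids`.
#' @param labels integer class labels `0..C-1` (or a factor), one per node;
#'   `NA` marks unlabeled nodes.
#' @param split character vector per node in `{"train", "test",
#'   "unlabeled"}`; defaults to all `"train"` for labeled nodes.
#' @return An object of class `"multimodal_dataset"`.
#' @export
multimodal_dataset <- function(tables, labels, split = NULL) {
  if (!length(tables)) stopf("need at least one modality table")
  stopifnot(all(vapply(tables, inherits, TRUE, "modality_table")))
  ids <- tables[[1]]$node_ids
  for (tb in tables[-1]) {
    if (!identical(tb$node_ids, ids)) {
      stopf("modality '%s' is not aligned with modality '%s'",
            tb$modality_name, tables[[1]]$modality_name)
    }
  }
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (length(labels) != length(ids)) stopf("one label per node required")
  if (is.null(split)) split <- ifelse(is.na(labels), "unlabeled", "train")
  if (!all(split %in% c("train", "test", "unlabeled"))) {
    stopf("split flags must be 'train', 'test' or 'unlabeled'")
  }
  if (length(split) != length(ids)) stopf("one split flag per node required")
  if (anyNA(labels[split != "unlabeled"])) {
    stopf("train/test nodes must all be labeled")
  }
  names(tables) <- vapply(tables, `[[`, "", "modality_name")
  structure(list(tables = tables, labels = labels, split = split,
                 node_ids = ids,
                 n_classes = length(unique(labels[!is.na(labels)]))),
            class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat(sprintf("Multimodal dataset: %d subjects, %d classes\n",
              length(x$node_ids), x$n_classes))
  for (tb in x$tables) {
    cat(sprintf("  %-14s %d features\n", tb$modality_name,
                ncol(tb$features)))
  }
  cat(sprintf("  split: %d train / %d test / %d unlabeled\n",
              sum(x$split == "train"), sum(x$split == "test"),
              sum(x$split == "unlabeled")))
  invisible(x)
}

#' KNN hypergraph construction for one modality
#'
#' Builds one hyperedge per node (the *centroid*): the centroid plus its `Z`
#' nearest neighbours under the Euclidean metric, so every hyperedge has
#' exactly `Z + 1` members, always includes its centroid (a built-in
#' self-connection), and `|E| = |Q|`. Distance ties are broken by ascending
#' node index, making the construction deterministic. Weights are unit.
#'
#' Distances should be computed on normalized features; the cohort pipeline
#' z-scores each modality (on training statistics) before calling this.
#'
#' @param table a [modality_table()].
#' @param Z positive integer neighbour count, `Z < |Q|`.
#' @return A [hypergraph()] with `|Q|` hyperedges named `knn_<node_id>`.
#' @export
knn_hyperedges <- function(table, Z) {
  stopifnot(inherits(table, "modality_table"))
  n <- length(table$node_ids)
  if (Z < 1 || Z >= n) stopf("Z must satisfy 1 <= Z < |Q| (= %d)", n)
  if (!all(is.finite(table$features))) stopf("features must be finite")
  D <- as.matrix(dist(table$features, method = "euclidean"))
  members <- vector("list", n)
  for (x in seq_len(n)) {
    others <- setdiff(seq_len(n), x)
    ord <- others[order(D[x, others], others)]   # tie-break: ascending index
    members[[x]] <- table$node_ids[c(x, ord[seq_len(Z)])]
  }
  hypergraph(members, table$node_ids,
             edge_ids = paste0("knn_", table$node_ids))
}

#' Fuse modalities into one feature matrix and one hypergraph
#'
#' Features are concatenated per node along the feature axis (total width
#' `sum(d_w)`); the per-modality KNN incidence matrices are concatenated
#' along the hyperedge axis, so the fused hypergraph has `W * |Q|`
#' hyperedges over the shared node set. Fused node degrees are therefore the
#' sum of the per-modality degrees.
#'
#' @param dataset a [multimodal_dataset()].
#' @param Z_per_modality integer vector of KNN neighbour counts, recycled
#'   across modalities.
#' @return List with `features` (numeric `|Q| x sum(d_w)` matrix) and
#'   `hypergraph` (the fused [hypergraph()]).
#' @export
fuse_modalities <- function(dataset, Z_per_modality = 5) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  W <- length(dataset$tables)
  Z_per_modality <- rep_len(Z_per_modality, W)
  features <- do.call(cbind, lapply(dataset$tables, `[[`, "features"))
  hgs <- mapply(knn_hyperedges, dataset$tables, Z_per_modality,
                SIMPLIFY = FALSE)
  B <- do.call(cbind, lapply(hgs, `[[`, "incidence"))
  edge_ids <- unlist(lapply(seq_len(W), function(w) {
    paste(dataset$tables[[w]]$modality_name,
          colnames(hgs[[w]]$incidence), sep = ":")
  }), use.names = FALSE)
  colnames(B) <- edge_ids
  members <- apply(B, 2, function(col) dataset$node_ids[col == 1],
                   simplify = FALSE)
  fused <- hypergraph(members, dataset$node_ids, edge_ids = edge_ids)
  list(features = features, hypergraph = fused)
}

# Z-score every modality using statistics from the `fit` rows (population
# sd; constant columns keep a unit divisor). Returns a new dataset.
standardize_dataset <- function(dataset, fit = NULL) {
  if (is.null(fit)) fit <- rep(TRUE, length(dataset$node_ids))
  tables <- lapply(dataset$tables, function(tb) {
    X <- tb$features
    mu <- colMeans(X[fit, , drop = FALSE])
    s <- sqrt(colMeans(sweep(X[fit, , drop = FALSE], 2, mu)^2))
    s[s == 0] <- 1
    modality_table(tb$modality_name, tb$node_ids,
                   sweep(sweep(X, 2, mu), 2, s, `/`))
  })
  multimodal_dataset(tables, dataset$labels, dataset$split)
}
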
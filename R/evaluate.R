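#' Repeated stratified k-fold cross-validation
#'
#' The paper-style protocol: `repeats` independent stratified partitions
#' into `folds` folds; for every (repeat, fold) pair the whole pipeline —
#' per-modality z-scoring on the training fold, KNN hypergraph construction
#' over all nodes, model training — is rerun from scratch with seed
#' `seed + r * folds + f` (zero-based `r`, `f`), and accuracy and macro-F1
#' are measured on the held-out fold. Fold assignment for repeat `r` uses
#' seed `seed + r`, so any two configurations evaluated with the same base
#' seed share identical splits and can be compared fold-by-fold.
#'
#' @param dataset a [multimodal_dataset()]; every class must have at least
#'   `folds` members.
#' @param Z KNN neighbour count(s) per modality.
#' @param folds number of folds (default 10).
#' @param repeats number of repetitions (default 10).
#' @param seed base seed.
#' @param ... further arguments to [hgcn()] (e.g. `propagation`, `gate`,
#'   `epochs`).
#' @return An object of class `"hgcn_cv"`: per-fold `accuracy` and
#'   `macro_f1` vectors (length `folds * repeats`, repeat-major order),
#'   their means and standard deviations, a `predictions` matrix
#'   (`repeats x n`, each node predicted once per repeat), the `config`
#'   snapshot and the seed.
#' @export
cross_validate <- function(dataset, Z = 5, folds = 10, repeats = 10,
                           seed = 1, ...) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  if (folds < 2) stopf("folds must be >= 2")
  if (repeats < 1) stopf("repeats must be >= 1")
  labels <- dataset$labels
  if (anyNA(labels)) stopf("cross-validation requires fully labeled data")
  counts <- table(labels)
  if (any(counts < folds)) {
    stopf("smallest class has %d members; needs >= %d folds",
          min(counts), folds)
  }
  n <- length(labels)
  acc <- f1 <- numeric(folds * repeats)
  predictions <- matrix(NA_integer_, repeats, n,
                        dimnames = list(NULL, dataset$node_ids))

  for (r in seq_len(repeats) - 1L) {
    fold_of <- stratified_folds(labels, folds, seed + r)
    for (f in seq_len(folds) - 1L) {
      test_idx <- which(fold_of == f + 1L)
      split <- rep("train", n)
      split[test_idx] <- "test"
      ds <- multimodal_dataset(dataset$tables, labels, split)
      fit <- hgcn(ds, Z = Z, seed = seed + r * folds + f, ...)
      pred <- predict(fit, subset = "test")
      k <- r * folds + f + 1L
      acc[k] <- accuracy(labels[test_idx], pred)
      f1[k] <- macro_f1(labels[test_idx], pred)
      predictions[r + 1L, test_idx] <- pred
    }
  }

  structure(
    list(accuracy = acc, macro_f1 = f1,
         mean_accuracy = mean(acc), sd_accuracy = sd(acc),
         mean_macro_f1 = mean(f1), sd_macro_f1 = sd(f1),
         predictions = predictions, labels = labels,
         folds = folds, repeats = repeats, seed = seed,
         config = list(Z = Z, ...)),
    class = "hgcn_cv"
  )
}

# Stratified fold assignment: within each class, members are shuffled under
# `seed` and dealt out evenly, with each class's remainder members going to
# the currently least-loaded folds. Per-fold class proportions stay within
# one subject of the global proportions and total fold sizes differ by at
# most one.
stratified_folds <- function(labels, folds, seed) {
  fold_of <- integer(length(labels))
  load <- integer(folds)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      members <- which(labels == cl)
      members <- members[sample.int(length(members))]
      m <- length(members)
      cnt <- rep(m %/% folds, folds)
      r <- m %% folds
      if (r > 0) {
        extra <- order(load, seq_len(folds))[seq_len(r)]
        cnt[extra] <- cnt[extra] + 1
      }
      fold_of[members] <- rep(seq_len(folds), cnt)
      load <- load + cnt
    }
  })
  fold_of
}

#' @export
print.hgcn_cv <- function(x, ...) {
  cat(sprintf("%d x %d-fold cross-validation (seed %d)\n", x$repeats,
              x$folds, x$seed))
  cat(sprintf("  accuracy: %.4f +/- %.4f\n", x$mean_accuracy,
              x$sd_accuracy))
  cat(sprintf("  macro-F1: %.4f +/- %.4f\n", x$mean_macro_f1,
              x$sd_macro_f1))
  invisible(x)
}

subset_modalities <- function(dataset, keep) {
  multimodal_dataset(dataset$tables[keep], dataset$labels, dataset$split)
}

#' Leave-one-modality-out ablation
#'
#' Runs one full [cross_validate()] with all modalities and one with each
#' modality excluded, all under the same base seed (hence identical fold
#' splits), then reports per-fold paired accuracy deltas with raw and
#' Holm-adjusted paired t-test p-values.
#'
#' @param dataset a [multimodal_dataset()] with at least two modalities.
#' @param Z neighbour count(s), recycled over modalities.
#' @inheritParams cross_validate
#' @return An object of class `"hgcn_ablation"`: `full` (an `"hgcn_cv"`),
#'   `without` (named list of `"hgcn_cv"`), `mean_drop`, `p_raw`, `p_holm`.
#' @export
ablate_modalities <- function(dataset, Z = 5, folds = 10, repeats = 10,
                              seed = 1, ...) {
  W <- length(dataset$tables)
  if (W < 2) stopf("modality ablation needs >= 2 modalities")
  Z <- rep_len(Z, W)
  full <- cross_validate(dataset, Z = Z, folds = folds, repeats = repeats,
                         seed = seed, ...)
  without <- vector("list", W)
  names(without) <- names(dataset$tables)
  for (w in seq_len(W)) {
    ds <- subset_modalities(dataset, setdiff(seq_len(W), w))
    without[[w]] <- cross_validate(ds, Z = Z[-w], folds = folds,
                                   repeats = repeats, seed = seed, ...)
  }
  mean_drop <- vapply(without, function(cv) {
    full$mean_accuracy - cv$mean_accuracy
  }, numeric(1))
  p_raw <- vapply(without, function(cv) {
    paired_t_test(full$accuracy, cv$accuracy)$p
  }, numeric(1))
  structure(
    list(full = full, without = without, mean_drop = mean_drop,
         p_raw = p_raw, p_holm = stats::p.adjust(p_raw, "holm")),
    class = "hgcn_ablation"
  )
}

#' @export
print.hgcn_ablation <- function(x, ...) {
  cat(sprintf("Modality ablation: full-model accuracy %.4f\n",
              x$full$mean_accuracy))
  for (nm in names(x$without)) {
    cat(sprintf("  without %-14s %.4f (drop %+0.4f, p = %.3g, Holm %.3g)\n",
                nm, x$without[[nm]]$mean_accuracy, -x$mean_drop[[nm]],
                x$p_raw[[nm]], x$p_holm[[nm]]))
  }
  invisible(x)
}

#' Adaptive vs static gate ablation
#'
#' Compares the learnable per-node retention gate against a fixed uniform
#' gate of 0.5 under identical seeds and fold splits; the static run's gate
#' vector is excluded from the optimizer. Reports per-fold paired deltas
#' and a paired t-test.
#'
#' @inheritParams cross_validate
#' @return An object of class `"hgcn_gate_ablation"`: `adaptive`, `static`
#'   (both `"hgcn_cv"`), `delta` (per-fold accuracy differences), `t_test`.
#' @export
ablate_static_weighting <- function(dataset, Z = 5, folds = 10,
                                    repeats = 10, seed = 1, ...) {
  adaptive <- cross_validate(dataset, Z = Z, folds = folds,
                             repeats = repeats, seed = seed,
                             gate = "adaptive", ...)
  static <- cross_validate(dataset, Z = Z, folds = folds,
                           repeats = repeats, seed = seed,
                           gate = "static", ...)
  structure(
    list(adaptive = adaptive, static = static,
         delta = adaptive$accuracy - static$accuracy,
         t_test = paired_t_test(adaptive$accuracy, static$accuracy)),
    class = "hgcn_gate_ablation"
  )
}

#' @export
print.hgcn_gate_ablation <- function(x, ...) {
  cat(sprintf("Gate ablation: adaptive %.4f vs static %.4f (p = %.3g)\n",
              x$adaptive$mean_accuracy, x$static$mean_accuracy,
              x$t_test$p))
  invisible(x)
}

#' Grid search over the hyperedge-size parameter Z
#'
#' Runs one [cross_validate()] per candidate `Z` under a shared base seed
#' (identical fold splits across rows) and tabulates mean accuracy against
#' `Z` — the accuracy-versus-hyperedge-size curve used to pick the KNN
#' neighbour count.
#'
#' @param Z_values integer vector of candidate neighbour counts, all
#'   `< |Q|`.
#' @inheritParams cross_validate
#' @return Data frame with columns `Z`, `mean_accuracy`, `sd_accuracy`,
#'   `mean_macro_f1`.
#' @export
grid_search_Z <- function(dataset, Z_values, folds = 10, repeats = 10,
                          seed = 1, ...) {
  n <- length(dataset$node_ids)
  if (any(Z_values >= n)) stopf("all Z must be < |Q| (= %d)", n)
  rows <- lapply(Z_values, function(z) {
    cv <- cross_validate(dataset, Z = z, folds = folds, repeats = repeats,
                         seed = seed, ...)
    data.frame(Z = z, mean_accuracy = cv$mean_accuracy,
               sd_accuracy = cv$sd_accuracy,
               mean_macro_f1 = cv$mean_macro_f1)
  })
  do.call(rbind, rows)
}

#' Clique-expansion GCN baseline
#'
#' Cross-validates the identical decoupled model head on the clique
#' expansion of the fused hypergraph, using the symmetric degree-normalized
#' adjacency with self-loops as the aggregator — the standard graph
#' convolutional comparison. Fold splits and seeds match
#' [cross_validate()]'s under the same base seed.
#'
#' @inheritParams cross_validate
#' @return An `"hgcn_cv"` report.
#' @export
run_baseline_gcn <- function(dataset, Z = 5, folds = 10, repeats = 10,
                             seed = 1, ...) {
  cross_validate(dataset, Z = Z, folds = folds, repeats = repeats,
                 seed = seed, propagation = "gcn_clique", ...)
}

#' Serialize an evaluation report
#'
#' Writes any of the report objects produced by this module as pretty JSON
#' (and, for `"hgcn_cv"`, optionally a flat per-fold CSV). Serialization is
#' deterministic: identical reports produce byte-identical files.
#'
#' @param report an `"hgcn_cv"`, `"hgcn_ablation"` or
#'   `"hgcn_gate_ablation"` object, or a plain list.
#' @param path output JSON path.
#' @param csv_path optional CSV path for per-fold metrics.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv_path = NULL) {
  jsonlite::write_json(unclass_report(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(csv_path) && inherits(report, "hgcn_cv")) {
    df <- data.frame(fold = seq_along(report$accuracy),
                     accuracy = report$accuracy,
                     macro_f1 = report$macro_f1)
    write.table(df, csv_path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

unclass_report <- function(x) {
  if (is.list(x)) {
    x <- lapply(unclass(x), unclass_report)
  }
  x
}
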
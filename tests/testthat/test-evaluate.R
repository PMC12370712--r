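# Evaluation harness tests run with shortened training (small epochs) so the
# protocol properties — stratification, pairing, reproducibility — are
# exercised quickly; full-length training is covered by test-acceptance.R.

test_that("fold assignment is stratified and partitions all nodes", {
  set.seed(91)
  for (i in 1:20) {
    n <- sample(30:60, 1)
    labels <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    while (min(table(labels)) < 5) {
      labels <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    }
    fold_of <- hypergcn:::stratified_folds(labels, 5, seed = i)
    expect_true(all(fold_of %in% 1:5))
    for (cl in 0:2) {
      per_fold <- table(factor(fold_of[labels == cl], levels = 1:5))
      expect_lte(max(per_fold) - min(per_fold), 1)
    }
  }
})

test_that("303 subjects split into 10 folds of size 30 or 31", {
  labels <- rep(0:1, c(165, 138))
  fold_of <- hypergcn:::stratified_folds(labels, 10, seed = 1)
  sizes <- as.integer(table(fold_of))
  expect_equal(sum(sizes), 303)
  expect_true(all(sizes %in% c(30, 31)))
  # the paper-style 80/20 single split of 303 gives 242 train / 61 test
  expect_equal(303 - round(0.2 * 303), 242)
  expect_equal(round(0.2 * 303), 61)
})

test_that("cross-validation reports are complete and reproducible", {
  sim <- tiny_cohort(n = 30, effect = 6, seed = 17)
  cv <- cross_validate(sim$dataset, Z = 3, folds = 5, repeats = 2,
                       seed = 7, epochs = 60)
  expect_length(cv$accuracy, 10)
  expect_length(cv$macro_f1, 10)
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))
  expect_false(anyNA(cv$predictions))   # every node predicted every repeat

  cv2 <- cross_validate(sim$dataset, Z = 3, folds = 5, repeats = 2,
                        seed = 7, epochs = 60)
  expect_identical(cv$accuracy, cv2$accuracy)
  expect_identical(cv$predictions, cv2$predictions)

  expect_error(cross_validate(sim$dataset, folds = 20, repeats = 1),
               "class")

  # strong separation: near-perfect mean accuracy
  sim2 <- simulate_cohort(cohort_spec(n_subjects = 40, effect_size = 10,
                                      seed = 19))
  cv3 <- cross_validate(sim2$dataset, Z = 4, folds = 5, repeats = 1,
                        seed = 1, epochs = 150)
  expect_gte(cv3$mean_accuracy, 0.95)
})

test_that("modality ablation produces one report per left-out modality", {
  spec <- cohort_spec(n_subjects = 36,
                      modality_dims = c(physiological = 5, behavioral = 4,
                                        environmental = 3),
                      effect_size = c(4, 0, 0), seed = 23)
  sim <- simulate_cohort(spec)
  ab <- ablate_modalities(sim$dataset, Z = 4, folds = 4, repeats = 1,
                          seed = 3, epochs = 80)
  expect_length(ab$without, 3)          # full + 3 leave-one-out reports
  expect_named(ab$without, c("physiological", "behavioral", "environmental"))
  expect_length(ab$p_raw, 3)
  expect_length(ab$p_holm, 3)
  expect_true(all(ab$p_holm >= ab$p_raw - 1e-15))
  # only physiological is informative: dropping it hurts most
  expect_equal(names(which.max(ab$mean_drop)), "physiological")

  one <- multimodal_dataset(sim$dataset$tables[1], sim$dataset$labels,
                            sim$dataset$split)
  expect_error(ablate_modalities(one), ">= 2 modalities")
})

test_that("gate ablation pairs identical folds and tests the deltas", {
  sim <- tiny_cohort(n = 30, effect = 3, seed = 29)
  ab <- ablate_static_weighting(sim$dataset, Z = 3, folds = 5, repeats = 1,
                                seed = 11, epochs = 60)
  expect_length(ab$delta, 5)
  expect_true(all(c("t", "df", "p") %in% names(ab$t_test)))
  # shared seeds imply identical fold splits: per-fold metric vectors align
  expect_identical(ab$adaptive$seed, ab$static$seed)
  expect_equal(ab$delta, ab$adaptive$accuracy - ab$static$accuracy)
})

test_that("Z grid search emits one row per candidate with shared splits", {
  sim <- tiny_cohort(n = 30, effect = 6, seed = 31)
  grid <- grid_search_Z(sim$dataset, c(2, 4, 6), folds = 5, repeats = 1,
                        seed = 13, epochs = 60)
  expect_equal(nrow(grid), 3)
  expect_equal(grid$Z, c(2, 4, 6))
  expect_true(all(grid$mean_accuracy >= 0 & grid$mean_accuracy <= 1))
  expect_error(grid_search_Z(sim$dataset, c(2, 40), folds = 5),
               "Z must be")
})

test_that("the GCN baseline runs the same protocol on the clique expansion", {
  sim <- tiny_cohort(n = 30, effect = 6, seed = 37)
  gcn <- run_baseline_gcn(sim$dataset, Z = 3, folds = 5, repeats = 1,
                          seed = 17, epochs = 60)
  hg <- cross_validate(sim$dataset, Z = 3, folds = 5, repeats = 1,
                       seed = 17, epochs = 60)
  expect_s3_class(gcn, "hgcn_cv")
  expect_length(gcn$accuracy, length(hg$accuracy))
  expect_identical(gcn$seed, hg$seed)

  # on a pairwise-only hypergraph the two aggregators agree up to the
  # self-loop normalization convention: compare them algebraically
  h <- hypergraph(list(c("a", "b"), c("b", "c"), c("a", "c")),
                  node_ids = c("a", "b", "c"))
  G_h <- spectral_operator(h)$matrix
  G_gcn <- hypergcn:::build_operator(h, "gcn_clique")$matrix
  expect_equal(dim(G_h), dim(G_gcn))
  expect_true(all((G_h > 1e-12) == (G_gcn > 1e-12)))
})

test_that("report serialization is deterministic", {
  sim <- tiny_cohort(n = 24, effect = 6, seed = 41)
  cv <- cross_validate(sim$dataset, Z = 3, folds = 4, repeats = 1,
                       seed = 19, epochs = 40)
  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  on.exit(unlink(c(p1, p2)), add = TRUE)
  write_report(cv, p1, csv_path = sub("json$", "csv", p1))
  write_report(cv, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_true(file.exists(sub("json$", "csv", p1)))
})
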
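test_that("adaptive combination gates the raw features per node", {
  set.seed(71)
  h <- random_hypergraph()
  op <- spectral_operator(h)
  X0 <- matrix(rnorm(h$n_nodes * 3), ncol = 3)

  # zero gate parameter: sigmoid(0) = 0.5 blend
  expect_equal(adaptive_combine(op, X0, 2, rep(0, h$n_nodes)),
               propagate(op, X0, 2) + 0.5 * X0)

  # gate -> 0 with L = 0 recovers the propagated-only limit, here X0 itself
  expect_equal(adaptive_combine(op, X0, 0, rep(-1e3, h$n_nodes)),
               X0 + sigmoid(-1e3) * X0, tolerance = 1e-12)

  # elementwise oracle on a random instance
  R <- rnorm(h$n_nodes)
  out <- adaptive_combine(op, X0, 2, R)
  GL <- op$matrix %*% (op$matrix %*% X0)
  for (x in seq_len(h$n_nodes)) {
    expect_equal(out[x, ], GL[x, ] + sigmoid(R[x]) * X0[x, ])
  }

  # gate monotonicity: larger R retains strictly more of the raw feature
  gates <- sigmoid(c(-1, 0, 1, 2))
  expect_true(all(diff(gates) > 0))

  expect_error(adaptive_combine(op, X0, 2, rep(0, h$n_nodes + 1)), "length")
})

test_that("training separates well-separated classes and is reproducible", {
  sim <- tiny_cohort(n = 30, effect = 8, seed = 11)
  fit <- hgcn(sim$dataset, Z = 3, epochs = 200, seed = 0)

  expect_equal(fit$history$train_accuracy, 1.0)
  expect_true(all(is.finite(fit$history$loss)))
  expect_length(fit$history$loss, 200)
  expect_equal(ncol(fit$scores), 3)                  # C columns
  expect_true(all(sigmoid(fit$parameters$R) > 0 &
                  sigmoid(fit$parameters$R) < 1))

  fit2 <- hgcn(sim$dataset, Z = 3, epochs = 200, seed = 0)
  expect_identical(fit$history$loss, fit2$history$loss)
  expect_identical(fit$parameters, fit2$parameters)

  # single-class training split is rejected
  ds <- sim$dataset
  one_class <- multimodal_dataset(ds$tables, rep(0L, length(ds$labels)),
                                  ds$split)
  expect_error(hgcn(one_class, Z = 3, epochs = 5), "two classes")
})

test_that("duplicate nodes score identically iff their gates are tied", {
  # two nodes with identical features and identical hyperedges are
  # indistinguishable to propagation; only the adaptive gate can separate
  # their representations
  ids <- c("a", "b", "c", "d")
  h <- hypergraph(list(c("a", "b", "c"), c("a", "b", "d"), c("c", "d")),
                  node_ids = ids)
  op <- spectral_operator(h)
  X0 <- rbind(c(1, 2), c(1, 2), c(0, 1), c(3, 0))

  tied <- adaptive_combine(op, X0, 2, c(0.4, 0.4, 0, 0))
  expect_equal(tied[1, ], tied[2, ])
  untied <- adaptive_combine(op, X0, 2, c(-2, 2, 0, 0))
  expect_gt(max(abs(untied[1, ] - untied[2, ])), 1e-6)
  # and any downstream linear head preserves that (in)equality
  W <- matrix(rnorm(6), 2, 3)
  expect_equal((tied %*% W)[1, ], (tied %*% W)[2, ])
})

test_that("prediction takes the argmax with ties to the lowest class", {
  sim <- tiny_cohort(n = 20, effect = 8, seed = 4)
  fit <- hgcn(sim$dataset, Z = 3, epochs = 50, seed = 1)

  expect_length(predict(fit, subset = "test"),
                sum(sim$dataset$split == "test"))

  # manipulate the stored scores to exercise the tie rule
  fit$scores[1, ] <- c(0.2, 0.7, 0.1)
  fit$scores[2, ] <- c(0.5, 0.5, 0.1)
  pred <- predict(fit, subset = fit$node_ids[1:2])
  expect_equal(unname(pred), c(1L, 0L))

  expect_error(predict(fit, subset = "nope"), "unknown node")

  # evaluation-mode forward is deterministic; training mode is seedable
  expect_identical(hgcn_forward(fit), hgcn_forward(fit))
  expect_identical(hgcn_forward(fit, training = TRUE, seed = 3),
                   hgcn_forward(fit, training = TRUE, seed = 3))
})

test_that("static gating excludes the gate vector from optimization", {
  sim <- tiny_cohort(n = 20, effect = 6, seed = 8)
  fit <- hgcn(sim$dataset, Z = 3, epochs = 30, seed = 2, gate = "static")
  expect_equal(fit$parameters$R, rep(0, 20))    # untouched initialization
  adaptive <- hgcn(sim$dataset, Z = 3, epochs = 30, seed = 2)
  expect_gt(max(abs(adaptive$parameters$R)), 0)
})

test_that("checkpoints round-trip through JSON", {
  sim <- tiny_cohort(n = 20, effect = 6, seed = 13)
  fit <- hgcn(sim$dataset, Z = 3, epochs = 40, seed = 5)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_hgcn(fit, path)
  fit2 <- read_hgcn(path, sim$dataset)
  expect_equal(fit2$parameters$R, fit$parameters$R)
  expect_equal(fit2$parameters$theta1, fit$parameters$theta1,
               ignore_attr = TRUE)
  expect_equal(unname(fit2$scores), unname(fit$scores), tolerance = 1e-12)
  expect_identical(predict(fit2, "test"), predict(fit, "test"))
})

test_that("informative modalities help test accuracy directionally", {
  # only the first modality carries class signal; including it must beat
  # excluding it (the generator's ground-truth ordering)
  accs_with <- accs_without <- numeric(6)
  for (s in 1:6) {
    spec <- cohort_spec(n_subjects = 45,
                        modality_dims = c(physiological = 6, behavioral = 6),
                        effect_size = c(5, 0), seed = 100 + s)
    sim <- simulate_cohort(spec)
    test_mask <- sim$dataset$split == "test"
    truth <- sim$dataset$labels[test_mask]
    fit_full <- hgcn(sim$dataset, Z = 4, epochs = 150, seed = s)
    ds_noise <- multimodal_dataset(sim$dataset$tables[2],
                                   sim$dataset$labels, sim$dataset$split)
    fit_noise <- hgcn(ds_noise, Z = 4, epochs = 150, seed = s)
    accs_with[s] <- accuracy(truth, predict(fit_full, "test"))
    accs_without[s] <- accuracy(truth, predict(fit_noise, "test"))
  }
  expect_gt(mean(accs_with), mean(accs_without))
})
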
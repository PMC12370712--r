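# Fixture builders shared across the test files. Everything is generated in
# code under explicit seeds; no data files.

# A random small hypergraph with no isolated nodes. When `connected = TRUE`
# a chain of 2-node hyperedges is appended so the clique expansion is
# connected.
random_hypergraph <- function(n_max = 12, m_max = 12, connected = FALSE,
                              weights = FALSE) {
  n <- sample(3:n_max, 1)
  m <- sample(2:m_max, 1)
  members <- lapply(seq_len(m), function(i) {
    as.character(sample(n, sample(2:min(n, 4), 1)))
  })
  missing <- setdiff(as.character(seq_len(n)), unlist(members))
  if (length(missing)) {
    members <- c(members, lapply(missing, function(id) {
      c(id, as.character(sample(setdiff(seq_len(n), as.integer(id)), 1)))
    }))
  }
  if (connected) {
    members <- c(members, lapply(seq_len(n - 1), function(i) {
      as.character(c(i, i + 1))
    }))
  }
  w <- if (weights) sample(1:3, length(members), replace = TRUE) else NULL
  hypergraph(members, as.character(seq_len(n)), edge_weights = w)
}

# Small Gaussian two-cluster modality table for KNN tests.
random_table <- function(n = 10, d = 2, name = "other") {
  modality_table(name, sprintf("s%02d", seq_len(n)),
                 matrix(rnorm(n * d), n, d))
}

# Tiny well-separated cohort for fast model tests.
tiny_cohort <- function(n = 30, effect = 6, seed = 11, dims = c(3, 2)) {
  spec <- cohort_spec(n_subjects = n,
                      modality_dims = c(physiological = dims[1],
                                        behavioral = dims[2]),
                      effect_size = effect, seed = seed)
  simulate_cohort(spec)
}

# Brute-force nearest-class-mean classifier (independent oracle for the
# Gaussian generator's separability).
nearest_mean_oracle <- function(dataset, truth) {
  X <- do.call(cbind, lapply(dataset$tables, function(tb) tb$features))
  mu <- do.call(cbind, truth$class_means)   # C x total width
  apply(X, 1, function(x) {
    which.min(colSums((t(mu) - x)^2)) - 1L
  })
}
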
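test_that("incidence matrix follows the membership definition", {
  h <- hypergraph(list(c("a", "b"), c("b", "c")), node_ids = c("a", "b", "c"))
  expect_equal(unname(h$incidence), rbind(c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(h$edge_weights, c(1, 1))   # weights default to unit

  single <- hypergraph(list("a"), node_ids = "a")
  expect_equal(unname(single$incidence), matrix(1))
  expect_equal(hg_degrees(single)$node_degrees, 1)
  expect_equal(hg_degrees(single)$edge_degrees, c(e1 = 1))

  dup <- hypergraph(list(c("a", "b"), c("a", "b")), node_ids = c("a", "b"))
  expect_equal(dup$incidence[, 1], dup$incidence[, 2])
  expect_equal(hg_degrees(dup)$node_degrees, c(2, 2))

  expect_error(hypergraph(list(c("a", "zz")), node_ids = c("a", "b")),
               "unknown node")
  expect_error(hypergraph(list(character(0)), node_ids = "a"), "empty")
  expect_error(hypergraph(list("a"), node_ids = c("a", "a")), "duplicate")
})

test_that("degrees are the exact weighted incidence sums", {
  h <- hypergraph(list(c("a", "b"), c("b", "c")), node_ids = c("a", "b", "c"))
  d <- hg_degrees(h)
  expect_identical(d$node_degrees, c(1, 2, 1))
  expect_identical(unname(d$edge_degrees), c(2, 2))

  hw <- hypergraph(list(c("a", "b")), node_ids = c("a", "b"),
                   edge_weights = 3)
  expect_identical(hg_degrees(hw)$node_degrees, c(3, 3))
  expect_identical(unname(hg_degrees(hw)$edge_degrees), 2)
})

test_that("degree identities hold exactly on random hypergraphs", {
  set.seed(101)
  for (i in 1:200) {
    h <- random_hypergraph(weights = (i %% 2 == 0))
    d <- hg_degrees(h)
    expect_identical(d$node_degrees,
                     as.numeric(h$incidence %*% h$edge_weights))
    expect_identical(unname(d$edge_degrees), unname(colSums(h$incidence)))
    if (all(h$edge_weights == 1)) {
      # both sides count total incidences
      expect_equal(sum(d$node_degrees), sum(d$edge_degrees))
    }
  }
})

test_that("laplacian is symmetric PSD with null eigenvalue", {
  h2 <- hypergraph(list(c("a", "b")), node_ids = c("a", "b"))
  expect_equal(hg_laplacian(h2),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2,
                      dimnames = list(c("a", "b"), c("a", "b"))))

  set.seed(7)
  for (i in 1:50) {
    h <- random_hypergraph(weights = (i %% 2 == 0))
    L <- hg_laplacian(h)
    expect_lt(max(abs(L - t(L))), 1e-12)
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    expect_lt(abs(min(ev)), 1e-8)         # smallest eigenvalue is 0
    # the null direction is Dq^{1/2} 1
    dq <- sqrt(hg_degrees(h)$node_degrees)
    expect_lt(max(abs(L %*% dq)), 1e-8)
  }

  iso <- hypergraph(list("a"), node_ids = c("a", "b"))
  expect_error(hg_laplacian(iso), "isolated")
})

test_that("disconnected hypergraphs have null multiplicity >= components", {
  set.seed(13)
  for (i in 1:20) {
    h1 <- random_hypergraph(n_max = 6, m_max = 5)
    h2 <- random_hypergraph(n_max = 6, m_max = 5)
    ids2 <- paste0("b", h2$node_ids)
    members <- c(
      apply(h1$incidence, 2, function(cl) h1$node_ids[cl == 1],
            simplify = FALSE),
      apply(h2$incidence, 2, function(cl) ids2[cl == 1], simplify = FALSE)
    )
    h <- hypergraph(members, c(h1$node_ids, ids2))
    ev <- eigen(hg_laplacian(h), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(sum(abs(ev) < 1e-8), 2)
  }
})

test_that("clique expansion connects all pairs within a hyperedge", {
  tri <- clique_expand(hypergraph(list(c("a", "b", "c")),
                                  node_ids = c("a", "b", "c")))
  expect_equal(sum(tri$adjacency) / 2, 3)
  expect_equal(unname(diag(tri$adjacency)), c(0, 0, 0))

  # pairwise hyperedges reduce to the ordinary graph
  h <- hypergraph(list(c("a", "b"), c("c", "d")),
                  node_ids = c("a", "b", "c", "d"))
  g <- clique_expand(h)
  expect_equal(g$adjacency["a", "b"], 1)
  expect_equal(g$adjacency["a", "c"], 0)

  # k-node hyperedge: k(k-1)/2 edges, brute-force pair enumeration
  for (k in 3:6) {
    ids <- letters[seq_len(k)]
    g <- clique_expand(hypergraph(list(ids), node_ids = ids))
    pairs <- 0
    for (x in seq_len(k)) for (v in seq_len(k)) {
      if (x < v) pairs <- pairs + g$adjacency[x, v]
    }
    expect_equal(pairs, k * (k - 1) / 2)
  }
})

test_that("pairwise-hypergraph expansion matches the B B' oracle", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    members <- lapply(1:8, function(j) as.character(sample(n, 2)))
    members <- c(members, lapply(seq_len(n - 1), function(i) {
      as.character(c(i, i + 1))
    }))
    h <- hypergraph(members, as.character(seq_len(n)))
    A_oracle <- h$incidence %*% t(h$incidence)
    diag(A_oracle) <- 0
    A_oracle <- (A_oracle >= 1) * 1
    expect_equal(clique_expand(h)$adjacency, A_oracle)
    # idempotence under re-expansion of the 2-node encoding
    edges <- which(upper.tri(A_oracle) & A_oracle == 1, arr.ind = TRUE)
    members2 <- lapply(seq_len(nrow(edges)), function(r) {
      h$node_ids[c(edges[r, 1], edges[r, 2])]
    })
    h2 <- hypergraph(members2, h$node_ids)
    expect_equal(clique_expand(h2)$adjacency, A_oracle)
  }
})

test_that("hyperedge-list files round-trip", {
  h <- hypergraph(list(c("a", "b"), c("b", "c")), node_ids = c("a", "b", "c"),
                  edge_weights = c(1, 2.5))
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path), add = TRUE)
  write_hypergraph(h, path)
  h2 <- read_hypergraph(path)
  expect_equal(h2$incidence, h$incidence)
  expect_equal(h2$edge_weights, h$edge_weights)
  expect_identical(h2$node_ids, h$node_ids)

  # weightless edges default to 1; undeclared members are parse errors
  path2 <- tempfile(fileext = ".txt")
  on.exit(unlink(path2), add = TRUE)
  writeLines(c("#nodes: a b", "# a comment", "e1\t1\ta,b"), path2)
  expect_equal(read_hypergraph(path2)$edge_weights, 1)
  writeLines(c("#nodes: a b", "e1\t1\ta,zz"), path2)
  expect_error(read_hypergraph(path2), "not declared")
  writeLines(c("#nodes: a b", "e1 1 a"), path2)
  expect_error(read_hypergraph(path2), "field")
})
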
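#' Propagation operators for hypergraph convolution
#'
#' Both hypergraph convolution variants reduce to a dense linear node
#' aggregator `G` applied to the node-feature matrix:
#'
#' * spectral: `G = Dq^{-1/2} B M De^{-1} B' Dq^{-1/2}`, the symmetric
#'   positive-semidefinite operator obtained from the first-order Chebyshev
#'   truncation of spectral filtering on the hypergraph Laplacian; it
#'   satisfies `G = I - L` and filters a signal with frequency response
#'   `1 - lambda`.
#' * spatial: `G = Dq^{-1} B M De^{-1} B'`, the explicit
#'   node-to-hyperedge-to-node averaging; it is row-stochastic, so each
#'   output coordinate is a convex combination of input coordinates and
#'   constant signals are preserved exactly.
#'
#' @param h a [hypergraph()]; every node must belong to at least one
#'   hyperedge.
#' @return An object of class `"hg_operator"`: list with `kind`
#'   (`"spectral"` or `"spatial"`), the dense `matrix` `G`, and `node_ids`.
#' @examples
#' h <- hypergraph(list(c("a", "b")), node_ids = c("a", "b"))
#' spectral_operator(h)$matrix   # all entries 0.5
#' spatial_operator(h)$matrix    # row-stochastic
#' @export
spectral_operator <- function(h) {
  stopifnot(inherits(h, "hypergraph"))
  check_no_isolated(h)
  deg <- hg_degrees(h)
  B <- h$incidence
  dq_is <- 1 / sqrt(deg$node_degrees)
  # Dq^{-1/2} B M De^{-1} B' Dq^{-1/2} via column/row scaling
  BW <- sweep(B, 2, h$edge_weights / deg$edge_degrees, `*`)
  G <- (dq_is * BW) %*% t(B) * rep(dq_is, each = h$n_nodes)
  G <- (G + t(G)) / 2
  new_operator("spectral", G, h$node_ids)
}

#' @rdname spectral_operator
#' @export
spatial_operator <- function(h) {
  stopifnot(inherits(h, "hypergraph"))
  check_no_isolated(h)
  deg <- hg_degrees(h)
  B <- h$incidence
  BW <- sweep(B, 2, h$edge_weights / deg$edge_degrees, `*`)
  G <- (BW %*% t(B)) / deg$node_degrees
  new_operator("spatial", G, h$node_ids)
}

new_operator <- function(kind, G, node_ids) {
  dimnames(G) <- list(node_ids, node_ids)
  structure(list(kind = kind, matrix = G, node_ids = node_ids),
            class = "hg_operator")
}

#' @export
print.hg_operator <- function(x, ...) {
  cat(sprintf("Hypergraph propagation operator (%s), %d x %d\n",
              x$kind, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' One explicit message-passing step
#'
#' Spells out spatial hypergraph convolution as its three constituent steps
#' rather than as a matrix product: (1) each hyperedge averages the features
#' of its member nodes (divide by the edge degree `d(e)`); (2) each node sums
#' its incident hyperedges' features scaled by the hyperedge weights `m(e)`;
#' (3) the sum is divided by the node's weighted degree `d(q_x)` and
#' multiplied by the transformation matrix `theta`. With unit weights the
#' weighted degree equals the incident-edge count `|E(q_x)|`, so the two
#' normalization readings coincide; the weighted degree is used so that the
#' loop form agrees with the spatial operator matrix for any weights.
#'
#' @param h a [hypergraph()].
#' @param features numeric matrix with one row per node.
#' @param theta optional transformation matrix (default: identity).
#' @return The updated feature matrix, equal to
#'   `spatial_operator(h)$matrix %*% features %*% theta` up to rounding.
#' @export
message_passing_step <- function(h, features, theta = NULL) {
  stopifnot(inherits(h, "hypergraph"))
  features <- as.matrix(features)
  if (nrow(features) != h$n_nodes) {
    stopf("features has %d rows but the hypergraph has %d nodes",
          nrow(features), h$n_nodes)
  }
  check_no_isolated(h)
  deg <- hg_degrees(h)
  B <- h$incidence
  d <- ncol(features)
  edge_feat <- matrix(0, h$n_edges, d)
  for (y in seq_len(h$n_edges)) {               # node -> hyperedge average
    members <- which(B[, y] == 1)
    edge_feat[y, ] <- colSums(features[members, , drop = FALSE]) /
      deg$edge_degrees[y]
  }
  out <- matrix(0, h$n_nodes, d, dimnames = dimnames(features))
  for (x in seq_len(h$n_nodes)) {               # hyperedge -> node update
    incident <- which(B[x, ] == 1)
    acc <- rep(0, d)
    for (y in incident) {
      acc <- acc + h$edge_weights[y] * edge_feat[y, ]
    }
    out[x, ] <- acc / deg$node_degrees[x]
  }
  if (!is.null(theta)) out <- out %*% theta
  out
}

#' Single hypergraph convolution layer
#'
#' Computes `sigma(G X Theta)` with dropout applied to the input features
#' during training only; evaluation mode is deterministic. This is the
#' classical coupled layer; the decoupled model in [hgcn()] separates
#' propagation ([propagate()]) from transformation instead.
#'
#' @param op an `"hg_operator"` from [spectral_operator()] or
#'   [spatial_operator()].
#' @param features numeric node-feature matrix (`|Q| x d_in`).
#' @param theta weight matrix `d_in x d_out`.
#' @param activation nonlinearity applied elementwise (default [relu]).
#' @param dropout dropout probability on the input during training.
#' @param training logical; apply dropout?
#' @param seed RNG seed for the dropout mask (required for reproducibility
#'   when `training = TRUE` and `dropout > 0`).
#' @return `|Q| x d_out` feature matrix.
#' @export
hgcn_layer <- function(op, features, theta, activation = relu,
                       dropout = 0, training = FALSE, seed = NULL) {
  stopifnot(inherits(op, "hg_operator"))
  features <- as.matrix(features)
  if (ncol(features) != nrow(theta)) {
    stopf("feature width %d does not match theta input dimension %d",
          ncol(features), nrow(theta))
  }
  if (training && dropout > 0) {
    features <- with_seed(seed, apply_dropout(features, dropout))
  }
  activation(op$matrix %*% features %*% theta)
}

# Inverted dropout: zero with probability p, scale survivors by 1/(1-p).
apply_dropout <- function(x, p) {
  mask <- matrix(runif(length(x)) >= p, nrow(x), ncol(x))
  x * mask / (1 - p)
}

#' Decoupled feature propagation
#'
#' Applies the aggregator `L` times: `G^L X`, with no weights and no
#' nonlinearity. Separating propagation from transformation lets the
#' propagated features be precomputed once per hypergraph; it also exposes
#' the oversmoothing behaviour directly, since for a connected hypergraph
#' `G^L X` converges to a componentwise-constant matrix as `L` grows.
#'
#' @param op an `"hg_operator"`.
#' @param features numeric node-feature matrix.
#' @param L nonnegative integer layer count (`L = 0` returns `features`).
#' @return `|Q| x d` matrix `G^L %*% features`.
#' @export
propagate <- function(op, features, L) {
  stopifnot(inherits(op, "hg_operator"))
  if (length(L) != 1 || is.na(L) || L < 0 || L != round(L)) {
    stopf("L must be a single nonnegative integer")
  }
  out <- as.matrix(features)
  for (i in seq_len(L)) out <- op$matrix %*% out
  out
}
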
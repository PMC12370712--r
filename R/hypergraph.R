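#' Construct a hypergraph from hyperedge member lists
#'
#' A hypergraph generalizes a graph by letting each edge (a *hyperedge*) join
#' any number of nodes. It is stored as a binary incidence matrix `B` of
#' dimension `|Q| x |E|` (`B[x, y] = 1` iff node `x` belongs to hyperedge
#' `y`) together with a nonnegative weight per hyperedge (the diagonal of the
#' weight matrix `M`). Weights default to one and are never trained.
#'
#' Duplicate hyperedges are retained as separate columns: the KNN
#' construction can legitimately produce identical neighbourhoods for two
#' centroids, and node degrees then count that multiplicity.
#'
#' @param edge_members list of character vectors; each element names the
#'   nodes belonging to one hyperedge. Must be nonempty sets drawn from
#'   `node_ids`.
#' @param node_ids ordered character vector of unique node identifiers;
#'   fixes the row order of the incidence matrix.
#' @param edge_weights optional numeric vector of nonnegative hyperedge
#'   weights, recycled to all ones when omitted.
#' @param edge_ids optional character vector naming the hyperedges.
#' @return An object of class `"hypergraph"`: a list with elements
#'   `n_nodes`, `n_edges`, `incidence` (binary matrix), `edge_weights`
#'   and `node_ids`.
#' @examples
#' h <- hypergraph(list(c("a", "b"), c("b", "c")), node_ids = c("a", "b", "c"))
#' hg_degrees(h)
#' @export
hypergraph <- function(edge_members, node_ids, edge_weights = NULL,
                       edge_ids = NULL) {
  if (!length(edge_members)) stopf("hypergraph needs at least one hyperedge")
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stopf("duplicate node ids")
  n <- length(node_ids)
  m <- length(edge_members)
  if (is.null(edge_weights)) edge_weights <- rep(1, m)
  if (length(edge_weights) != m) stopf("edge_weights must have one entry per hyperedge")
  if (any(edge_weights < 0)) stopf("hyperedge weights must be nonnegative")
  if (is.null(edge_ids)) edge_ids <- paste0("e", seq_len(m))

  B <- matrix(0, n, m, dimnames = list(node_ids, edge_ids))
  for (y in seq_len(m)) {
    members <- unique(as.character(edge_members[[y]]))
    if (!length(members)) stopf("hyperedge %d is empty", y)
    idx <- match(members, node_ids)
    if (anyNA(idx)) {
      stopf("hyperedge %d references unknown node id(s): %s", y,
            paste(members[is.na(idx)], collapse = ", "))
    }
    B[idx, y] <- 1
  }

  structure(
    list(n_nodes = n, n_edges = m, incidence = B,
         edge_weights = as.numeric(edge_weights), node_ids = node_ids),
    class = "hypergraph"
  )
}

#' @export
print.hypergraph <- function(x, ...) {
  deg <- hg_degrees(x)
  cat(sprintf("Hypergraph: %d nodes, %d hyperedges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  edge sizes: %s\n",
              paste(range(deg$edge_degrees), collapse = "-")))
  cat(sprintf("  node degrees: %s (weighted)\n",
              paste(signif(range(deg$node_degrees), 4), collapse = "-")))
  invisible(x)
}

#' Node and hyperedge degrees
#'
#' The degree of node `q_x` is the weighted count of hyperedges containing
#' it, `d(q_x) = sum_y m(e_y) B[x, y]`; the degree of hyperedge `e_y` is the
#' number of nodes it contains, `d(e_y) = sum_x B[x, y]`. Both are exact for
#' integer weights.
#'
#' @param h a [hypergraph()].
#' @return A list with numeric vectors `node_degrees` (length `|Q|`) and
#'   `edge_degrees` (length `|E|`).
#' @export
hg_degrees <- function(h) {
  stopifnot(inherits(h, "hypergraph"))
  list(
    node_degrees = as.numeric(h$incidence %*% h$edge_weights),
    edge_degrees = colSums(h$incidence)
  )
}

# Error unless every node sits in at least one hyperedge (so that the node
# degree matrix is invertible).
check_no_isolated <- function(h) {
  deg <- hg_degrees(h)$node_degrees
  if (any(deg <= 0)) {
    stopf("isolated node(s) with zero degree: %s",
          paste(h$node_ids[deg <= 0], collapse = ", "))
  }
  invisible(deg)
}

#' Normalized hypergraph Laplacian
#'
#' Computes `L = I - Dq^{-1/2} B M De^{-1} B' Dq^{-1/2}` where `Dq` and `De`
#' are the diagonal node- and edge-degree matrices. `L` is symmetric positive
#' semidefinite with smallest eigenvalue 0; its eigenpairs define the Fourier
#' basis used by spectral hypergraph convolution.
#'
#' @param h a [hypergraph()] with no isolated nodes.
#' @return A symmetric `|Q| x |Q|` numeric matrix.
#' @export
hg_laplacian <- function(h) {
  G <- spectral_operator(h)$matrix
  L <- diag(nrow(G)) - G
  (L + t(L)) / 2
}

#' Clique expansion of a hypergraph
#'
#' Replaces every hyperedge by the complete set of pairwise edges among its
#' members, producing a simple undirected graph on the same node set. Node
#' features and labels are untouched; only the connectivity structure is
#' reduced. This is the standard bridge that lets an ordinary graph
#' convolutional network run on hypergraph-constructed data.
#'
#' @param h a [hypergraph()].
#' @return An object of class `"simple_graph"`: list with `n_nodes`,
#'   `adjacency` (symmetric binary matrix, zero diagonal) and `node_ids`.
#' @export
clique_expand <- function(h) {
  stopifnot(inherits(h, "hypergraph"))
  A <- h$incidence %*% t(h$incidence)
  A <- (A > 0) * 1
  diag(A) <- 0
  structure(
    list(n_nodes = h$n_nodes, adjacency = A, node_ids = h$node_ids),
    class = "simple_graph"
  )
}

#' @export
print.simple_graph <- function(x, ...) {
  cat(sprintf("Simple graph: %d nodes, %d edges\n",
              x$n_nodes, sum(x$adjacency) / 2))
  invisible(x)
}

#' Read / write hyperedge-list files
#'
#' Plain-text UTF-8 format: a header line `#nodes: id1 id2 ...` declaring the
#' node order, then one line per hyperedge,
#' `edge_id<TAB>weight<TAB>member,member,...`. Other lines starting with `#`
#' are comments. `write_hypergraph()` followed by `read_hypergraph()` is the
#' identity on (incidence, weights, node_ids).
#'
#' @param path file path.
#' @return `read_hypergraph()` returns a [hypergraph()];
#'   `write_hypergraph()` returns `path` invisibly.
#' @export
read_hypergraph <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header_at <- grep("^#nodes:", lines)
  if (!length(header_at)) stopf("%s: missing '#nodes:' header", path)
  node_ids <- strsplit(trimws(sub("^#nodes:", "", lines[header_at[1]])),
                       "[[:space:]]+")[[1]]
  edge_members <- list()
  edge_ids <- character()
  weights <- numeric()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (i == header_at[1] || grepl("^[[:space:]]*(#|$)", ln)) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3L) {
      stopf("%s:%d: expected 'edge_id<TAB>weight<TAB>members', got %d field(s)",
            path, i, length(parts))
    }
    w <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(w)) stopf("%s:%d: non-numeric weight '%s'", path, i, parts[2])
    members <- strsplit(parts[3], ",", fixed = TRUE)[[1]]
    members <- trimws(members)
    if (!all(members %in% node_ids)) {
      stopf("%s:%d: member(s) not declared in header: %s", path, i,
            paste(setdiff(members, node_ids), collapse = ", "))
    }
    edge_ids <- c(edge_ids, parts[1])
    weights <- c(weights, w)
    edge_members <- c(edge_members, list(members))
  }
  hypergraph(edge_members, node_ids, weights, edge_ids)
}

#' @rdname read_hypergraph
#' @param h a [hypergraph()] to serialize.
#' @export
write_hypergraph <- function(h, path) {
  stopifnot(inherits(h, "hypergraph"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#nodes: ", paste(h$node_ids, collapse = " ")), con)
  for (y in seq_len(h$n_edges)) {
    members <- h$node_ids[h$incidence[, y] == 1]
    writeLines(sprintf("%s\t%s\t%s", colnames(h$incidence)[y],
                       format(h$edge_weights[y], digits = 15),
                       paste(members, collapse = ",")), con)
  }
  invisible(path)
}
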
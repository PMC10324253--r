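#' Build an interaction network from an edge table
#'
#' Constructs an undirected simple graph from a two-column (plus optional
#' `weight`) edge data frame.  Duplicate edges (in either orientation) and
#' self-loops are removed.  The vertex order — which fixes the alignment of
#' every vector and matrix in the package — is the order of first
#' appearance in the edge table.
#'
#' @param edges Data frame whose first two columns are node identifiers;
#'   an optional `weight` column holds per-edge confidences in \[0, 1\].
#' @return An `igraph` object.
#' @export
as_interaction_network <- function(edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2 || nrow(edges) == 0) {
    stop_input("edge table must have at least two columns and one row")
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  keep <- a != b
  if (any(!keep)) warn(sprintf("dropped %d self-loop(s)", sum(!keep)))
  g <- igraph::graph_from_data_frame(
    cbind(data.frame(from = a[keep], to = b[keep]),
          edges[keep, setdiff(names(edges), names(edges)[1:2]), drop = FALSE]),
    directed = FALSE
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(weight = "max", "ignore"))
}

#' Largest connected component
#'
#' The algorithm requires a connected network; disconnected inputs are
#' reduced to their largest component with a warning stating how many nodes
#' were dropped.  If several components tie for the maximum size, the one
#' containing the lexicographically smallest node identifier is kept, so
#' the result is deterministic.
#'
#' @param graph An `igraph` object.
#' @return The induced subgraph on the largest component.
#' @export
largest_connected_component <- function(graph) {
  if (igraph::vcount(graph) == 0) stop_input("empty graph")
  comp <- igraph::components(graph)
  if (comp$no == 1) return(graph)
  biggest <- which(comp$csize == max(comp$csize))
  if (length(biggest) > 1) {
    nm <- igraph::V(graph)$name
    first_member <- vapply(biggest, function(k) min(nm[comp$membership == k]), "")
    biggest <- biggest[order(first_member)][1]
  }
  keep <- which(comp$membership == biggest)
  warn(sprintf("graph is disconnected: keeping largest component (%d nodes), dropping %d",
               length(keep), igraph::vcount(graph) - length(keep)))
  igraph::induced_subgraph(graph, keep)
}

#' Node coreness (k-core number)
#'
#' The coreness of a node is the largest k such that the node belongs to a
#' subgraph in which every node has degree at least k.  It is a global
#' centrality that, unlike degree, is not inflated by star-like hubs, and
#' it replaces degree in the transition-matrix normalization to attenuate
#' the ascertainment-driven degree bias of interaction databases.
#'
#' @param graph An `igraph` object.
#' @return Named integer vector of core numbers, in vertex order.
#' @export
node_coreness <- function(graph) {
  k <- as.integer(igraph::coreness(graph))
  names(k) <- igraph::V(graph)$name
  k
}

#' Core-normalized transition matrix
#'
#' Column-stochastic transition matrix for the random walk.  In each column
#' j the non-zero entries of the adjacency matrix are replaced by the
#' coreness of the corresponding row node and the column is rescaled to sum
#' to one:
#' \deqn{(A_N)_{ij} = k_i / \sum_{l:\,A_{lj}\neq 0} k_l.}
#' Entry (i, j) is the probability that a walker at node j steps to
#' neighbor i.  On a k-regular graph this reduces exactly to degree
#' normalization.
#'
#' @param graph A connected `igraph` object with at least 2 nodes.
#' @param weighted If `TRUE` and the graph has a `weight` edge attribute,
#'   coreness contributions are multiplied by the edge confidence before
#'   normalizing (off by default: confidences are normally used only to
#'   threshold the input network).
#' @return A sparse `dgCMatrix` with rows/columns in vertex order; every
#'   column sums to 1.
#' @export
core_transition_matrix <- function(graph, weighted = FALSE) {
  n <- igraph::vcount(graph)
  if (n < 2) stop_input("need at least 2 nodes to build a transition matrix")
  if (weighted && "weight" %in% igraph::edge_attr_names(graph)) {
    A <- igraph::as_adjacency_matrix(graph, sparse = TRUE, attr = "weight")
  } else {
    A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  }
  k <- as.numeric(igraph::coreness(graph))
  M <- Matrix::Diagonal(n, x = k) %*% A     # entry ij: k_i where A_ij != 0
  cs <- Matrix::colSums(M)
  if (any(cs == 0)) {
    stop_input("graph has isolated node(s) (or zero-coreness columns); transition matrix undefined")
  }
  M <- M %*% Matrix::Diagonal(n, x = 1 / cs)
  dimnames(M) <- list(igraph::V(graph)$name, igraph::V(graph)$name)
  methods::as(M, "CsparseMatrix")
}

#' Core-clustering coefficient
#'
#' The MCODE node statistic used as the topological term of the module
#' score: take the closed neighborhood of a node (the node plus its
#' neighbors), extract the k-core of that induced subgraph with maximal k,
#' and return its edge density 2E / (n (n - 1)).  Unlike the ordinary
#' clustering coefficient it is not dragged down by sparsely connected
#' neighbors.  The density of a single node (or of a 0-core with no edges)
#' is defined as 0.
#'
#' @param graph An `igraph` object.
#' @param v Vertices to evaluate (default all), as names or indices.
#' @return Numeric vector in \[0, 1\], one value per requested vertex.
#' @export
core_clustering_coefficient <- function(graph, v = igraph::V(graph)) {
  idx <- as.integer(igraph::V(graph)[v])
  vapply(idx, function(i) {
    nb <- c(i, as.integer(igraph::neighbors(graph, i)))
    sub <- igraph::induced_subgraph(graph, unique(nb))
    kc <- igraph::coreness(sub)
    core <- igraph::induced_subgraph(sub, which(kc == max(kc)))
    n <- igraph::vcount(core)
    if (n < 2) return(0)
    2 * igraph::ecount(core) / (n * (n - 1))
  }, numeric(1))
}
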
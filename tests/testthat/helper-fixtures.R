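## Small named graphs used across tests

graph_from_edges <- function(...) {
  el <- matrix(c(...), ncol = 2, byrow = TRUE)
  igraph::graph_from_edgelist(el, directed = FALSE)
}

path3 <- function() graph_from_edges("a", "b", "b", "c")

triangle <- function() graph_from_edges("a", "b", "b", "c", "a", "c")

star4 <- function() graph_from_edges("hub", "l1", "hub", "l2", "hub", "l3")

## connected Erdos-Renyi graph with named vertices v01, v02, ...
random_connected_graph <- function(n, p = 0.3) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

## signed-weight instance for MWCS tests; guarantees >= 1 positive node
random_signed_instance <- function(n, p = 0.35) {
  g <- random_connected_graph(n, p)
  w <- stats::rnorm(n)
  if (!any(w > 0)) w[which.max(w)] <- abs(w[which.max(w)]) + 0.1
  names(w) <- igraph::V(g)$name
  list(graph = g, weights = w)
}

## tiny planted-module instance for fast engine tests
small_instance <- function(seed = 7L, N = 60, m = 8) {
  simulate_amend_data(synthetic_spec(N = N, m = m, seed = seed))
}
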
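#' Heuristic maximum-weight connected subgraph (Heinz step)
#'
#' Given signed node weights (shifted propagation scores), finds a
#' connected subgraph of large total weight.  Exact MWCS solvers reduce
#' the problem to a prize-collecting Steiner tree and are expensive; this
#' heuristic instead
#' \enumerate{
#'   \item contracts each connected component of positive-weight nodes
#'     into a meta-node whose weight is the sum of its members,
#'   \item connects meta-nodes by shortest paths through negative nodes,
#'     a path costing the sum of |negative weight| along it,
#'   \item builds the complete meta-graph and takes its minimum spanning
#'     tree under edge cost (path cost) - (incident meta-node weights),
#'   \item iteratively prunes tree leaves whose removal increases the
#'     total weight (leaf weight < connector cost), worst leaf first,
#'   \item expands meta-nodes and connector paths back to original nodes,
#'     then absorbs any positive node adjacent to the selection (which is
#'     always cost-free).
#' }
#' All tie-breaks are by ascending node identifier, so the output is a
#' deterministic function of the input.  The result is always connected
#' and never lighter than the heaviest single positive meta-node.
#'
#' @param graph A connected `igraph` object.
#' @param weights Numeric node weights with both signs, named by node or
#'   aligned to vertex order.
#' @return A list of class `mwcs_solution`: `nodes` (character, in vertex
#'   order) and `weight` (total node weight of the selection).
#' @seealso [mwcs_exact()] for the brute-force oracle on small graphs.
#' @export
heinz_heuristic <- function(graph, weights) {
  nm <- igraph::V(graph)$name
  if (is.null(nm)) stop_input("graph vertices must be named")
  if (!igraph::is_connected(graph)) stop_input("input graph must be connected")
  w <- align_weights(weights, nm)
  if (!any(w > 0)) {
    stop_algorithm("no positively weighted node: filtering rate too aggressive")
  }

  pos_idx <- which(w > 0)
  gp <- igraph::induced_subgraph(graph, pos_idx)
  cm <- igraph::components(gp)$membership
  n_meta <- max(cm)
  neg_idx <- which(w <= 0)

  grp <- integer(length(nm))
  grp[pos_idx] <- cm[nm[pos_idx]]
  grp[neg_idx] <- n_meta + seq_along(neg_idx)
  group_members <- split(nm, grp)            # names are group ids as strings
  group_members <- group_members[as.character(seq_len(n_meta + length(neg_idx)))]
  meta_w <- vapply(group_members[seq_len(n_meta)], function(m) sum(w[m]), 0)
  meta_key <- vapply(group_members[seq_len(n_meta)], min, "")

  if (n_meta == 1) {
    return(finish_solution(graph, w, nm, group_members[[1]]))
  }

  ## contracted graph: metas + individual non-positive nodes; edge weight =
  ## mean endpoint cost, so a path cost telescopes to the sum of interior
  ## |negative| costs (meta endpoints cost 0)
  cost <- numeric(n_meta + length(neg_idx))
  cost[grp[neg_idx]] <- -w[neg_idx]
  cg <- igraph::contract(graph, grp, vertex.attr.comb = "ignore")
  el <- igraph::as_edgelist(cg, names = FALSE)
  igraph::E(cg)$weight <- (cost[el[, 1]] + cost[el[, 2]]) / 2
  cg <- igraph::simplify(cg, edge.attr.comb = list(weight = "min"))

  metas <- seq_len(n_meta)
  d <- igraph::distances(cg, v = metas, to = metas, weights = igraph::E(cg)$weight)

  ## Kruskal MST of the complete meta-graph, deterministic edge order
  pr <- which(upper.tri(d), arr.ind = TRUE)
  i1 <- pr[, 1]; i2 <- pr[, 2]
  ecost <- d[pr] - meta_w[i1] - meta_w[i2]
  ka <- pmin(meta_key[i1], meta_key[i2])
  kb <- pmax(meta_key[i1], meta_key[i2])
  ord <- order(ecost, ka, kb)
  parent <- metas
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  tree_i <- integer(0); tree_j <- integer(0); tree_cost <- numeric(0)
  for (e in ord) {
    ra <- find(i1[e]); rb <- find(i2[e])
    if (ra != rb) {
      parent[ra] <- rb
      tree_i <- c(tree_i, i1[e]); tree_j <- c(tree_j, i2[e])
      tree_cost <- c(tree_cost, d[i1[e], i2[e]])
      if (length(tree_i) == n_meta - 1) break
    }
  }

  ## prune non-beneficial leaves, worst first; ties drop the meta whose
  ## smallest member id sorts last, so low identifiers survive
  alive_meta <- rep(TRUE, n_meta)
  alive_edge <- rep(TRUE, length(tree_i))
  repeat {
    if (sum(alive_meta) <= 1) break
    deg <- tabulate(c(tree_i[alive_edge], tree_j[alive_edge]), nbins = n_meta)
    leaves <- which(alive_meta & deg == 1)
    if (!length(leaves)) break
    leaf_edge <- vapply(leaves, function(m) {
      which(alive_edge & (tree_i == m | tree_j == m))[1]
    }, integer(1))
    benefit <- meta_w[leaves] - tree_cost[leaf_edge]
    bad <- benefit < 0
    if (!any(bad)) break
    pick <- which(bad)[order(benefit[bad], -xtfrm(meta_key[leaves[bad]]))][1]
    alive_meta[leaves[pick]] <- FALSE
    alive_edge[leaf_edge[pick]] <- FALSE
  }

  ## expand back to original nodes: kept metas plus every contracted vertex
  ## on the connector paths of kept tree edges
  sel_groups <- which(alive_meta)
  for (e in which(alive_edge)) {
    vp <- igraph::shortest_paths(cg, from = tree_i[e], to = tree_j[e],
                                 weights = igraph::E(cg)$weight)$vpath[[1]]
    sel_groups <- c(sel_groups, as.integer(vp))
  }
  sel <- unlist(group_members[unique(sel_groups)], use.names = FALSE)

  out <- finish_solution(graph, w, nm, sel)

  ## guarantee: never worse than the heaviest single meta-node
  ord_meta <- order(-meta_w, meta_key)
  best_single <- meta_w[ord_meta[1]]
  if (out$weight < best_single - 1e-12) {
    out <- finish_solution(graph, w, nm, group_members[[ord_meta[1]]])
  }
  out
}

## absorb cost-free positive neighbors, order nodes by vertex order,
## check connectivity, package as mwcs_solution
finish_solution <- function(graph, w, nm, sel) {
  repeat {
    nb <- unique(unlist(igraph::adjacent_vertices(graph, sel), use.names = FALSE))
    add <- setdiff(nm[nb][w[nm[nb]] > 0], sel)
    if (!length(add)) break
    sel <- c(sel, add)
  }
  nodes <- nm[sort(match(sel, nm))]
  sub <- igraph::induced_subgraph(graph, nodes)
  if (!igraph::is_connected(sub)) {
    stop_algorithm("internal error: MWCS heuristic produced a disconnected subgraph")
  }
  structure(list(nodes = nodes, weight = sum(w[nodes])), class = "mwcs_solution")
}

align_weights <- function(weights, nm) {
  w <- weights
  if (!is.null(names(w))) {
    w <- w[nm]
    if (any(is.na(w))) stop_input("weights do not cover all graph nodes")
  } else {
    if (length(w) != length(nm)) stop_input("weights not aligned to graph nodes")
    names(w) <- nm
  }
  w
}

#' Exact maximum-weight connected subgraph by enumeration
#'
#' Enumerates every connected induced subgraph (bitmask search, so the
#' graph is capped at 16 nodes) and returns the maximum-weight one, ties
#' broken by the lexicographically smallest node set.  This is the
#' independent oracle against which [heinz_heuristic()] is validated; it
#' is not usable at network scale.
#'
#' @inheritParams heinz_heuristic
#' @return A list of class `mwcs_solution`: `nodes` and `weight`.
#' @export
mwcs_exact <- function(graph, weights) {
  nm <- igraph::V(graph)$name
  if (is.null(nm)) stop_input("graph vertices must be named")
  n <- length(nm)
  if (n > 16) stop_input("exact enumeration is limited to 16 nodes")
  w <- align_weights(weights, nm)
  adj <- integer(n)
  el <- igraph::as_edgelist(graph, names = FALSE)
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]; b <- el[r, 2]
    adj[a] <- bitwOr(adj[a], bitwShiftL(1L, b - 1L))
    adj[b] <- bitwOr(adj[b], bitwShiftL(1L, a - 1L))
  }
  res <- mwcs_exact_cpp(adj, unname(w))
  nodes <- nm[res$members]
  structure(list(nodes = nodes, weight = res$weight), class = "mwcs_solution")
}

#' @exportS3Method base::print
print.mwcs_solution <- function(x, ...) {
  cat(sprintf("<mwcs_solution> %d nodes, total weight %.6g\n",
              length(x$nodes), x$weight))
  invisible(x)
}
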
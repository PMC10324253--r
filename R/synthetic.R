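#' Specification for a synthetic planted-module instance
#'
#' Describes the generative model used for end-to-end validation: a sparse
#' scale-free-like background network (preferential attachment, mimicking
#' the heavy-tailed degree distribution of protein interaction networks)
#' with a connected planted module wired in by a small number of bridge
#' edges.  Planted genes carry extreme ECIs in the direction of interest;
#' background genes carry near-zero noise ECIs.
#'
#' @param N Background network size (nodes).
#' @param attachment Edges added per node by the preferential-attachment
#'   generator.
#' @param m Planted module size (appended to the background, so the full
#'   network has `N + m` nodes).
#' @param planted_p Probability of each extra intra-module edge beyond the
#'   random spanning tree that guarantees the planted module is connected.
#' @param bridges Number of bridge edges tying the planted module to the
#'   background (2 keeps recovery nontrivial but possible).
#' @param s Direction of interest of the planted signal (+1 or -1).
#' @param eci_range Range of |ECI| for planted genes.
#' @param noise Standard deviation of the background ECI noise (mean 0;
#'   with sd 0.1 essentially all background |ECI| stay below 0.3).
#' @param seed Integer seed; the generator is fully deterministic given
#'   the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(N = 500, attachment = 2, m = 15, planted_p = 0.3,
                           bridges = 2, s = -1, eci_range = c(0.7, 0.95),
                           noise = 0.1, seed = 1L) {
  if (m >= N) stop_input("planted module must be smaller than the background")
  if (!s %in% c(-1, 1)) stop_input("`s` must be +1 or -1")
  assert_scalar_prob(planted_p, "planted_p")
  structure(list(N = N, attachment = attachment, m = m, planted_p = planted_p,
                 bridges = bridges, s = s, eci_range = eci_range,
                 noise = noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic network with a planted module
#'
#' Draws a preferential-attachment background on `N` nodes, appends a
#' connected planted subgraph of `m` nodes (random spanning tree plus
#' Bernoulli(`planted_p`) extra edges), and joins the two with
#' `spec$bridges` bridge edges.  Node identifiers are `g0001, g0002, ...`;
#' planted nodes are the last `m` and are flagged in the vertex attribute
#' `planted`.
#'
#' @param spec A [synthetic_spec()].
#' @return An `igraph` with logical vertex attribute `planted`.
#' @export
generate_network <- function(spec) {
  set.seed(spec$seed)
  total <- spec$N + spec$m
  ids <- sprintf("g%04d", seq_len(total))
  bg <- igraph::sample_pa(spec$N, power = 1, m = spec$attachment,
                          directed = FALSE)
  el <- igraph::as_edgelist(bg, names = FALSE)
  edges <- data.frame(from = ids[el[, 1]], to = ids[el[, 2]])

  if (spec$m > 0) {
    planted <- seq.int(spec$N + 1, total)
    if (spec$m > 1) {
      ## random spanning tree: attach node j to a uniformly chosen earlier node
      anchor <- vapply(seq_len(spec$m - 1), function(j) {
        planted[sample.int(j, 1)]
      }, integer(1))
      tree <- data.frame(from = ids[anchor], to = ids[planted[-1]])
      extra_pairs <- utils::combn(planted, 2)
      in_tree <- paste(pmin(anchor, planted[-1]), pmax(anchor, planted[-1]))
      pair_key <- paste(extra_pairs[1, ], extra_pairs[2, ])
      candidate <- which(!(pair_key %in% in_tree))
      keep <- candidate[runif(length(candidate)) < spec$planted_p]
      extra <- data.frame(from = ids[extra_pairs[1, keep]],
                          to = ids[extra_pairs[2, keep]])
      edges <- rbind(edges, tree, extra)
    }
    bridge_from <- planted[sample.int(spec$m, spec$bridges,
                                      replace = spec$bridges > spec$m)]
    bridge_to <- sample(seq_len(spec$N), spec$bridges)
    edges <- rbind(edges, data.frame(from = ids[bridge_from], to = ids[bridge_to]))
  }

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  g <- igraph::simplify(g)
  g <- largest_connected_component(g)
  igraph::V(g)$planted <- igraph::V(g)$name %in% ids[seq.int(spec$N + 1, length.out = spec$m)]
  g
}

#' Generate gene statistics with a planted ECI signal
#'
#' For each gene a target ECI is drawn — planted genes: |ECI| uniform in
#' `spec$eci_range`, signed by the direction of interest; background
#' genes: Normal(0, `spec$noise`) clamped to \[-0.95, 0.95\] — and a
#' quadruple (beta1, p1, beta2, p2) is constructed that reproduces the
#' target exactly through [compute_eci()]: with target e and p-values
#' drawn small enough that `|e| / (1 - max(p))` stays below 1, setting
#' `beta2 = sign(e) * beta1 * |e| / (1 - max(p))` recovers e.  Planted
#' genes get small p-values and `significant = TRUE`.
#'
#' @param spec A [synthetic_spec()].
#' @param graph The network from [generate_network()] (supplies node ids
#'   and planted flags).
#' @return A tibble with `gene_id`, `beta1`, `p1`, `beta2`, `p2`, `eci`,
#'   `z`, `significant`, `planted` and `eci_target` (the drawn target the
#'   quadruple was constructed to reproduce).
#' @export
generate_gene_stats <- function(spec, graph) {
  set.seed(spec$seed + 1L)
  ids <- igraph::V(graph)$name
  planted <- igraph::V(graph)$planted %||% rep(FALSE, length(ids))
  n <- length(ids)

  target <- numeric(n)
  target[planted] <- spec$s * runif(sum(planted), spec$eci_range[1], spec$eci_range[2])
  target[!planted] <- pmin(0.95, pmax(-0.95, rnorm(sum(!planted), 0, spec$noise)))

  p1 <- numeric(n); p2 <- numeric(n)
  p1[planted] <- runif(sum(planted), 0.001, 0.04)
  p2[planted] <- runif(sum(planted), 0.001, 0.04)
  p1[!planted] <- runif(sum(!planted), 0.05, 0.5)
  p2[!planted] <- runif(sum(!planted), 0.05, 0.5)
  ## resample p-values where the damped ratio would exceed 1
  for (iter in 1:50) {
    bad <- abs(target) / (1 - pmax(p1, p2)) > 1
    if (!any(bad)) break
    p1[bad] <- runif(sum(bad), 0.001, 0.04)
    p2[bad] <- runif(sum(bad), 0.001, 0.04)
  }

  b <- runif(n, 0.5, 2) * sample(c(-1, 1), n, replace = TRUE)
  ratio <- abs(target) / (1 - pmax(p1, p2))
  beta2 <- ifelse(target == 0, 0, sign(target) * sign(b) * ratio * abs(b))

  out <- tibble::tibble(
    gene_id = ids,
    beta1 = b, p1 = p1, beta2 = beta2, p2 = p2,
    planted = planted, eci_target = target
  )
  out$eci <- compute_eci(out$beta1, out$p1, out$beta2, out$p2)
  out$z <- standardize_eci(out$eci, s = spec$s)
  out$significant <- planted
  out
}

#' Generate a complete synthetic instance
#'
#' Convenience wrapper returning the network, the gene statistics table
#' and the planted node set together.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `graph`, `stats`, `planted` (character vector),
#'   `spec`.
#' @export
simulate_amend_data <- function(spec = synthetic_spec()) {
  g <- generate_network(spec)
  stats <- generate_gene_stats(spec, g)
  list(graph = g, stats = stats,
       planted = igraph::V(g)$name[igraph::V(g)$planted], spec = spec)
}
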
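#' Descriptive statistics for a module
#'
#' @param nodes Character vector of module genes, or an `amend_run`.
#' @param graph The parent network (ignored when `nodes` is an
#'   `amend_run`).
#' @param stats Gene statistics table with `gene_id`, `eci` and optionally
#'   a logical `significant` column.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `edge_density`
#'   (2E / n(n-1), 0 for a single node), `median_eci` and
#'   `prop_significant` (`NA` when no significance flags were supplied —
#'   the upstream ECI bootstrap is outside this package's scope).
#' @export
module_stats <- function(nodes, graph = NULL, stats) {
  if (inherits(nodes, "amend_run")) {
    graph <- nodes$module$graph
    nodes <- nodes$module$nodes
    sub <- graph
  } else {
    if (!all(nodes %in% igraph::V(graph)$name)) {
      stop_input("module nodes must belong to the network")
    }
    sub <- igraph::induced_subgraph(graph, nodes)
  }
  n <- length(nodes)
  e <- igraph::ecount(sub)
  eci <- stats$eci[match(nodes, stats$gene_id)]
  if (any(is.na(eci))) stop_input("every module gene needs a row in `stats`")
  prop_sig <- NA_real_
  if ("significant" %in% names(stats)) {
    prop_sig <- mean(stats$significant[match(nodes, stats$gene_id)])
  }
  tibble::tibble(
    n_nodes = n,
    n_edges = e,
    edge_density = if (n < 2) 0 else 2 * e / (n * (n - 1)),
    median_eci = median(eci),
    prop_significant = prop_sig
  )
}

#' Hypergeometric overrepresentation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a module and each
#' gene set, with the network's gene universe as background and
#' Benjamini-Hochberg adjustment across sets.  Sets are intersected with
#' the universe before testing.
#'
#' @param module Character vector of module genes.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector: all genes of the network.
#' @param alpha Significance level applied to the adjusted p-value.
#' @return A tibble with one row per gene set: `set`, `set_size`,
#'   `overlap`, `p`, `p_adj`, `significant`, sorted by `p`.
#' @export
hypergeom_ora <- function(module, gene_sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop_input("empty gene universe")
  module <- intersect(unique(module), universe)
  sets <- lapply(gene_sets, function(s) intersect(unique(s), universe))
  N <- length(universe)
  n <- length(module)
  res <- purrr::imap_dfr(sets, function(s, nm) {
    K <- length(s)
    x <- length(intersect(s, module))
    tibble::tibble(set = nm, set_size = K, overlap = x,
                   p = phyper(x - 1, K, N - K, n, lower.tail = FALSE))
  })
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj <= alpha
  dplyr::arrange(res, .data$p, .data$set)
}

## pathway-level enrichment score across a set of modules:
## max over modules of -log10(raw hypergeometric p)
enrichment_scores <- function(modules, gene_sets, universe) {
  per_mod <- lapply(modules, hypergeom_ora, gene_sets = gene_sets, universe = universe)
  score <- rep(0, length(gene_sets))
  names(score) <- names(gene_sets)
  for (ora in per_mod) {
    s <- -log10(pmax(ora$p, .Machine$double.xmin))
    score <- pmax(score, s[match(names(score), ora$set)])
  }
  list(score = score, per_module = per_mod)
}

#' Empirical-to-hypergeometric ratio (EHR and mEHR)
#'
#' Permutation-based validation of overrepresentation results.  A
#' pathway's enrichment score for a set of modules is the maximum
#' -log10(p) of its hypergeometric tests across those modules.  `M`
#' re-runs of the module-identification pipeline on permuted data supply a
#' null distribution of enrichment scores per pathway; the empirical
#' p-value is the proportion of null scores at least as large as the
#' observed score (ties count toward the null).  A pathway is
#' *empirically validated* (EV) when its empirical p <= `alpha` and its
#' minimum BH-adjusted hypergeometric p across the observed modules is
#' <= `alpha`.  The EHR is the fraction of significantly enriched
#' pathways that are EV; the mEHR is the same fraction computed per
#' module.
#'
#' @param modules List of character vectors: the observed module(s).
#' @param permuted_runner Function taking a permutation index `1..M` and
#'   returning the list of modules identified on data with ECI values
#'   permuted across genes (see [permute_gene_stats()]).
#' @param gene_sets Named list of gene sets.
#' @param universe Background gene universe (all network genes).
#' @param M Number of permutations.
#' @param alpha Significance level for both p-values.
#' @return A list: `ehr` (scalar in \[0, 1\], `NA` if no pathway is
#'   significant), `pathways` (tibble with observed score, empirical p,
#'   min adjusted p, EV flag), `mehr` (tibble, one row per module).
#' @export
ehr <- function(modules, permuted_runner, gene_sets, universe, M = 50,
                alpha = 0.05) {
  if (M < 1) stop_input("`M` must be >= 1")
  obs <- enrichment_scores(modules, gene_sets, universe)
  null_scores <- matrix(0, nrow = M, ncol = length(gene_sets),
                        dimnames = list(NULL, names(gene_sets)))
  for (m in seq_len(M)) {
    perm_modules <- permuted_runner(m)
    null_scores[m, ] <- enrichment_scores(perm_modules, gene_sets, universe)$score
  }
  emp_p <- vapply(seq_along(gene_sets), function(j) {
    mean(null_scores[, j] >= obs$score[j])
  }, 0)
  min_padj <- vapply(names(gene_sets), function(nm) {
    min(vapply(obs$per_module, function(ora) ora$p_adj[match(nm, ora$set)], 0))
  }, 0)
  pathways <- tibble::tibble(
    set = names(gene_sets),
    observed_score = unname(obs$score),
    empirical_p = emp_p,
    min_p_adj = unname(min_padj),
    significant = min_padj <= alpha,
    ev = emp_p <= alpha & min_padj <= alpha
  )
  n_sig <- sum(pathways$significant)
  ehr_val <- if (n_sig == 0) NA_real_ else sum(pathways$ev) / n_sig
  mehr <- purrr::imap_dfr(obs$per_module, function(ora, i) {
    sig_sets <- ora$set[ora$significant]
    ev_m <- pathways$ev[match(sig_sets, pathways$set)] &
      ora$p_adj[match(sig_sets, ora$set)] <= alpha
    tibble::tibble(module = i, n_significant = length(sig_sets),
                   n_ev = sum(ev_m),
                   mehr = if (length(sig_sets)) sum(ev_m) / length(sig_sets) else NA_real_)
  })
  list(ehr = ehr_val, pathways = pathways, mehr = mehr)
}

#' Permute gene statistics for the EHR null
#'
#' Returns a copy of the gene statistics table with the ECI values (and
#' significance flags, if present) permuted uniformly at random across
#' genes, breaking the gene-network association while preserving the ECI
#' distribution.
#'
#' @param stats Gene statistics table.
#' @return The permuted tibble.
#' @export
permute_gene_stats <- function(stats) {
  idx <- sample.int(nrow(stats))
  out <- stats
  perm_cols <- intersect(c("beta1", "p1", "beta2", "p2", "eci", "z", "significant"),
                         names(stats))
  out[perm_cols] <- stats[idx, perm_cols]
  out
}

#' Jaccard and nested similarity of two modules
#'
#' `jaccard` is |A∩B| / |A∪B|; `nested` is |A∩B| / min(|A|, |B|), the
#' degree to which the smaller module is contained in the larger.  Nested
#' is always at least Jaccard.
#'
#' @param a,b Non-empty character vectors (node sets).
#' @return A scalar in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  if (!length(a) || !length(b)) stop_input("modules must be non-empty")
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

#' @rdname jaccard
#' @export
nested <- function(a, b) {
  if (!length(a) || !length(b)) stop_input("modules must be non-empty")
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Bootstrap significance of consistency indices
#'
#' Each module is represented as a binary membership vector over the `N`
#' genes of the shared network.  `B` bootstrap resamples of size `N` are
#' drawn with replacement from the elements of each vector, the Jaccard
#' and nested indices are recomputed on every resample pair, and the
#' p-value of each index is the proportion of bootstrap values at least
#' as large as the observed one.
#'
#' @param a,b Character vectors (node sets).
#' @param universe Character vector of all network genes.
#' @param B Number of bootstrap resamples.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with rows `jaccard` and `nested`: observed value and
#'   bootstrap p-value.
#' @export
bootstrap_index_pvalue <- function(a, b, universe, B = 1000, seed = NULL) {
  if (B < 1) stop_input("`B` must be >= 1")
  universe <- unique(universe)
  va <- universe %in% a
  vb <- universe %in% b
  N <- length(universe)
  if (!is.null(seed)) set.seed(seed)
  bj <- numeric(B); bn <- numeric(B)
  for (i in seq_len(B)) {
    ra <- va[sample.int(N, N, replace = TRUE)]
    rb <- vb[sample.int(N, N, replace = TRUE)]
    inter <- sum(ra & rb)
    uni <- sum(ra | rb)
    mn <- min(sum(ra), sum(rb))
    bj[i] <- if (uni == 0) 0 else inter / uni
    bn[i] <- if (mn == 0) 0 else inter / mn
  }
  obs_j <- jaccard(a, b)
  obs_n <- nested(a, b)
  tibble::tibble(
    index = c("jaccard", "nested"),
    observed = c(obs_j, obs_n),
    p_value = c(mean(bj >= obs_j), mean(bn >= obs_n))
  )
}
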
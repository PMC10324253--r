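#' Read an interaction network from a file
#'
#' Supported formats:
#' \describe{
#'   \item{`edgelist`}{Tab-separated file whose first two columns are node
#'     identifiers, with an optional third `weight` column in \[0, 1\].}
#'   \item{`graphml`}{GraphML, read via igraph.}
#'   \item{`string`}{A STRING links file with columns `protein1`,
#'     `protein2`, `combined_score` on STRING's native 0-1000 integer
#'     scale.  Edges with `combined_score >= score_threshold` are kept;
#'     the default 800 corresponds to a combined confidence of 0.8.  An
#'     optional two-column protein-to-gene `mapping` table is applied to
#'     the identifiers before deduplication.}
#' }
#' In every case the result is an undirected simple graph: duplicate
#' edges (either orientation) are merged and self-loops dropped, with the
#' node/edge counts after each step reported via message.
#'
#' @param path Path to the network file.
#' @param format One of `"auto"`, `"edgelist"`, `"graphml"`, `"string"`.
#'   `"auto"` picks `graphml` for `.graphml`/`.xml` extensions, `string`
#'   when the header names a `combined_score` column, else `edgelist`.
#' @param score_threshold STRING combined-score threshold (0-1000 scale).
#' @param mapping Optional data frame (or TSV path) with two columns,
#'   identifier-in-file and gene identifier; unmapped nodes are dropped.
#' @return An `igraph` object.
#' @export
load_network <- function(path, format = c("auto", "edgelist", "graphml", "string"),
                         score_threshold = 800, mapping = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input(sprintf("network file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("graphml", "xml")) {
      format <- "graphml"
    } else {
      hdr <- tolower(readLines(path, n = 1))
      format <- if (grepl("combined_score", hdr)) "string" else "edgelist"
    }
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "max", "ignore"))
    return(igraph::simplify(g, edge.attr.comb = list(weight = "max", "ignore")))
  }
  tab <- tryCatch(
    readr::read_delim(path, delim = guess_delim(path), show_col_types = FALSE,
                      progress = FALSE),
    error = function(e) stop_input(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
  )
  if (format == "string") {
    need <- c("protein1", "protein2", "combined_score")
    if (!all(need %in% names(tab))) {
      stop_input("STRING links file needs columns protein1, protein2, combined_score")
    }
    bad <- which(!is.finite(tab$combined_score))
    if (length(bad)) {
      stop_input(sprintf("malformed combined_score at line %d", bad[1] + 1L))
    }
    n_in <- nrow(tab)
    tab <- tab[tab$combined_score >= score_threshold, need[1:2]]
    message(sprintf("STRING links: kept %d of %d rows at combined_score >= %s",
                    nrow(tab), n_in, format(score_threshold)))
    if (!is.null(mapping)) {
      if (is.character(mapping)) {
        mapping <- readr::read_tsv(mapping, show_col_types = FALSE, progress = FALSE)
      }
      map <- setNames(as.character(mapping[[2]]), as.character(mapping[[1]]))
      tab$protein1 <- map[tab$protein1]
      tab$protein2 <- map[tab$protein2]
      dropped <- sum(is.na(tab$protein1) | is.na(tab$protein2))
      if (dropped) message(sprintf("dropped %d rows with unmapped identifiers", dropped))
      tab <- tab[!is.na(tab$protein1) & !is.na(tab$protein2), ]
    }
  } else {
    if (ncol(tab) < 2) stop_input("edge list needs at least two columns")
  }
  if (nrow(tab) == 0) stop_input("no edges left after filtering")
  g <- as_interaction_network(tab)
  message(sprintf("network: %d nodes, %d edges after deduplication",
                  igraph::vcount(g), igraph::ecount(g)))
  g
}

guess_delim <- function(path) {
  l <- readLines(path, n = 1)
  if (grepl("\t", l)) "\t" else if (grepl(",", l)) "," else " "
}

#' Write a network to edge-list TSV or GraphML
#'
#' @param graph An `igraph` object.
#' @param path Output path; format chosen by extension (`.graphml` for
#'   GraphML, anything else for a `from`/`to`(/`weight`) TSV).
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path) {
  if (tolower(tools::file_ext(path)) == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    df <- data.frame(from = el[, 1], to = el[, 2])
    if ("weight" %in% igraph::edge_attr_names(graph)) {
      df$weight <- igraph::E(graph)$weight
    }
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a differential-expression summary table
#'
#' Expects a delimited file with columns `gene_id`, `log2fc`, `pvalue`
#' (and optionally `significant`); alternatively a single file carrying
#' both contrasts as suffixed columns (`log2fc1`/`pvalue1`,
#' `log2fc2`/`pvalue2`), in which case a list of two tables is returned.
#'
#' @param path Path to the file.
#' @return A tibble, or a list of two tibbles for a suffixed-column file.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("DE table not found: %s", path))
  tab <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  if (all(c("gene_id", "log2fc", "pvalue") %in% names(tab))) {
    return(tibble::as_tibble(tab))
  }
  if (all(c("gene_id", "log2fc1", "pvalue1", "log2fc2", "pvalue2") %in% names(tab))) {
    return(list(
      tibble::tibble(gene_id = tab$gene_id, log2fc = tab$log2fc1, pvalue = tab$pvalue1),
      tibble::tibble(gene_id = tab$gene_id, log2fc = tab$log2fc2, pvalue = tab$pvalue2)
    ))
  }
  stop_input("DE table needs columns gene_id, log2fc, pvalue (or suffixed pairs)")
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated as name, description,
#' then member genes.
#'
#' @param path Path to the `.gmt` file.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("GMT file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop_input(sprintf("malformed GMT line %d (need name, description, genes)", bad[1]))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  sets
}

#' Restrict a network and a gene statistics table to each other
#'
#' Drops network nodes without experimental statistics (exact identifier
#' match), takes the largest connected component of what remains, and
#' aligns the statistics table to the surviving vertex order.
#'
#' @param graph An `igraph` object.
#' @param stats Gene statistics table with a `gene_id` column.
#' @return A list: `network`, `stats` (rows in vertex order).
#' @export
join_stats_to_network <- function(graph, stats) {
  nm <- igraph::V(graph)$name
  keep <- nm %in% stats$gene_id
  if (!any(keep)) stop_input("no network node has a matching gene statistic")
  n_drop <- sum(!keep)
  g <- if (n_drop > 0) igraph::induced_subgraph(graph, which(keep)) else graph
  if (n_drop > 0) {
    message(sprintf("dropped %d network node(s) without gene statistics", n_drop))
  }
  g <- largest_connected_component(g)
  stats <- stats[match(igraph::V(g)$name, stats$gene_id), , drop = FALSE]
  list(network = g, stats = tibble::as_tibble(stats))
}

#' Read an AMEND configuration from YAML or JSON
#'
#' The file mirrors the arguments of [amend_config()]; unknown keys are
#' rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `amend_config` object.
#' @export
read_amend_config <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("config file not found: %s", path))
  vals <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    ## keep YAML 1.1 yes/no literals (incl. the key "n") as plain strings;
    ## no config field is logical
    yaml::read_yaml(path, handlers = list(
      "bool#yes" = function(x) x, "bool#no" = function(x) x))
  }
  known <- names(formals(amend_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_input(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(vals$pso)) vals$pso <- utils::modifyList(formals(amend_config)$pso |> eval(), vals$pso)
  do.call(amend_config, vals)
}

#' Write the results of a run to a directory
#'
#' Produces `module_nodes.tsv` (gene, ECI, standardized ECI, per-node
#' core-clustering coefficient), `module_edges.tsv`, `module.graphml`, and
#' `report.json` — a machine-readable run report holding the
#' configuration echo, input digests (node/edge/gene counts), the full
#' per-iteration trace, the final module and the RNG seed, which together
#' determine reproduction.  Output is byte-stable: identical runs write
#' identical files.
#'
#' @param run An `amend_run` object.
#' @param dir Output directory (created if needed).
#' @param stats Optional gene statistics table to annotate module nodes.
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(run, dir, stats = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- run$module
  nodes <- tibble::tibble(gene_id = m$nodes)
  if (!is.null(stats)) {
    idx <- match(nodes$gene_id, stats$gene_id)
    nodes$eci <- stats$eci[idx]
    if ("z" %in% names(stats)) nodes$z <- stats$z[idx]
  }
  nodes$core_clustering <- core_clustering_coefficient(m$graph, nodes$gene_id)
  readr::write_tsv(nodes, file.path(dir, "module_nodes.tsv"), progress = FALSE)
  el <- igraph::as_edgelist(m$graph)
  readr::write_tsv(data.frame(from = el[, 1], to = el[, 2]),
                   file.path(dir, "module_edges.tsv"), progress = FALSE)
  write_network(m$graph, file.path(dir, "module.graphml"))

  report <- list(
    package_version = as.character(utils::packageVersion("amendr")),
    seed = run$seed,
    config = unclass(run$config),
    eta0 = run$eta0,
    decay = run$decay,
    input = run$input,
    trace = dplyr::select(run$trace, -"nodes"),
    module = list(nodes = m$nodes, score = m$score, iteration = m$iteration,
                  alpha = m$alpha, filtering_rate = m$filtering_rate,
                  n_nodes = length(m$nodes), n_edges = igraph::ecount(m$graph))
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
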
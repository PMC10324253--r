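#' Filtering rate schedule
#'
#' The quantile used to shift propagation scores at iteration `i` decays
#' exponentially from the starting rate:
#' \deqn{f(i, \eta_0, d) = \eta_0\, e^{-d (i - 1)}.}
#' Because roughly a fraction f of nodes go negative after the shift and
#' negative nodes are the ones the MWCS solver can drop, f acts as the
#' per-iteration filtering rate.
#'
#' @param i Iteration index (>= 1), vectorized.
#' @param eta0 Starting filtering rate in (0, 1).
#' @param d Decay parameter (>= 0).
#' @return The filtering rate(s) in (0, eta0\].
#' @export
filtering_rate <- function(i, eta0, d) {
  if (any(i < 1)) stop_input("iteration index must be >= 1")
  assert_scalar_prob(eta0, "eta0", open_left = TRUE, open_right = TRUE)
  if (length(d) != 1 || !is.finite(d) || d < 0) stop_input("`d` must be a single value >= 0")
  eta0 * exp(-d * (i - 1))
}

#' Simulate module sizes under a filtering schedule
#'
#' Treating the filtering rate as the fraction of nodes removed per
#' iteration, iterates `s[i+1] = max(1, ceiling(s[i] * (1 - f(i))))` from
#' the starting network size until the size stops changing.  Larger decay
#' `d` collapses the rate sooner, so the simulated final size is
#' non-decreasing in `d` — the monotonicity that [calibrate_decay()]
#' exploits.
#'
#' @param n0 Starting network size (>= 1).
#' @param eta0,d Schedule parameters, see [filtering_rate()].
#' @return Integer vector of simulated sizes, ending with the repeated
#'   stable size; the last element is the predicted final module size.
#' @export
simulate_sizes <- function(n0, eta0, d) {
  if (length(n0) != 1 || n0 < 1 || n0 != round(n0)) stop_input("`n0` must be a positive integer")
  sizes <- as.integer(n0)
  i <- 1L
  repeat {
    s_next <- max(1L, as.integer(ceiling(sizes[i] * (1 - filtering_rate(i, eta0, d)))))
    sizes <- c(sizes, s_next)
    if (s_next == sizes[i]) break
    i <- i + 1L
    if (i > 10000L) break   # unreachable under f > 0; guard anyway
  }
  sizes
}

#' Calibrate the decay parameter for a target module size
#'
#' Scans a fixed geometric grid of decay values (60 points from 1e-3 to
#' 10) and returns the smallest one whose simulated final size (see
#' [simulate_sizes()]) reaches the requested module size `n`.  The grid
#' scan relies on the final size being non-decreasing in `d`.
#'
#' @param n0 Starting network size.
#' @param eta0 Starting filtering rate in (0, 1).
#' @param n Target approximate final module size, `1 <= n <= n0`.
#' @param d_grid Decay grid (ascending); the default spans \[1e-3, 10\]
#'   geometrically in 60 steps.
#' @return The calibrated decay value.
#' @export
calibrate_decay <- function(n0, eta0, n,
                            d_grid = exp(seq(log(1e-3), log(10), length.out = 60))) {
  if (n < 1 || n > n0) stop_input("`n` must satisfy 1 <= n <= n0")
  for (d in d_grid) {
    final <- tail(simulate_sizes(n0, eta0, d), 1)
    if (final >= n) return(d)
  }
  stop_input(paste0("no decay on the grid reaches a simulated final size >= ", n,
                    "; the first-iteration retention ceiling(n0 * (1 - eta0)) caps the ",
                    "achievable size -- use a smaller eta0 or a smaller n"))
}

#' Module score
#'
#' The score of a candidate module is the product of its experimental and
#' topological quality: \eqn{f(G) = \bar Z_G \times \bar C_G}, the mean
#' standardized ECI of the module's nodes times their mean core-clustering
#' coefficient, the latter computed within the module's induced subgraph.
#'
#' @param module_graph The module as an induced `igraph` subgraph.
#' @param z Standardized ECIs named by gene, covering the module's nodes.
#' @return The scalar score.
#' @export
score_network <- function(module_graph, z) {
  nm <- igraph::V(module_graph)$name
  if (!length(nm)) stop_input("module is empty")
  zg <- z[nm]
  if (any(is.na(zg))) stop_input("standardized ECIs do not cover all module nodes")
  mean(zg) * mean(core_clustering_coefficient(module_graph))
}

#' Configuration for an AMEND run
#'
#' Collects every tunable of [run_amend()] with the package defaults.
#'
#' @param n Target approximate final module size.
#' @param s Direction of interest: `-1` seeks inversely changed genes,
#'   `+1` equivalently changed genes.
#' @param c Seed weight for genes against the direction of interest,
#'   in \[0, 1\].
#' @param alpha_grid Restart-probability grid searched at every iteration;
#'   default 8 evenly spaced values in \[0.05, 0.95\].
#' @param eta0 Starting filtering rate in (0, 1), or the string `"pso"` to
#'   choose it by particle swarm optimization.
#' @param pso PSO settings used when `eta0 = "pso"`: `swarm`, `iterations`,
#'   `inertia`, `cognitive`, `social`, `bounds`.
#' @param eps RWR convergence tolerance.
#' @param rwr_max_iter RWR iteration cap.
#' @param max_iter Outer-loop iteration cap.
#' @return A list of class `amend_config`.
#' @export
amend_config <- function(n = 15, s = -1, c = 0.5,
                         alpha_grid = seq(0.05, 0.95, length.out = 8),
                         eta0 = 0.5,
                         pso = list(swarm = 10, iterations = 20, inertia = 0.7,
                                    cognitive = 1.5, social = 1.5,
                                    bounds = c(0.1, 0.9)),
                         eps = 1e-10, rwr_max_iter = 10000L, max_iter = 100L) {
  if (!s %in% c(-1, 1)) stop_input("`s` must be +1 or -1")
  assert_scalar_prob(c, "c")
  if (!length(alpha_grid) || any(alpha_grid <= 0 | alpha_grid > 1)) {
    stop_input("`alpha_grid` values must lie in (0, 1]")
  }
  if (!identical(eta0, "pso")) {
    assert_scalar_prob(eta0, "eta0", open_left = TRUE, open_right = TRUE)
  }
  structure(list(n = n, s = s, c = c, alpha_grid = sort(alpha_grid),
                 eta0 = eta0, pso = pso, eps = eps,
                 rwr_max_iter = as.integer(rwr_max_iter),
                 max_iter = as.integer(max_iter)),
            class = "amend_config")
}

#' One filtering iteration: RWR grid search, shift, MWCS, score
#'
#' For each restart value in the grid: build seeds from the original ECIs
#' restricted to the current network, propagate, shift by the quantile
#' `k`, solve the MWCS heuristically, and score the resulting module.
#' Returns the best-scoring module; score ties go to the smaller restart
#' value.
#'
#' @param graph Current (connected) network.
#' @param eci Original ECIs named by gene (restricted internally).
#' @param z Standardized ECIs named by gene (fixed, from the full data set).
#' @param k Filtering rate (quantile level) for this iteration.
#' @param config An [amend_config()].
#' @return A list: `nodes`, `graph` (induced module subgraph), `score`,
#'   `alpha`, `mean_z`, `mean_ccc`.
#' @export
iterate_once <- function(graph, eci, z, k, config = amend_config()) {
  nm <- igraph::V(graph)$name
  if (length(nm) < 2) stop_input("need at least 2 nodes to iterate")
  seeds <- seed_vector(eci[nm], s = config$s, c = config$c)
  trans <- core_transition_matrix(graph)
  best <- NULL
  errors <- character(0)
  for (alpha in config$alpha_grid) {
    sol <- tryCatch({
      prop <- rwr(trans, seeds, alpha, eps = config$eps,
                  max_iter = config$rwr_max_iter)
      shifted <- quantile_shift(prop, k)
      heinz_heuristic(graph, shifted)
    }, amendr_algorithm_error = function(e) e)
    if (inherits(sol, "error")) {
      errors <- c(errors, conditionMessage(sol))
      next
    }
    sub <- igraph::induced_subgraph(graph, sol$nodes)
    sc <- score_network(sub, z)
    if (is.null(best) || sc > best$score) {
      best <- list(nodes = sol$nodes, graph = sub, score = sc, alpha = alpha,
                   mean_z = mean(z[sol$nodes]),
                   mean_ccc = mean(core_clustering_coefficient(sub)))
    }
  }
  if (is.null(best)) {
    stop_algorithm(paste0("MWCS failed for every restart value: ",
                          paste(unique(errors), collapse = "; ")))
  }
  best
}

#' Identify the active module
#'
#' The full iterative procedure: calibrate the filtering-rate schedule for
#' the target size, then repeat \{seed, propagate, shift, extract, score\}
#' on a shrinking network until the node set stops changing (or the
#' iteration cap is hit), and return the highest-scoring module seen,
#' together with the complete per-iteration trace.  Seeds are re-derived
#' from the original ECIs of the surviving nodes at every iteration;
#' standardized ECIs stay fixed at their full-data values.
#'
#' @param graph The interaction network (`igraph`); if disconnected, the
#'   largest connected component is used with a warning.
#' @param stats Gene statistics table from [prepare_gene_stats()] (or any
#'   data frame with `gene_id` and `eci` columns; `z` is recomputed over
#'   the genes present in the network).
#' @param config An [amend_config()].
#' @param seed Optional integer seed; only consumed when
#'   `config$eta0 = "pso"`.
#' @return An object of class `amend_run` with elements `module` (nodes,
#'   graph, score, iteration, alpha, filtering_rate), `trace` (tibble, one
#'   row per iteration), `config`, `eta0`, `decay` and `seed`.
#' @examples
#' sim <- simulate_amend_data(synthetic_spec(N = 60, m = 8, seed = 7))
#' run <- run_amend(sim$graph, sim$stats, amend_config(n = 8))
#' glance(run)
#' @export
run_amend <- function(graph, stats, config = amend_config(), seed = NULL) {
  if (!all(c("gene_id", "eci") %in% names(stats))) {
    stop_input("`stats` needs columns gene_id and eci")
  }
  joined <- join_stats_to_network(graph, stats)
  graph <- joined$network
  stats <- joined$stats

  if (identical(config$eta0, "pso")) {
    opt <- optimize_eta0(graph, stats, config, seed = seed)
    return(opt$run)
  }

  eci <- setNames(stats$eci, stats$gene_id)
  z <- setNames(standardize_eci(stats$eci, s = config$s), stats$gene_id)
  eta0 <- config$eta0
  decay <- calibrate_decay(igraph::vcount(graph), eta0, config$n)

  cur <- graph
  rows <- list()
  modules <- list()
  for (i in seq_len(config$max_iter)) {
    k <- filtering_rate(i, eta0, decay)
    res <- iterate_once(cur, eci, z, k, config)
    rows[[i]] <- tibble::tibble(
      iteration = i,
      n_nodes = length(res$nodes),
      n_edges = igraph::ecount(res$graph),
      score = res$score,
      alpha = res$alpha,
      filtering_rate = k,
      mean_z = res$mean_z,
      mean_ccc = res$mean_ccc,
      nodes = list(res$nodes)
    )
    modules[[i]] <- res
    unchanged <- length(res$nodes) == igraph::vcount(cur)
    no_improvement <- i > 1 && res$score <= rows[[i - 1]]$score
    ## the decay was calibrated so the schedule lands at ~n nodes; shrinking
    ## past the target means the filtering overshot and the run is done
    overshot <- length(res$nodes) < config$n
    cur <- res$graph
    if (unchanged || no_improvement || overshot || length(res$nodes) < 2) break
  }
  trace <- dplyr::bind_rows(rows)
  best_i <- which.max(trace$score)
  best <- modules[[best_i]]
  structure(list(
    module = list(nodes = best$nodes, graph = best$graph, score = best$score,
                  iteration = best_i, alpha = best$alpha,
                  filtering_rate = trace$filtering_rate[best_i]),
    trace = trace,
    input = list(n_nodes = igraph::vcount(graph), n_edges = igraph::ecount(graph)),
    config = config, eta0 = eta0, decay = decay, seed = seed
  ), class = "amend_run")
}

#' Choose the starting filtering rate by particle swarm optimization
#'
#' Runs global-best PSO over the starting filtering rate, each objective
#' evaluation being a full (deterministic) [run_amend()] with a fixed
#' `eta0`; the objective is the final module score.  All randomness
#' (initial particle positions, velocity jitter) is governed by `seed`.
#'
#' @inheritParams run_amend
#' @param seed Integer seed for the swarm RNG.
#' @return A list: `eta0` (best rate found), `run` (the corresponding
#'   `amend_run`), and `history` (tibble of particle evaluations).
#' @export
optimize_eta0 <- function(graph, stats, config = amend_config(eta0 = "pso"),
                          seed = 1L) {
  ps <- config$pso
  lo <- ps$bounds[1]; hi <- ps$bounds[2]
  if (lo <= 0 || hi >= 1 || lo >= hi) stop_input("PSO bounds must lie inside (0, 1)")

  evaluate <- function(eta0) {
    cfg <- config
    cfg$eta0 <- eta0
    run_amend(graph, stats, cfg)
  }

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %||% 1L)

  n_p <- ps$swarm
  x <- runif(n_p, lo, hi)
  v <- runif(n_p, -(hi - lo) / 4, (hi - lo) / 4)
  fit <- vapply(x, function(e) evaluate(e)$module$score, 0)
  pbest_x <- x; pbest_f <- fit
  g <- which.max(fit)
  gbest_x <- x[g]; gbest_f <- fit[g]
  hist_rows <- list(tibble::tibble(iteration = 0L, particle = seq_len(n_p),
                                   eta0 = x, score = fit))

  for (t in seq_len(ps$iterations)) {
    r1 <- runif(n_p); r2 <- runif(n_p)
    v <- ps$inertia * v + ps$cognitive * r1 * (pbest_x - x) +
      ps$social * r2 * (gbest_x - x)
    x <- pmin(hi, pmax(lo, x + v))
    fit <- vapply(x, function(e) evaluate(e)$module$score, 0)
    upd <- fit > pbest_f
    pbest_x[upd] <- x[upd]; pbest_f[upd] <- fit[upd]
    g <- which.max(pbest_f)
    if (pbest_f[g] > gbest_f) {
      gbest_f <- pbest_f[g]; gbest_x <- pbest_x[g]
    }
    hist_rows[[t + 1L]] <- tibble::tibble(iteration = t, particle = seq_len(n_p),
                                          eta0 = x, score = fit)
  }
  gbest_run <- evaluate(gbest_x)   # deterministic in eta0
  gbest_run$eta0 <- gbest_x
  gbest_run$seed <- seed
  list(eta0 = gbest_x, run = gbest_run, history = dplyr::bind_rows(hist_rows))
}

#' @exportS3Method base::print
print.amend_run <- function(x, ...) {
  m <- x$module
  cat(sprintf(paste0("<amend_run> module of %d nodes / %d edges ",
                     "(score %.4f, iteration %d of %d, alpha %.3g, eta0 %.3g, decay %.3g)\n"),
              length(m$nodes), igraph::ecount(m$graph), m$score, m$iteration,
              nrow(x$trace), m$alpha, x$eta0, x$decay))
  invisible(x)
}
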
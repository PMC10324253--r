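test_that("filtering rate follows the exponential decay schedule", {
  expect_equal(filtering_rate(1, 0.5, 3.7), 0.5)
  expect_equal(filtering_rate(3, 0.5, 0), 0.5)
  expect_equal(filtering_rate(2, 0.5, 0.1), 0.5 * exp(-0.1), tolerance = 1e-5)
  expect_error(filtering_rate(0, 0.5, 1), class = "amendr_input_error")
  expect_error(filtering_rate(1, 1, 1), class = "amendr_input_error")
  expect_error(filtering_rate(1, 0.5, -1), class = "amendr_input_error")
})

test_that("size simulation iterates the ceil-retention recursion to a fixed point", {
  expect_identical(simulate_sizes(100, 0.5, 0),
                   c(100L, 50L, 25L, 13L, 7L, 4L, 2L, 1L, 1L))
  # huge decay: the rate collapses after one effective step
  s <- simulate_sizes(1000, 0.5, 50)
  expect_identical(tail(s, 1), as.integer(ceiling(1000 * 0.5)))
})

test_that("simulated final size is monotone non-decreasing in the decay", {
  set.seed(7)
  for (i in 1:60) {
    n0 <- sample(20:5000, 1)
    eta0 <- runif(1, 0.05, 0.95)
    ds <- sort(runif(8, 0, 5))
    finals <- vapply(ds, function(d) tail(simulate_sizes(n0, eta0, d), 1), 1L)
    expect_true(all(diff(finals) >= 0))
  }
})

test_that("decay calibration returns the smallest grid value reaching the target", {
  grid <- exp(seq(log(1e-3), log(10), length.out = 60))
  d <- calibrate_decay(1000, 0.5, 15)
  expect_gte(tail(simulate_sizes(1000, 0.5, d), 1), 15L)
  prev <- grid[match(d, grid) - 1]
  expect_lt(tail(simulate_sizes(1000, 0.5, prev), 1), 15L)
  # n = 1 is reached by any decay, so the smallest grid point comes back
  expect_equal(calibrate_decay(1000, 0.5, 1), grid[1])
  # a target above the first-step retention ceiling cannot be reached
  expect_error(calibrate_decay(100, 0.5, 100), class = "amendr_input_error")
  expect_error(calibrate_decay(100, 0.5, 0), class = "amendr_input_error")
})

test_that("module score multiplies mean standardized ECI by mean core clustering", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  z <- c(a = 2, b = 2, c = 2, d = 2)
  expect_equal(score_network(k4, z), 2)            # clique: mean CCC is 1
  z2 <- c(a = 1, b = -1, c = 2, d = -2)
  expect_equal(score_network(k4, z2), 0)           # mean z = 0 kills the score
  p <- path3()
  zp <- c(a = 1, b = 2, c = 3)
  expect_equal(score_network(p, zp), 2 * mean(core_clustering_coefficient(p)))
})

test_that("one iteration equals the best arm of the restart grid", {
  sim <- small_instance(seed = 13)
  eci <- setNames(sim$stats$eci, sim$stats$gene_id)
  z <- setNames(sim$stats$z, sim$stats$gene_id)
  grid <- c(0.2, 0.5, 0.9)
  cfg <- amend_config(n = 8, alpha_grid = grid)
  res <- iterate_once(sim$graph, eci, z, k = 0.3, cfg)
  # recompute each arm independently
  arm_score <- vapply(grid, function(a) {
    cfg1 <- amend_config(n = 8, alpha_grid = a)
    iterate_once(sim$graph, eci, z, k = 0.3, cfg1)$score
  }, 0)
  expect_equal(res$score, max(arm_score), tolerance = 1e-12)
  expect_equal(res$alpha, grid[which.max(arm_score)])
  expect_true(igraph::is_connected(res$graph))
  # k = 0: only the minimum node can be non-positive, so the module is
  # (essentially) the whole network
  res0 <- iterate_once(sim$graph, eci, z, k = 0,
                       amend_config(n = 8, alpha_grid = 0.5))
  expect_gte(length(res0$nodes), igraph::vcount(sim$graph) - 1L)
})

test_that("the run returns the argmax-score module with a strictly shrinking trace", {
  sim <- small_instance(seed = 13)
  run <- run_amend(sim$graph, sim$stats, amend_config(n = 8))
  expect_s3_class(run, "amend_run")
  expect_true(igraph::is_connected(run$module$graph))
  expect_equal(run$module$score, max(run$trace$score))
  expect_identical(run$module$iteration, which.max(run$trace$score))
  shrinking <- head(diff(run$trace$n_nodes), -1)
  expect_true(all(shrinking < 0))
  # every module is nested in the previous iteration's node set
  for (i in 2:nrow(run$trace)) {
    expect_true(all(run$trace$nodes[[i]] %in% run$trace$nodes[[i - 1]]))
  }
})

test_that("identical configuration and seed reproduce the run exactly", {
  sim <- small_instance(seed = 21)
  cfg <- amend_config(n = 8)
  r1 <- run_amend(sim$graph, sim$stats, cfg, seed = 4L)
  r2 <- run_amend(sim$graph, sim$stats, cfg, seed = 4L)
  expect_identical(r1$module$nodes, r2$module$nodes)
  expect_equal(r1$trace, r2$trace, tolerance = 0)
})

test_that("PSO degenerates gracefully and is never beaten by a coarse grid scan", {
  sim <- small_instance(seed = 5, N = 50, m = 6)
  cfg <- amend_config(n = 6, alpha_grid = c(0.2, 0.8), eta0 = "pso",
                      pso = list(swarm = 1, iterations = 0, inertia = 0.7,
                                 cognitive = 1.5, social = 1.5, bounds = c(0.1, 0.9)))
  one <- optimize_eta0(sim$graph, sim$stats, cfg, seed = 2L)
  expect_s3_class(one$run, "amend_run")
  expect_equal(one$eta0, one$run$eta0)

  cfg$pso <- list(swarm = 4, iterations = 3, inertia = 0.7,
                  cognitive = 1.5, social = 1.5, bounds = c(0.1, 0.9))
  opt <- optimize_eta0(sim$graph, sim$stats, cfg, seed = 2L)
  grid_scores <- vapply(seq(0.1, 0.9, length.out = 5), function(e0) {
    run_amend(sim$graph, sim$stats,
              amend_config(n = 6, alpha_grid = c(0.2, 0.8), eta0 = e0))$module$score
  }, 0)
  expect_gte(opt$run$module$score, max(grid_scores) - 1e-9)
  # deterministic under the seed
  opt2 <- optimize_eta0(sim$graph, sim$stats, cfg, seed = 2L)
  expect_identical(opt$eta0, opt2$eta0)
  expect_identical(opt$run$module$nodes, opt2$run$module$nodes)
})

test_that("broom-style accessors and plots summarise a run", {
  sim <- small_instance(seed = 13)
  run <- run_amend(sim$graph, sim$stats, amend_config(n = 8))
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_false("nodes" %in% names(td))
  gl <- glance(run)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_nodes, length(run$module$nodes))
  expect_s3_class(autoplot(run), "ggplot")
  expect_s3_class(plot_module(run, sim$stats), "ggplot")
})
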
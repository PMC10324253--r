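test_that("module statistics report size, density, median ECI and significance", {
  g <- path3()
  stats <- tibble::tibble(gene_id = c("a", "b", "c"),
                          eci = c(-0.5, -0.7, -0.9),
                          significant = c(TRUE, TRUE, TRUE))
  ms <- module_stats(c("a", "b", "c"), g, stats)
  expect_equal(ms$median_eci, -0.7)
  expect_equal(ms$edge_density, 2 / 3)
  expect_equal(ms$prop_significant, 1)
  # single node: density is defined as 0
  expect_equal(module_stats("a", g, stats)$edge_density, 0)
  # without flags the proportion is unavailable, not fabricated
  expect_true(is.na(module_stats("a", g, stats[c("gene_id", "eci")])$prop_significant))
})

test_that("hypergeometric ORA reproduces the closed-form tail and its edge cases", {
  universe <- sprintf("u%02d", 1:20)
  sets <- list(S = universe[1:5])
  module <- c(universe[1:3], universe[10])    # overlap 3 of a 4-gene module
  ora <- hypergeom_ora(module, sets, universe)
  expect_equal(ora$p, 155 / 4845, tolerance = 1e-12)
  # zero overlap: the upper tail P(X >= 0) is 1
  ora0 <- hypergeom_ora(universe[10:13], list(S = universe[1:5]), universe)
  expect_equal(ora0$p, 1)
  # module = set = universe: the overlap is forced
  ora1 <- hypergeom_ora(universe, list(S = universe), universe)
  expect_equal(ora1$p, 1)
  expect_error(hypergeom_ora(module, sets, character(0)), class = "amendr_input_error")
})

test_that("hypergeometric p matches exhaustive enumeration on small universes", {
  # oracle: count modules of the same size with overlap >= observed
  set.seed(31)
  universe <- letters[1:10]
  all_modules <- utils::combn(10, 4)
  for (rep in 1:5) {
    set_genes <- sample(universe, sample(3:6, 1))
    module <- sample(universe, 4)
    obs <- length(intersect(module, set_genes))
    tail_count <- sum(apply(all_modules, 2, function(idx) {
      length(intersect(universe[idx], set_genes)) >= obs
    }))
    p_enum <- tail_count / ncol(all_modules)
    ora <- hypergeom_ora(module, list(S = set_genes), universe)
    expect_equal(ora$p, p_enum, tolerance = 1e-12)
  }
})

test_that("BH adjustment preserves the raw p ranking", {
  set.seed(8)
  universe <- sprintf("u%03d", 1:60)
  sets <- lapply(1:12, function(i) sample(universe, sample(5:15, 1)))
  names(sets) <- paste0("S", 1:12)
  ora <- hypergeom_ora(sample(universe, 10), sets, universe)
  expect_true(all(ora$p_adj >= ora$p))
  expect_true(all(diff(ora$p_adj[order(ora$p)]) >= -1e-15))
})

test_that("EHR collapses to 0 and 1 in the degenerate permutation regimes", {
  universe <- sprintf("u%02d", 1:20)
  sets <- list(S1 = universe[1:5], S2 = universe[6:10])
  observed <- list(universe[1:5])   # perfectly enriched for S1
  # permuted runs that reproduce the original module: null dominates, EHR 0
  same <- function(m) observed
  res_same <- ehr(observed, same, sets, universe, M = 5)
  expect_true(all(res_same$pathways$empirical_p == 1))
  expect_equal(res_same$ehr, 0)
  # permuted runs with no enrichment at all: EHR 1
  null_runner <- function(m) list(universe[c(2, 7, 12, 17)])
  res_null <- ehr(observed, null_runner, sets, universe, M = 5)
  expect_equal(res_null$ehr, 1)
  expect_equal(res_null$mehr$mehr[1], 1)
})

test_that("empirical p-values live on the permutation grid", {
  universe <- sprintf("u%02d", 1:30)
  sets <- list(A = universe[1:6], B = universe[7:12])
  observed <- list(universe[1:6])
  set.seed(12)
  runner <- function(m) list(sample(universe, 6))
  M <- 8
  res <- ehr(observed, runner, sets, universe, M = M)
  expect_true(all(res$pathways$empirical_p %in% ((0:M) / M)))
})

test_that("empirical p counts null scores at least as large as observed", {
  # direct check of the tail rule on a crafted null: scores 0,1,2,3 vs observed 2
  universe <- sprintf("u%02d", 1:40)
  target <- universe[1:10]
  sets <- list(S = target)
  # modules engineered so -log10(p) takes 4 distinct increasing values
  mods <- list(universe[11:20], universe[c(1, 12:20)],
               universe[c(1:5, 16:20)], universe[1:10])
  scores <- vapply(mods, function(m) {
    -log10(hypergeom_ora(m, sets, universe)$p)
  }, 0)
  expect_true(all(diff(scores) > 0))
  runner <- function(m) mods[m]
  res <- ehr(list(mods[[3]]), runner, sets, universe, M = 4)
  expect_equal(res$pathways$empirical_p, 2 / 4)
})

test_that("jaccard and nested indices follow their set formulas", {
  a <- letters[1:4]; b <- letters[3:8]
  expect_equal(jaccard(a, a), 1)
  expect_equal(nested(a, a), 1)
  expect_equal(jaccard(a, letters[10:12]), 0)
  expect_equal(nested(a, letters[10:12]), 0)
  expect_equal(jaccard(a, b), 2 / 8)
  expect_equal(nested(a, b), 2 / 4)
  expect_error(jaccard(character(0), a), class = "amendr_input_error")
  set.seed(44)
  pool <- sprintf("g%03d", 1:50)
  for (i in 1:200) {
    x <- sample(pool, sample(1:20, 1))
    y <- sample(pool, sample(1:20, 1))
    expect_gte(nested(x, y), jaccard(x, y))
    expect_true(jaccard(x, y) >= 0 && jaccard(x, y) <= 1)
  }
})

test_that("bootstrap index p-values behave at the extremes and under a fixed seed", {
  universe <- sprintf("g%03d", 1:60)
  # disjoint modules: observed 0 is never exceeded from below, p = 1
  res <- bootstrap_index_pvalue(universe[1:10], universe[21:30], universe,
                                B = 200, seed = 9)
  expect_equal(res$p_value, c(1, 1))
  # identical large modules: observed 1 beats essentially every resample
  res2 <- bootstrap_index_pvalue(universe[1:10], universe[1:10], universe,
                                 B = 200, seed = 9)
  expect_equal(res2$observed, c(1, 1))
  expect_lt(res2$p_value[1], 0.05)
  # reproducible to the exact value under a fixed seed
  r1 <- bootstrap_index_pvalue(universe[1:12], universe[7:20], universe,
                               B = 500, seed = 123)
  r2 <- bootstrap_index_pvalue(universe[1:12], universe[7:20], universe,
                               B = 500, seed = 123)
  expect_identical(r1, r2)
})

test_that("permuting gene statistics shuffles ECIs but keeps their distribution", {
  sim <- small_instance(seed = 3)
  set.seed(77)
  perm <- permute_gene_stats(sim$stats)
  expect_identical(perm$gene_id, sim$stats$gene_id)
  expect_identical(sort(perm$eci), sort(sim$stats$eci))
  expect_false(identical(perm$eci, sim$stats$eci))
})
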
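test_that("ECI reproduces hand-evaluated cases exactly", {
  # halved in one contrast, doubled in the other, both certain: exactly inverse
  expect_identical(compute_eci(-1, 0, 1, 0), -1)
  # a p-value of 1 wipes out the evidence
  expect_identical(compute_eci(1, 1, 1, 0), 0)
  # (1/2) * (1 - 0.2)
  expect_equal(compute_eci(2, 0.1, 1, 0.2), 0.4, tolerance = 1e-15)
  # zero effect in either contrast gives zero, including the 0/0 corner
  expect_identical(compute_eci(0, 0.1, 3, 0.1), 0)
  expect_identical(compute_eci(0, 0, 0, 0), 0)
})

test_that("ECI is bounded, symmetric in the contrasts, and sign follows the betas", {
  set.seed(42)
  b1 <- rnorm(500, sd = 2); b2 <- rnorm(500, sd = 2)
  q1 <- runif(500); q2 <- runif(500)
  e <- compute_eci(b1, q1, b2, q2)
  expect_true(all(e >= -1 & e <= 1))
  expect_equal(e, compute_eci(b2, q2, b1, q1), tolerance = 1e-15)
  nz <- e != 0
  expect_identical(sign(e[nz]), sign(b1[nz] * b2[nz]))
})

test_that("|ECI| decreases as p-values worsen or effect sizes diverge", {
  ps <- seq(0, 1, by = 0.05)
  eci_p <- abs(compute_eci(1.2, ps, -0.7, 0))
  expect_true(all(diff(eci_p) <= 0))
  ratios <- 2^seq(0, 4, by = 0.25)        # increasing |log ratio| of betas
  eci_r <- abs(compute_eci(1, 0.1, ratios, 0.1))
  expect_true(all(diff(eci_r) <= 0))
})

test_that("ECI rejects invalid p-values and non-finite betas", {
  expect_error(compute_eci(1, -0.1, 1, 0), class = "amendr_input_error")
  expect_error(compute_eci(1, 0, 1, 1.5), class = "amendr_input_error")
  expect_error(compute_eci(Inf, 0.5, 1, 0.5), class = "amendr_input_error")
  expect_error(compute_eci(1, NA, 1, 0.5), class = "amendr_input_error")
})

test_that("standardization centers, scales, and flips by the direction of interest", {
  expect_equal(standardize_eci(c(-1, 0, 1), s = -1), c(1, 0, -1), tolerance = 1e-15)
  set.seed(1)
  e <- rnorm(100)
  z <- standardize_eci(e, s = 1)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize_eci(e, s = -1), -z, tolerance = 1e-15)
  expect_error(standardize_eci(rep(0.3, 5), s = 1), class = "amendr_input_error")
  expect_error(standardize_eci(0.3, s = 1), class = "amendr_input_error")
})

test_that("seed vectors weight the direction of interest and sum to one", {
  expect_equal(seed_vector(c(-0.8, 0.4, 0), s = -1, c = 0.5),
               c(0.8, 0.2, 0), tolerance = 1e-15)
  set.seed(3)
  for (i in 1:20) {
    e <- rnorm(50)
    p0 <- seed_vector(e, s = sample(c(-1, 1), 1), c = runif(1))
    expect_true(all(p0 >= 0))
    expect_equal(sum(p0), 1, tolerance = 1e-12)
  }
  # invariant to uniform rescaling of the ECI vector
  e <- rnorm(30)
  expect_equal(seed_vector(e, -1, 0.5), seed_vector(5 * e, -1, 0.5),
               tolerance = 1e-12)
  # c = 1 collapses the indicator: weights proportional to |e|
  expect_equal(seed_vector(e, -1, 1), abs(e) / sum(abs(e)), tolerance = 1e-12)
  # a gene against the DOI gets exactly c times the weight of its mirror image
  p0 <- seed_vector(c(-0.6, 0.6), s = -1, c = 0.5)
  expect_equal(p0[2] / p0[1], 0.5, tolerance = 1e-12)
  expect_error(seed_vector(c(0, 0), s = -1, c = 0.5),
               class = "amendr_algorithm_error")
})

test_that("gene statistics are assembled from two DE contrasts by exact id match", {
  de1 <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        log2fc = c(-1, 2, 0.5), pvalue = c(0, 0.1, 0.2),
                        significant = c(TRUE, TRUE, FALSE))
  de2 <- tibble::tibble(gene_id = c("g2", "g1", "g4"),
                        log2fc = c(1, 1, 3), pvalue = c(0.2, 0, 0.1),
                        significant = c(TRUE, FALSE, TRUE))
  st <- prepare_gene_stats(de1, de2, s = -1)
  expect_identical(st$gene_id, c("g1", "g2"))
  expect_equal(st$eci, compute_eci(st$beta1, st$p1, st$beta2, st$p2))
  expect_equal(st$eci[1], -1)
  expect_equal(st$eci[2], 0.4, tolerance = 1e-12)
  expect_identical(st$significant, c(FALSE, TRUE))
  expect_error(prepare_gene_stats(de1[0, ], de2, s = -1), class = "amendr_input_error")
})
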
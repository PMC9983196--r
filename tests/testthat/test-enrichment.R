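test_that("the normal upper tail reproduces its defining identities", {
  expect_equal(normal_p_from_z(0), 0.5)
  for (z in c(-3.1, -0.4, 0, 1.2, 4.64)) {
    expect_equal(normal_p_from_z(z) + normal_p_from_z(-z), 1)
  }
  expect_error(normal_p_from_z(Inf), "finite")
})

test_that("overlap percentages round half up", {
  expect_identical(overlap_percent(153, 480), 32L)
  expect_identical(overlap_percent(45, 115), 39L)
  expect_identical(overlap_percent(0, 100), 0L)
  expect_identical(overlap_percent(1, 8), 13L)   # 12.5 rounds up
  expect_error(overlap_percent(1, 0), "> 0")
  expect_error(overlap_percent(5, 4), "k")
})

test_that("the 2x2 chi-square matches the closed form", {
  prop <- matrix(c(10, 5, 20, 10), 2)
  res <- chisq_2x2(prop)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  t2 <- matrix(c(10, 20, 20, 10), 2)
  res2 <- chisq_2x2(t2)
  # N(ad - bc)^2 / product of margins
  expect_equal(res2$statistic, 60 * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30))
  expect_equal(res2$statistic, 6.667, tolerance = 1e-3)
  expect_equal(res2$p_value, 0.0098, tolerance = 1e-2)
  expect_error(chisq_2x2(matrix(c(0, 1, 0, 2), 2)), "margins")
})

boundary_toy <- function() {
  # 10 unit boundaries at 100kb spacing; features sit exactly on the first 3
  pool <- tibble::tibble(chrom = "chr1", start = (0:9) * 1e5,
                         end = (0:9) * 1e5 + 2e4)
  list(pool = pool, target = pool[1:3, ],
       features = pool[1:3, ] |> dplyr::mutate(start = start + 5e3,
                                               end = start + 100))
}

test_that("boundary enrichment matches the exhaustive C(10,3) oracle", {
  toy <- boundary_toy()
  res <- boundary_enrichment(toy$features, toy$target, toy$pool,
                             n_samples = 10000, seed = 4)
  expect_equal(res$observed, 3)
  # exhaustive oracle: every 3-subset of the 10 pool boundaries
  combos <- utils::combn(10, 3)
  counts <- apply(combos, 2, function(idx) sum(idx %in% 1:3))
  exact_mean <- mean(counts)
  exact_sd <- pop_sd(counts)
  expect_equal(res$null_mean, exact_mean, tolerance = 4 * exact_sd / sqrt(10000) / exact_mean)
  expect_equal(res$null_sd, exact_sd, tolerance = 0.05)
  expect_equal(res$z, (3 - exact_mean) / exact_sd, tolerance = 0.1)
  expect_equal(res$p, normal_p_from_z(res$z))
})

test_that("boundary enrichment edge cases and reproducibility", {
  toy <- boundary_toy()
  none <- toy$features[0, ]
  res0 <- boundary_enrichment(none, toy$target, toy$pool, n_samples = 200,
                              seed = 1)
  expect_equal(res0$observed, 0)
  expect_true(res0$z <= 0 || res0$indeterminate)

  r1 <- boundary_enrichment(toy$features, toy$target, toy$pool,
                            n_samples = 500, seed = 99)
  r2 <- boundary_enrichment(toy$features, toy$target, toy$pool,
                            n_samples = 500, seed = 99)
  expect_identical(r1, r2)
  expect_error(boundary_enrichment(toy$features, toy$pool, toy$target,
                                   n_samples = 10, seed = 1),
               "pool smaller")
})

gene_toy <- function() {
  genes <- tibble::tibble(
    chrom = "chr1",
    start = c(0, 2e5, 4e5, 6e5),
    end = c(1e5, 3e5, 5e5, 7e5),
    name = paste0("g", 1:4),
    stratum = "coding"
  )
  list(
    universe = genes,
    interest = genes[1:2, ],
    astads = tibble::tibble(chrom = "chr1", start = 0, end = 1.5e5),  # covers g1
    tads = tibble::tibble(chrom = "chr1", start = 0, end = 1e6)
  )
}

test_that("stratified gene enrichment matches the exhaustive C(4,2) oracle", {
  toy <- gene_toy()
  res <- stratified_gene_enrichment(toy$interest, toy$universe, toy$astads,
                                    toy$tads, n_samples = 10000, seed = 11)
  expect_equal(res$observed, 1)
  combos <- utils::combn(4, 2)
  counts <- apply(combos, 2, function(idx) sum(idx == 1))
  expect_equal(res$null_mean, mean(counts), tolerance = 0.03)
  expect_equal(res$null_sd, pop_sd(counts), tolerance = 0.05)
})

test_that("interest set equal to the universe gives z = 0", {
  toy <- gene_toy()
  res <- stratified_gene_enrichment(toy$universe, toy$universe, toy$astads,
                                    toy$tads, n_samples = 100, seed = 2)
  expect_equal(res$z, 0)
  expect_false(res$indeterminate)
})

test_that("stratified enrichment applies exclusions and validates strata", {
  toy <- gene_toy()
  # blacklist removes g1 -> observed drops to 0
  res <- stratified_gene_enrichment(
    toy$interest, toy$universe, toy$astads, toy$tads,
    blacklist = tibble::tibble(chrom = "chr1", start = 0, end = 5e4),
    n_samples = 100, seed = 3
  )
  expect_equal(res$observed, 0)

  big <- dplyr::mutate(toy$interest, stratum = c("coding", "lnc"))
  expect_error(
    stratified_gene_enrichment(big, toy$universe, toy$astads, toy$tads,
                               n_samples = 10, seed = 1),
    "stratum"
  )
  expect_error(
    stratified_gene_enrichment(
      dplyr::mutate(toy$interest, name = c("zz", "g2")),
      toy$universe, toy$astads, toy$tads, n_samples = 10, seed = 1
    ),
    "present in the universe"
  )
})

test_that("same seed gives bit-identical enrichment results", {
  toy <- gene_toy()
  r1 <- stratified_gene_enrichment(toy$interest, toy$universe, toy$astads,
                                   toy$tads, n_samples = 300, seed = 7)
  r2 <- stratified_gene_enrichment(toy$interest, toy$universe, toy$astads,
                                   toy$tads, n_samples = 300, seed = 7)
  expect_identical(r1, r2)
})
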
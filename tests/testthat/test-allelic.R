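test_that("joint normalization leaves identical alleles unchanged", {
  v <- random_symmetric(12, seed = 1) + 1
  g <- make_grid(12)
  pair <- allele_pair(contact_matrix(g, v), contact_matrix(g, v))
  norm <- joint_normalize(pair)
  expect_equal(norm$pair$a1$values, v, tolerance = 1e-9)
  expect_equal(norm$pair$a2$values, v, tolerance = 1e-9)
  expect_equal(norm$model$fitted_curve$log2_ratio, rep(0, 12),
               tolerance = 1e-9)
})

test_that("a constant 2x coverage ratio is absorbed symmetrically", {
  v <- random_symmetric(12, seed = 2) + 1
  g <- make_grid(12)
  pair <- allele_pair(contact_matrix(g, v), contact_matrix(g, 2 * v))
  norm <- joint_normalize(pair)
  expect_equal(norm$model$fitted_curve$log2_ratio, rep(1, 12),
               tolerance = 1e-9)
  expect_equal(norm$pair$a1$values, v * sqrt(2), tolerance = 1e-9)
  expect_equal(norm$pair$a2$values, 2 * v / sqrt(2), tolerance = 1e-9)
})

test_that("joint normalization preserves the cellwise product", {
  v1 <- random_symmetric(20, seed = 3) + 0.5
  v2 <- random_symmetric(20, seed = 4) + 0.5
  g <- make_grid(20)
  norm <- joint_normalize(allele_pair(contact_matrix(g, v1),
                                      contact_matrix(g, v2)))
  expect_equal(norm$pair$a1$values * norm$pair$a2$values, v1 * v2,
               tolerance = 1e-9)
})

test_that("a planted smooth distance bias is recovered by the fit", {
  cfg <- simulation_config(chrom_length = 3e6, seed = 11,
                           base_intensity = 2000)
  lam <- expected_matrix(cfg, "A1")
  n <- nrow(lam)
  d <- abs(row(lam) - col(lam))
  g_of_d <- 2^(0.8 * sin(d / 100))          # smooth log2 bias curve
  mats <- withr::with_seed(5, {
    draw <- function(l) {
      m <- matrix(0, n, n)
      ut <- upper.tri(m, diag = TRUE)
      m[ut] <- rpois(sum(ut), l[ut])
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    }
    list(a1 = draw(lam), a2 = draw(lam * g_of_d))
  })
  grid <- bin_grid(cfg$chrom, cfg$chrom_length, cfg$bin_size)
  norm <- joint_normalize(allele_pair(contact_matrix(grid, mats$a1),
                                      contact_matrix(grid, mats$a2)))
  fit <- norm$model$fitted_curve
  interior <- fit$distance >= 5 & fit$distance <= 200
  planted <- 0.8 * sin(fit$distance / 100)
  expect_lt(max(abs(fit$log2_ratio[interior] - planted[interior])), 0.1)
  # post-fit mean log ratio per distance is near zero
  o1 <- norm$pair$a1$values
  o2 <- norm$pair$a2$values
  joint <- upper.tri(o1, diag = TRUE) & o1 > 0 & o2 > 0
  dd <- abs(row(o1) - col(o1))[joint]
  resid <- tapply(log2(o2[joint] / o1[joint]), dd, mean)
  resid <- resid[as.numeric(names(resid)) %in% 5:200]
  # per-distance means scatter with sampling noise; on average they are ~0
  expect_lt(mean(abs(resid)), 0.05)
})

test_that("too few joint-nonzero cells is an error", {
  g <- make_grid(4)
  v <- matrix(0, 4, 4)
  diag(v) <- 1
  pair <- allele_pair(contact_matrix(g, v), contact_matrix(g, v))
  expect_error(joint_normalize(pair), "insufficient overlap")
})

test_that("subtraction of identical alleles is zero and swap negates", {
  v <- random_symmetric(12, seed = 6) + 1
  g <- make_grid(12)
  pair <- allele_pair(contact_matrix(g, v), contact_matrix(g, v))
  s <- subtraction(pair)
  expect_equal(s$values, matrix(0, 12, 12), tolerance = 1e-12)

  v2 <- random_symmetric(12, seed = 7) + 1
  pair2 <- allele_pair(contact_matrix(g, v), contact_matrix(g, v2))
  expect_equal(subtraction(swap_alleles(pair2))$values,
               -subtraction(pair2)$values, tolerance = 1e-12)
})

test_that("a doubled cell appears as the only signed entry after O/E subtraction", {
  # hand-computed per-diagonal means on a 3x3 fixture
  v1 <- matrix(c(4, 2, 0, 2, 4, 2, 0, 2, 4), 3)
  v2 <- v1
  v2[1, 2] <- v2[2, 1] <- 4       # A2 doubles one off-diagonal cell
  g <- make_grid(3)
  s <- subtraction(allele_pair(contact_matrix(g, v1), contact_matrix(g, v2)))
  # A1 O/E off-diagonal: 2/2 = 1; A2 off-diagonal mean = 3 -> (4/3, 2/3)
  expect_equal(s$values[1, 2], 4 / 3 - 1)
  expect_equal(s$values[2, 3], 2 / 3 - 1)
  expect_gt(s$values[1, 2], 0)
  expect_equal(s$values, t(s$values))
  expect_equal(diag(s$values), rep(0, 3))
})

test_that("the full normalize-subtract-denoise chain is antisymmetric under allele swap", {
  sim <- simulate_pair(simulation_config(chrom_length = 1e6, seed = 21,
                                         coverage_a2 = 1.3))
  s_fwd <- subtraction_pipeline(sim$pair)
  s_rev <- subtraction_pipeline(swap_alleles(sim$pair))
  expect_equal(s_rev$values, -s_fwd$values, tolerance = 1e-9)
})

test_that("median filter: identity at kernel 1, no-op on constants, removes spikes", {
  v <- random_signed_symmetric(9, seed = 8)
  s <- make_subtraction(v)
  expect_equal(median_denoise(s, 1)$values, v)
  cons <- make_subtraction(matrix(2, 9, 9))
  expect_equal(median_denoise(cons, 3)$values, matrix(2, 9, 9))
  spike <- matrix(0, 9, 9)
  spike[3, 6] <- spike[6, 3] <- 10
  sp <- median_denoise(make_subtraction(spike), 3)
  expect_equal(sp$values, matrix(0, 9, 9))
  expect_error(median_denoise(s, 2), "odd")
})

test_that("median filter keeps masked cells masked and excludes them from neighbors", {
  v <- random_signed_symmetric(9, seed = 9)
  s <- make_subtraction(v, mask = c(rep(FALSE, 4), TRUE, rep(FALSE, 4)))
  out <- median_denoise(s, 3)
  expect_true(all(is.na(out$values[5, ])))
  # neighborhood of (4,4) excludes the masked row/col 5
  nb <- as.vector(s$values[3:5, 3:5])
  expect_equal(out$values[4, 4], median(nb, na.rm = TRUE))
  expect_equal(out$values, t(out$values))
})

test_that("null pairs give a denoised subtraction mean within 3 SE of zero", {
  sim <- simulate_pair(simulation_config(chrom_length = 2e6, seed = 31))
  s <- subtraction_pipeline(sim$pair)
  cells <- s$values[upper.tri(s$values, diag = TRUE)]
  cells <- cells[!is.na(cells)]
  se <- sd(cells) / sqrt(length(cells))
  expect_lt(abs(mean(cells)), 3 * se)
})
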
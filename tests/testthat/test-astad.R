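test_that("domain scores are upper-triangle absolute sums with mask accounting", {
  g <- make_grid(6)
  zeros <- make_subtraction(matrix(0, 6, 6), g)
  d <- tibble::tibble(chrom = g$chrom, start = 0, end = 2e4)
  expect_equal(domain_score(zeros, d)$abs_sum, 0)

  v <- matrix(0, 6, 6)
  v[1, 1] <- 1
  v[1, 2] <- v[2, 1] <- -2
  v[2, 2] <- 3
  sc <- domain_score(make_subtraction(v, g), d)
  expect_equal(sc$abs_sum, 6)
  expect_equal(sc$n_cells, 3)
  expect_equal(sc$frac_informative, 1)

  masked <- make_subtraction(matrix(1, 6, 6), g,
                             mask = c(TRUE, TRUE, rep(FALSE, 4)))
  scm <- domain_score(masked, d)
  expect_equal(scm$abs_sum, 0)
  expect_equal(scm$frac_informative, 0)
  expect_error(
    domain_score(zeros, tibble::tibble(chrom = g$chrom, start = 0, end = 9e4)),
    "outside"
  )
})

test_that("background windows enumerate diagonal-anchored squares", {
  g <- make_grid(10)
  v <- random_signed_symmetric(10, seed = 2)
  s <- make_subtraction(v, g)
  bg <- background_distribution(s, 3)
  expect_length(bg, 8)

  # Toeplitz values -> identical scores in every interior window
  tp <- outer(1:10, 1:10, function(i, j) (-1)^abs(i - j) / (abs(i - j) + 1))
  bgt <- background_distribution(make_subtraction(tp, g), 4)
  expect_equal(diff(bgt), rep(0, 6), tolerance = 1e-12)
  expect_error(background_distribution(s, 11), "exceeds")
})

test_that("window scores agree with exhaustive enumeration on a random fixture", {
  n <- 20
  v <- random_signed_symmetric(n, seed = 7)
  mask <- rep(FALSE, n); mask[13] <- TRUE
  s <- make_subtraction(v, make_grid(n), mask = mask)
  for (w in c(2, 5, 9)) {
    oracle <- vapply(1:(n - w + 1), function(p) {
      abs_sum_oracle(s$values, p, p + w - 1)
    }, numeric(1))
    expect_equal(background_distribution(s, w), oracle, tolerance = 1e-12)
  }
  # stride > 1 subsamples the same enumeration
  expect_equal(background_distribution(s, 5, stride = 3),
               vapply(seq(1, 16, 3), function(p) abs_sum_oracle(s$values, p, p + 4),
                      numeric(1)),
               tolerance = 1e-12)
})

test_that("Z-scores use the population sd and a strict threshold", {
  sc <- tibble::tibble(chrom = "c", start = 0, end = 2e4, size_bins = 2L,
                       abs_sum = 20, n_cells = 3L, frac_informative = 1)
  z <- z_score(sc, 1:10)
  expect_equal(z$z, (20 - 5.5) / sqrt(mean((1:10 - 5.5)^2)))
  expect_equal(z$z, 5.049, tolerance = 1e-3)
  expect_true(z$is_astad)

  flat <- z_score(dplyr::mutate(sc, abs_sum = 4), rep(4, 8))
  expect_equal(flat$z, 0)
  expect_false(flat$is_astad)

  indet <- z_score(dplyr::mutate(sc, abs_sum = 5), rep(4, 8))
  expect_true(indet$indeterminate)
  expect_false(indet$is_astad)

  # exactly at the threshold is NOT called (strict >)
  bg <- 1:10
  mu <- mean(bg); sg <- sqrt(mean((bg - mu)^2))
  at2 <- z_score(dplyr::mutate(sc, abs_sum = mu + 2 * sg), bg)
  expect_equal(at2$z, 2)
  expect_false(at2$is_astad)
})

test_that("z is invariant to global rescaling and to allele swap", {
  n <- 30
  v <- random_signed_symmetric(n, seed = 5)
  g <- make_grid(n)
  doms <- tibble::tibble(chrom = g$chrom, start = c(0, 1e5), end = c(1e5, 2e5))
  z1 <- call_astads(make_subtraction(v, g), doms)$z
  expect_equal(call_astads(make_subtraction(7.3 * v, g), doms)$z, z1,
               tolerance = 1e-9)
  expect_equal(call_astads(make_subtraction(-v, g), doms)$z, z1,
               tolerance = 1e-12)
})

test_that("low-informative domains are flagged and never called", {
  n <- 20
  v <- random_signed_symmetric(n, seed = 6) + 5
  v <- (v + t(v)) / 2
  mask <- c(rep(TRUE, 4), rep(FALSE, n - 4))
  s <- make_subtraction(v, make_grid(n), mask = mask)
  doms <- tibble::tibble(chrom = "chrT", start = 0, end = 5e4)  # 4 of 5 bins masked
  calls <- call_astads(s, doms)
  expect_true(calls$flagged_uninformative)
  expect_false(calls$is_astad)
})

test_that("an empty domain list yields an empty call table", {
  s <- make_subtraction(random_signed_symmetric(10, seed = 1))
  out <- call_astads(s, tibble::tibble(chrom = character(), start = numeric(),
                                       end = numeric(), size_bins = integer()))
  expect_s3_class(out, "astad_calls")
  expect_equal(nrow(out), 0)
})

test_that("increasing the planted allelic multiplier never decreases the planted z", {
  zs <- vapply(c(1, 1.5, 2, 3), function(delta) {
    sim <- simulate_pair(recovery_config(seed = 101, delta = delta))
    s <- subtraction_pipeline(sim$pair)
    calls <- call_astads(s, tad_domains(sim$truth$tads, sim$pair$a1$grid))
    planted <- calls$start %in% sim$truth$astads$start
    min(calls$z[planted])
  }, numeric(1))
  expect_true(all(diff(zs) >= 0))
})

test_that("calls are ordered by coordinate and carry one row per domain", {
  sim <- simulate_pair(recovery_config(seed = 55))
  s <- subtraction_pipeline(sim$pair)
  doms <- tad_domains(sim$truth$tads, sim$pair$a1$grid)
  calls <- call_astads(s, doms[sample(nrow(doms)), ])
  expect_equal(nrow(calls), nrow(doms))
  expect_false(is.unsorted(calls$start))
})
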
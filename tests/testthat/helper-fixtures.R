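# shared fixture builders (all fixtures are generated in code)

make_grid <- function(n_bins, bin_size = 1e4, chrom = "chrT") {
  bin_grid(chrom, n_bins * bin_size, bin_size)
}

# symmetric random matrix with positive entries
random_symmetric <- function(n, seed = 1, min = 0.1, max = 2) {
  withr::with_seed(seed, {
    a <- matrix(stats::runif(n * n, min, max), n)
    a + t(a)
  })
}

# symmetric signed random matrix (for subtraction fixtures)
random_signed_symmetric <- function(n, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(stats::rnorm(n * n), n)
    (a + t(a)) / 2
  })
}

make_subtraction <- function(values, grid = make_grid(nrow(values)),
                             mask = NULL) {
  as_subtraction_matrix(grid, values, mask = mask)
}

# independent fixed-point oracle for symmetric balancing (plain damped
# iteration, written without reference to the package implementation)
balance_oracle <- function(A, iters = 50000, tol = 1e-12) {
  x <- rep(1, nrow(A))
  for (i in seq_len(iters)) {
    r <- x * drop(A %*% x)
    if (max(abs(r - 1)) < tol) break
    x <- x / sqrt(r)
  }
  x
}

# brute-force upper-triangle absolute sum of a square block
abs_sum_oracle <- function(v, i0, i1) {
  s <- 0
  for (i in i0:i1) for (j in i:i1) {
    if (!is.na(v[i, j])) s <- s + abs(v[i, j])
  }
  s
}

write_triplets <- function(path, chrom, rows) {
  # rows: list of c(bin1_start, bin2_start, value)
  df <- do.call(rbind, rows)
  utils::write.table(
    data.frame(chrom, df[, 1], df[, 2], df[, 3]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  path
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
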
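#' Observed/expected distance normalization
#'
#' Divides every cell by the expected value at its genomic distance, removing
#' the power-law distance-decay trend so that long-range differences are
#' resolved on a common scale. The expected value at bin distance `d` is the
#' mean of the unmasked entries on that diagonal of this chromosome's matrix
#' (expected values are always computed per chromosome, never genome-wide).
#' Cells on diagonals whose expected value is zero are masked in the output.
#'
#' @param m A `contact_matrix`.
#' @return A `contact_matrix` with `units = "oe"`: the mean of unmasked
#'   entries on every diagonal is 1 (within floating-point tolerance).
#' @export
observed_expected <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  v <- m$values
  n <- nrow(v)
  d <- abs(row(v) - col(v))
  exp_d <- vapply(
    0:(n - 1L),
    function(k) {
      x <- v[d == k]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    },
    numeric(1)
  )
  denom <- exp_d[d + 1L]
  out <- v / denom
  out[!is.na(denom) & denom == 0] <- NA_real_
  res <- contact_matrix(m$grid, out, mask = m$mask, units = "oe")
  res$expected <- exp_d
  res
}

#' Crane-style insulation score
#'
#' For each bin `i`, averages the unmasked contacts in the square window
#' spanning rows `i - w .. i - 1` and columns `i + 1 .. i + w` (the contacts
#' that cross bin `i`), then reports `log2` of the window mean over the
#' chromosome-wide mean of window means. Local minima of the track mark
#' domain boundaries. Bins within `window_bins` of a chromosome end are
#' undefined (`NA`).
#'
#' @param m A `contact_matrix`.
#' @param window_bins Window half-width in bins (>= 1); the paper's figures do
#'   not state a window, so there is no claimed default.
#' @return A tibble with `bin`, `start`, `end` and `score` (log2 insulation),
#'   one row per bin.
#' @export
insulation_score <- function(m, window_bins) {
  stopifnot(inherits(m, "contact_matrix"))
  n <- m$grid$n_bins
  w <- as.integer(window_bins)
  if (w < 1L) abort("`window_bins` must be >= 1.")
  if (2L * w >= n) abort("`window_bins` too large for this chromosome.")
  v <- m$values
  raw <- rep(NA_real_, n)
  for (i in (w + 1L):(n - w)) {
    block <- v[(i - w):(i - 1L), (i + 1L):(i + w), drop = FALSE]
    if (!all(is.na(block))) raw[i] <- mean(block, na.rm = TRUE)
  }
  mu <- mean(raw, na.rm = TRUE)
  score <- ifelse(is.na(raw) | raw <= 0 | mu <= 0, NA_real_, log2(raw / mu))
  # windows that are uniformly zero still carry information (full insulation);
  # log2(0) is -Inf, so they are reported as NA with the mask, not as a value
  dplyr::mutate(bin_table(m$grid), score = score)
}

#' Write a per-bin track as bedGraph
#'
#' @param track A tibble with `start`, `end` and a value column (as returned
#'   by [insulation_score()]).
#' @param path Output path.
#' @param chrom Chromosome name.
#' @param value Name of the value column.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, chrom, value = "score") {
  df <- track[!is.na(track[[value]]), c("start", "end", value)]
  df <- cbind(chrom = chrom, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
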
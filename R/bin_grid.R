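#' Define a fixed-width binning of one chromosome
#'
#' A bin grid is the coordinate authority for every matrix in the package: a
#' chromosome partitioned into fixed-width, 0-based half-open bins
#' `[i * bin_size, min((i + 1) * bin_size, chrom_length))`. The last bin may be
#' shorter than `bin_size`; it is kept at full weight throughout.
#'
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param bin_size Bin width in bp. ASTAD analyses typically use 10 kb bins;
#'   compartment-scale analyses 20 kb.
#'
#' @return An object of class `bin_grid` with fields `chrom`, `chrom_length`,
#'   `bin_size` and `n_bins` (`ceiling(chrom_length / bin_size)`).
#' @examples
#' bin_grid("chr12", 1e6, 1e4)
#' @export
bin_grid <- function(chrom, chrom_length, bin_size) {
  if (!is.character(chrom) || length(chrom) != 1L) {
    abort("`chrom` must be a single chromosome name.")
  }
  chrom_length <- as.numeric(chrom_length)
  bin_size <- as.numeric(bin_size)
  if (!is.finite(bin_size) || bin_size <= 0) abort("`bin_size` must be > 0.")
  if (!is.finite(chrom_length) || chrom_length <= 0) {
    abort("`chrom_length` must be > 0.")
  }
  structure(
    list(
      chrom = chrom,
      chrom_length = chrom_length,
      bin_size = bin_size,
      n_bins = as.integer(ceiling(chrom_length / bin_size))
    ),
    class = "bin_grid"
  )
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf(
    "<bin_grid> %s: %s bp in %d bins of %s bp\n",
    x$chrom, format(x$chrom_length, big.mark = ","), x$n_bins,
    format(x$bin_size, big.mark = ",")
  ))
  invisible(x)
}

#' Bin coordinates of a grid
#'
#' @param grid A [bin_grid()].
#' @return A tibble with one row per bin: `bin` (0-based index), `start`,
#'   `end` (0-based half-open bp).
#' @export
bin_table <- function(grid) {
  stopifnot(inherits(grid, "bin_grid"))
  idx <- seq_len(grid$n_bins) - 1L
  tibble(
    bin = idx,
    start = idx * grid$bin_size,
    end = pmin((idx + 1) * grid$bin_size, grid$chrom_length)
  )
}

# bp position -> 0-based bin index; errors if not aligned to a bin start
# (used by the triplet reader, where misaligned coordinates are a format error)
coord_to_bin <- function(grid, pos, what = "coordinate") {
  bad <- pos %% grid$bin_size != 0
  if (any(bad)) {
    abort(sprintf(
      "%s %s is not a multiple of the bin size (%g bp).",
      what, format(pos[which(bad)[1]], scientific = FALSE), grid$bin_size
    ))
  }
  bin <- as.integer(pos %/% grid$bin_size)
  out <- bin < 0L | bin >= grid$n_bins
  if (any(out)) {
    abort(sprintf(
      "%s %s falls outside %s (%d bins).",
      what, format(pos[which(out)[1]], scientific = FALSE),
      grid$chrom, grid$n_bins
    ))
  }
  bin
}

same_grid <- function(a, b) {
  identical(a$chrom, b$chrom) &&
    a$chrom_length == b$chrom_length &&
    a$bin_size == b$bin_size
}
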
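#' Virtual-4C viewpoint trace
#'
#' Extracts, for each allele, the interaction-frequency trace between a
#' viewpoint locus and every bin within `flank` bp on either side — the
#' row(s) of the contact matrix anchored at the viewpoint, read as a 1-D
#' profile. Multi-bin viewpoints are averaged (not summed) so traces are
#' comparable across viewpoint sizes. Bins falling outside the chromosome are
#' reported as `NA` (undefined, not zero); the viewpoint's own bins are
#' reported but flagged.
#'
#' @param pair A (jointly normalized) `allele_pair`.
#' @param viewpoint One-row data frame with `chrom`, `start`, `end` (bp,
#'   0-based half-open) on the pair's chromosome.
#' @param flank Flank width in bp on each side (default 400,000).
#' @param smooth_bins Optional odd running-mean window (in bins) applied to
#'   each trace for plotting parity; default `NULL` (no smoothing).
#' @return A `viewpoint_trace` tibble in long format: `allele`, `bin`,
#'   `start`, `end`, `value`, `is_viewpoint`.
#' @export
viewpoint_trace <- function(pair, viewpoint, flank = 400000,
                            smooth_bins = NULL) {
  stopifnot(inherits(pair, "allele_pair"))
  grid <- pair$a1$grid
  if (viewpoint$chrom[1] != grid$chrom) {
    abort("viewpoint is not on the pair's chromosome.")
  }
  bs <- grid$bin_size
  i0 <- as.integer(viewpoint$start[1] %/% bs)
  i1 <- as.integer((viewpoint$end[1] - 1) %/% bs)
  if (i0 < 0L || i1 >= grid$n_bins || viewpoint$end[1] <= viewpoint$start[1]) {
    abort("viewpoint outside the bin grid.")
  }
  fbins <- as.integer(ceiling(flank / bs))
  jall <- (i0 - fbins):(i1 + fbins)
  inside <- jall >= 0L & jall < grid$n_bins
  one_allele <- function(m, label) {
    vals <- rep(NA_real_, length(jall))
    rows <- m$values[(i0:i1) + 1L, jall[inside] + 1L, drop = FALSE]
    v <- colMeans(rows, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    vals[inside] <- v
    if (!is.null(smooth_bins) && smooth_bins > 1L) {
      vals <- stats::filter(vals, rep(1 / smooth_bins, smooth_bins),
                            sides = 2)
      vals <- as.numeric(vals)
    }
    tibble(
      allele = label,
      bin = jall,
      start = jall * bs,
      end = pmin((jall + 1) * bs, grid$chrom_length),
      value = vals,
      is_viewpoint = jall >= i0 & jall <= i1
    )
  }
  out <- dplyr::bind_rows(
    one_allele(pair$a1, pair$labels[1]),
    one_allele(pair$a2, pair$labels[2])
  )
  attr(out, "viewpoint") <- as_tibble(viewpoint)[1, ]
  attr(out, "flank") <- flank
  class(out) <- c("viewpoint_trace", class(out))
  out
}

#' Write viewpoint traces as per-allele bedGraph files
#'
#' @param trace A `viewpoint_trace`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return The written paths, invisibly.
#' @export
write_viewpoint <- function(trace, dir, prefix = "viewpoint") {
  chrom <- attr(trace, "viewpoint")$chrom
  paths <- vapply(unique(trace$allele), function(al) {
    tr <- trace[trace$allele == al, ]
    tr <- tr[tr$bin >= 0 & !is.na(tr$value), ]
    p <- file.path(dir, sprintf("%s_%s.bedgraph", prefix, al))
    write_bedgraph(tr, p, chrom, value = "value")
    p
  }, character(1))
  invisible(paths)
}
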
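#' Construct a binned contact matrix
#'
#' A contact matrix holds symmetric, non-negative per-chromosome interaction
#' values on a [bin_grid()], together with a per-bin mask marking uninformative
#' bins (e.g. SNP deserts that cannot be haplotype-phased, or bins with no
#' observed contacts). Masked bins carry `NA` in both the matrix rows and
#' columns; unmasked entries are finite and >= 0.
#'
#' @param grid A [bin_grid()].
#' @param values A symmetric `n_bins x n_bins` numeric matrix.
#' @param mask Logical vector of length `n_bins`; `TRUE` marks a masked bin.
#'   Defaults to all unmasked. Bins that are `NA` across their whole row in
#'   `values` are also masked.
#' @param units Free-text unit label: `"raw"` counts, `"balanced"` contact
#'   frequency, or `"oe"` observed/expected ratios.
#'
#' @return An object of class `contact_matrix` with fields `grid`, `values`
#'   (masked rows/columns set to `NA`), `mask` and `units`.
#' @export
contact_matrix <- function(grid, values, mask = NULL, units = "raw") {
  stopifnot(inherits(grid, "bin_grid"))
  values <- as.matrix(values)
  n <- grid$n_bins
  if (nrow(values) != n || ncol(values) != n) {
    abort(sprintf("`values` must be %d x %d to match the grid.", n, n))
  }
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(is.logical(mask), length(mask) == n)
  mask <- mask | apply(values, 1L, function(r) all(is.na(r)))
  values[mask, ] <- NA_real_
  values[, mask] <- NA_real_
  # individual cells may be NA (cell-level masking, e.g. empty diagonals
  # after the O/E transform); everything else must be finite
  values[is.nan(values) | is.infinite(values)] <- NA_real_
  live <- values[!mask, !mask, drop = FALSE]
  live <- live[!is.na(live)]
  if (length(live)) {
    if (units != "subtraction" && any(live < 0)) {
      abort("contact values must be non-negative.")
    }
  }
  v_na <- values
  if (!isTRUE(all.equal(v_na, t(v_na), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    abort("`values` must be symmetric.")
  }
  structure(
    list(grid = grid, values = values, mask = mask, units = units),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %s, %d bins (%d masked), units = %s\n",
    x$grid$chrom, x$grid$n_bins, sum(x$mask), x$units
  ))
  invisible(x)
}

#' Read a sparse triplet contact matrix
#'
#' Reads the tab-separated sparse upper-triangle format
#' `chrom<TAB>bin1_start<TAB>bin2_start<TAB>value` (a 3-column file without the
#' chromosome column is also accepted). Starts are 0-based bp and must be
#' aligned to the grid. Records below the diagonal are mirrored above it and
#' duplicate cell records are summed. An empty file yields an all-zero matrix.
#'
#' @param path Path to the triplet text file.
#' @param grid A [bin_grid()] giving the coordinate system.
#' @param mask Optional logical per-bin mask to apply (e.g. from an explicit
#'   bin table marking absent bins). Bins never observed in the file are *not*
#'   masked implicitly.
#' @return A `contact_matrix` of raw counts.
#' @seealso [write_contacts()]
#' @export
read_contacts <- function(path, grid, mask = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  n <- grid$n_bins
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = NA, stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        data.frame()
      } else {
        stop(e)
      }
    }
  )
  if (nrow(df) == 0L) {
    return(contact_matrix(grid, matrix(0, n, n), mask = mask))
  }
  if (ncol(df) == 4L) {
    df <- df[df[[1]] == grid$chrom, -1, drop = FALSE]
  } else if (ncol(df) != 3L) {
    abort("triplet file must have 3 or 4 tab-separated columns.")
  }
  if (nrow(df) == 0L) {
    return(contact_matrix(grid, matrix(0, n, n), mask = mask))
  }
  val <- as.numeric(df[[3]])
  if (any(!is.finite(val)) || any(val < 0)) {
    abort("triplet values must be finite and non-negative.")
  }
  i <- coord_to_bin(grid, as.numeric(df[[1]]), "bin1_start")
  j <- coord_to_bin(grid, as.numeric(df[[2]]), "bin2_start")
  # mirror below-diagonal records, then accumulate duplicates
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  m <- matrix(0, n, n)
  acc <- tapply(val, list(lo, hi), sum)
  li <- as.integer(rownames(acc))[row(acc)] + 1L
  lj <- as.integer(colnames(acc))[col(acc)] + 1L
  keep <- !is.na(acc)
  m[cbind(li[keep], lj[keep])] <- acc[keep]
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  contact_matrix(grid, m, mask = mask)
}

#' Write a contact matrix as sparse triplet text
#'
#' Writes the upper triangle (including the diagonal) of non-zero, unmasked
#' cells as `chrom<TAB>bin1_start<TAB>bin2_start<TAB>value`. Masked bins are
#' absent from the output. The round trip `read_contacts(write_contacts(m))`
#' is lossless for integer counts.
#'
#' @param m A `contact_matrix` or `subtraction_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(m, path) {
  grid <- m$grid
  v <- m$values
  ut <- upper.tri(v, diag = TRUE)
  keep <- ut & !is.na(v) & v != 0
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(
    chrom = grid$chrom,
    bin1_start = (idx[, 1] - 1L) * grid$bin_size,
    bin2_start = (idx[, 2] - 1L) * grid$bin_size,
    value = v[keep]
  )
  df <- df[order(df$bin1_start, df$bin2_start), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# upper-triangle (incl. diagonal) index matrix helper
upper_cells <- function(n) which(upper.tri(matrix(0, n, n), diag = TRUE))
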
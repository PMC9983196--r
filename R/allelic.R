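#' Pair the two allelic matrices of one sample
#'
#' Binds the maternal/paternal (A1/A2) haplotype-resolved contact matrices of
#' one chromosome into a single object. The two matrices must share a grid;
#' their masks are combined (union), since a bin that cannot be phased on one
#' allele is uninformative for allelic comparison on both.
#'
#' @param a1,a2 `contact_matrix` objects on identical grids.
#' @param labels Character vector of length 2 naming the alleles.
#' @return An object of class `allele_pair`.
#' @export
allele_pair <- function(a1, a2, labels = c("A1", "A2")) {
  stopifnot(inherits(a1, "contact_matrix"), inherits(a2, "contact_matrix"))
  if (!same_grid(a1$grid, a2$grid)) abort("allele grids differ.")
  mask <- a1$mask | a2$mask
  structure(
    list(
      a1 = contact_matrix(a1$grid, a1$values, mask = mask, units = a1$units),
      a2 = contact_matrix(a2$grid, a2$values, mask = mask, units = a2$units),
      labels = labels
    ),
    class = "allele_pair"
  )
}

#' @export
print.allele_pair <- function(x, ...) {
  cat(sprintf(
    "<allele_pair> %s vs %s on %s (%d bins, %d masked)\n",
    x$labels[1], x$labels[2], x$a1$grid$chrom, x$a1$grid$n_bins,
    sum(x$a1$mask)
  ))
  invisible(x)
}

#' Swap the two alleles of a pair
#'
#' @param pair An `allele_pair`.
#' @return The pair with alleles (and labels) exchanged.
#' @export
swap_alleles <- function(pair) {
  stopifnot(inherits(pair, "allele_pair"))
  allele_pair(pair$a2, pair$a1, labels = rev(pair$labels))
}

#' Joint loess normalization of an allele pair
#'
#' Removes distance-dependent between-allele bias before subtraction, in the
#' manner of joint loess normalization of Hi-C sample pairs: for cells where
#' both alleles are non-zero, the log ratio `M = log2(a2 / a1)` is regressed
#' on genomic distance `D` with a degree-1 locally weighted fit, and the
#' fitted correction `f(d)` is split evenly between the alleles,
#' `a1' = a1 * 2^(f(d)/2)`, `a2' = a2 * 2^(-f(d)/2)`, so the cellwise product
#' `a1 * a2` is preserved. Cells where exactly one allele is zero receive the
#' correction but contribute nothing to the fit. After correction the mean log
#' ratio per distance is approximately zero.
#'
#' The fit is performed on per-distance mean log ratios weighted by the number
#' of contributing cells (cells at the same distance share one abscissa, so
#' this is the weighted equivalent of fitting all cells). When fewer than 10
#' distinct distances are present the per-distance means are used directly.
#'
#' @param pair An `allele_pair` of raw or balanced matrices.
#' @param span Loess span (fraction of distances in each local window).
#' @return A list with `pair` (the normalized `allele_pair`) and `model`, a
#'   `normalization_model` holding `span`, the fitted curve (tibble
#'   `distance`, `log2_ratio`) and `n_cells_fit`.
#' @export
joint_normalize <- function(pair, span = 0.3) {
  stopifnot(inherits(pair, "allele_pair"))
  v1 <- pair$a1$values
  v2 <- pair$a2$values
  n <- nrow(v1)
  ut <- upper.tri(v1, diag = TRUE)
  joint <- ut & !is.na(v1) & !is.na(v2) & v1 > 0 & v2 > 0
  if (sum(joint) < 10L) abort("insufficient overlap: fewer than 10 joint-nonzero cells.")
  d_all <- abs(row(v1) - col(v1))
  M <- log2(v2[joint] / v1[joint])
  D <- d_all[joint]
  per_d <- tapply(M, D, mean)
  cnt <- tapply(M, D, length)
  dd <- as.numeric(names(per_d))
  if (length(dd) < 30L) {
    # too few distinct distances for a stable local fit: use the exact
    # per-distance means (the limit of the fit as span -> 0)
    fit_at <- stats::approxfun(dd, per_d, rule = 2)
  } else {
    lo <- stats::loess(y ~ x, data = data.frame(x = dd, y = as.numeric(per_d)),
                       weights = as.numeric(cnt), span = span, degree = 1,
                       control = stats::loess.control(surface = "direct"))
    pr <- predict(lo, newdata = data.frame(x = dd))
    fit_at <- stats::approxfun(dd, pr, rule = 2)
  }
  f <- fit_at(0:(n - 1L))
  fmat <- matrix(f[d_all + 1L], n, n)
  a1p <- v1 * 2^(fmat / 2)
  a2p <- v2 * 2^(-fmat / 2)
  model <- structure(
    list(
      span = span,
      fitted_curve = tibble(distance = 0:(n - 1L), log2_ratio = f),
      n_cells_fit = sum(joint)
    ),
    class = "normalization_model"
  )
  out <- allele_pair(
    contact_matrix(pair$a1$grid, a1p, mask = pair$a1$mask, units = "normalized"),
    contact_matrix(pair$a2$grid, a2p, mask = pair$a2$mask, units = "normalized"),
    labels = pair$labels
  )
  list(pair = out, model = model)
}

#' @export
print.normalization_model <- function(x, ...) {
  cat(sprintf(
    "<normalization_model> span %.2f, fit on %d joint-nonzero cells\n",
    x$span, x$n_cells_fit
  ))
  invisible(x)
}

#' Allelic subtraction matrix
#'
#' Observed/expected-transforms each allele of a jointly normalized pair and
#' subtracts them cellwise (`A2 - A1`, on the linear O/E scale). Positive
#' values mark A2 enrichment, negative values A1 enrichment. The output is
#' antisymmetric under allele swap and masked wherever either allele is
#' masked.
#'
#' @param pair A jointly normalized `allele_pair` (see [joint_normalize()]).
#' @return A `subtraction_matrix`: a `contact_matrix` subclass with signed
#'   values and `units = "subtraction"`.
#' @export
subtraction <- function(pair) {
  stopifnot(inherits(pair, "allele_pair"))
  oe1 <- observed_expected(pair$a1)
  oe2 <- observed_expected(pair$a2)
  vals <- oe2$values - oe1$values
  out <- contact_matrix(pair$a1$grid, vals, mask = oe1$mask | oe2$mask,
                        units = "subtraction")
  class(out) <- c("subtraction_matrix", class(out))
  out
}

#' Construct a subtraction matrix from raw values
#'
#' Wraps an externally computed (or hand-built) symmetric signed matrix of
#' allelic differences as a `subtraction_matrix`, e.g. when importing the
#' triplet export of another run.
#'
#' @param grid A [bin_grid()].
#' @param values Symmetric numeric matrix of signed differences (A2 - A1).
#' @param mask Optional per-bin logical mask.
#' @return A `subtraction_matrix`.
#' @export
as_subtraction_matrix <- function(grid, values, mask = NULL) {
  out <- contact_matrix(grid, values, mask = mask, units = "subtraction")
  class(out) <- c("subtraction_matrix", class(out))
  out
}

#' Median-filter denoising of a subtraction matrix
#'
#' Replaces each unmasked cell by the median of the unmasked cells in its
#' `kernel_bins x kernel_bins` neighborhood, removing isolated single-cell
#' noise while preserving regions of consistent directional bias. Masked
#' cells stay masked and are excluded from their neighbors' medians. The
#' kernel always contains the cell itself, so output symmetry follows from
#' input symmetry.
#'
#' @param s A `subtraction_matrix`.
#' @param kernel_bins Odd kernel width in bins; `1` is the identity. The
#'   default 3 is the smallest symmetric kernel that removes single-cell
#'   spikes.
#' @return The denoised `subtraction_matrix`.
#' @export
median_denoise <- function(s, kernel_bins = 3L) {
  stopifnot(inherits(s, "subtraction_matrix"))
  k <- as.integer(kernel_bins)
  if (k < 1L || k %% 2L == 0L) abort("`kernel_bins` must be odd and >= 1.")
  if (k == 1L) return(s)
  out <- median_filter_mat(s$values, (k - 1L) %/% 2L)
  res <- contact_matrix(s$grid, out, mask = s$mask, units = "subtraction")
  class(res) <- c("subtraction_matrix", class(res))
  res
}

#' One-call subtraction pipeline
#'
#' Convenience wrapper running the full chain
#' normalize -> observed/expected -> subtract -> median-denoise.
#'
#' @inheritParams joint_normalize
#' @inheritParams median_denoise
#' @return A denoised `subtraction_matrix`.
#' @export
subtraction_pipeline <- function(pair, span = 0.3, kernel_bins = 3L) {
  norm <- joint_normalize(pair, span = span)
  median_denoise(subtraction(norm$pair), kernel_bins = kernel_bins)
}
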
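#' Read and snap TAD domains to a bin grid
#'
#' Domains are consumed as input (e.g. from an external TAD caller) as BED3+
#' intervals, 0-based half-open. Starts are snapped down and ends up to bin
#' boundaries, with a warning when snapping changes a coordinate. Domains must
#' span at least 2 bins after snapping.
#'
#' @param domains A data frame with `chrom`, `start`, `end` (or a BED path,
#'   read via [read_bed()]).
#' @param grid A [bin_grid()].
#' @return A tibble with `chrom`, `start`, `end`, `size_bins`, ordered by
#'   coordinate.
#' @export
tad_domains <- function(domains, grid) {
  if (is.character(domains)) domains <- read_bed(domains)
  stopifnot(inherits(grid, "bin_grid"))
  d <- as_tibble(domains)
  d <- d[d$chrom == grid$chrom, , drop = FALSE]
  bs <- grid$bin_size
  s <- floor(d$start / bs) * bs
  e <- ceiling(d$end / bs) * bs
  if (any(s != d$start | e != d$end)) {
    warn("some domains were snapped to bin boundaries.")
  }
  if (any(e <= s)) abort("domains must satisfy end > start.")
  if (any(s < 0 | e > grid$n_bins * bs)) abort("domain outside the bin grid.")
  out <- tibble(
    chrom = d$chrom, start = s, end = e,
    size_bins = as.integer((e - s) / bs)
  )
  if (any(out$size_bins < 2L)) abort("domains must span at least 2 bins.")
  dplyr::arrange(out, .data$start, .data$end)
}

#' Absolute intra-domain difference score
#'
#' Sums the absolute allelic differences over the intra-domain cells of a
#' subtraction matrix. "Intra-domain cells" are the upper triangle including
#' the diagonal of the domain's square block (the symmetric mirror would
#' double every off-diagonal cell). Masked cells contribute 0 and lower the
#' informative fraction.
#'
#' @param s A (denoised) `subtraction_matrix`.
#' @param domain A one-row data frame with `chrom`, `start`, `end` aligned to
#'   the grid (see [tad_domains()]).
#' @return A one-row tibble: `chrom`, `start`, `end`, `size_bins`, `abs_sum`,
#'   `n_cells`, `frac_informative`.
#' @export
domain_score <- function(s, domain) {
  stopifnot(inherits(s, "subtraction_matrix"))
  grid <- s$grid
  bs <- grid$bin_size
  i0 <- as.integer(domain$start[1] %/% bs)
  i1 <- as.integer((domain$end[1] - 1) %/% bs)
  if (i0 < 0L || i1 >= grid$n_bins) abort("domain outside the bin grid.")
  idx <- (i0:i1) + 1L
  block <- s$values[idx, idx, drop = FALSE]
  ut <- upper.tri(block, diag = TRUE)
  cells <- block[ut]
  tibble(
    chrom = grid$chrom,
    start = domain$start[1],
    end = domain$end[1],
    size_bins = length(idx),
    abs_sum = sum(abs(cells), na.rm = TRUE),
    n_cells = length(cells),
    frac_informative = mean(!is.na(cells))
  )
}

#' Chromosome-wide background of window scores
#'
#' Computes the absolute intra-window difference score of every
#' diagonal-anchored square window of `size_bins` bins sliding along the
#' chromosome, under the same masking rule as [domain_score()] (masked cells
#' contribute 0). This is the empirical null against which a domain of that
#' size is judged.
#'
#' @param s A `subtraction_matrix`.
#' @param size_bins Window size in bins.
#' @param stride Step between window starts, in bins (default 1).
#' @return Numeric vector of window scores, one per window
#'   (`floor((n_bins - size_bins) / stride) + 1` of them).
#' @export
background_distribution <- function(s, size_bins, stride = 1L) {
  stopifnot(inherits(s, "subtraction_matrix"))
  n <- s$grid$n_bins
  w <- as.integer(size_bins)
  stride <- as.integer(stride)
  if (w > n) abort("`size_bins` exceeds the number of bins.")
  if (w < 1L || stride < 1L) abort("`size_bins` and `stride` must be >= 1.")
  A <- abs(s$values)
  A[is.na(A)] <- 0
  # 2-D prefix sums: square-block sum in O(1) per window
  P <- matrix(0, n + 1L, n + 1L)
  P[-1L, -1L] <- apply(apply(A, 2L, cumsum), 1L, cumsum)  # P[i+1,j+1] = sum A[1:i,1:j]
  P <- t(P)
  dg <- c(0, cumsum(diag(A)))
  starts <- seq.int(1L, n - w + 1L, by = stride)
  vapply(starts, function(p) {
    q <- p + w - 1L
    sq <- P[q + 1L, q + 1L] - P[p, q + 1L] - P[q + 1L, p] + P[p, p]
    (sq + (dg[q + 1L] - dg[p])) / 2   # upper triangle incl. diagonal
  }, numeric(1))
}

#' Background Z-score for one domain
#'
#' Standardizes a domain's absolute-difference score against the
#' chromosome-wide background of same-size windows, using the population
#' standard deviation. Domains with `z` strictly greater than the threshold
#' are classified as ASTADs. Degenerate backgrounds (zero spread) yield
#' `z = 0` when the observed score equals the background mean, and an
#' indeterminate call otherwise (no infinite z is emitted).
#'
#' @param score A one-row tibble from [domain_score()].
#' @param background Numeric vector from [background_distribution()].
#' @param threshold Z threshold for classification (default 2; calls require
#'   `z > threshold`, strictly).
#' @param min_informative Minimum `frac_informative` for a domain to be
#'   eligible; domains below the floor (e.g. in SNP deserts) are reported but
#'   flagged and never called.
#' @return A one-row tibble extending the score with `bg_mean`, `bg_sd`, `z`,
#'   `indeterminate`, `flagged_uninformative`, `is_astad`.
#' @export
z_score <- function(score, background, threshold = 2,
                    min_informative = 0.5) {
  if (length(background) == 0L) abort("`background` must be non-empty.")
  mu <- mean(background)
  sg <- sqrt(mean((background - mu)^2))
  obs <- score$abs_sum
  if (sg == 0) {
    z <- if (obs == mu) 0 else NA_real_
    indet <- obs != mu
  } else {
    z <- (obs - mu) / sg
    indet <- FALSE
  }
  uninf <- score$frac_informative < min_informative
  dplyr::mutate(
    score,
    bg_mean = mu, bg_sd = sg, z = z,
    indeterminate = indet,
    flagged_uninformative = uninf,
    is_astad = !indet & !uninf & !is.na(z) & z > threshold
  )
}

#' Call allele-specific TADs
#'
#' Scores every domain's intra-domain absolute allelic difference on a
#' denoised subtraction matrix and classifies ASTADs by comparing each score
#' against the chromosome-wide background of diagonal-anchored windows of the
#' same size ([background_distribution()]). Backgrounds are computed once per
#' distinct domain size; the scored domain's own windows are not excluded
#' from its background (a conservative choice: any planted signal inflates
#' the null it is judged against).
#'
#' @param s A denoised `subtraction_matrix` (see [subtraction_pipeline()]).
#' @param domains Domains from [tad_domains()] (or a raw BED-like data frame,
#'   snapped internally).
#' @param threshold Z threshold (strict `>`; default 2).
#' @param stride Background window stride in bins.
#' @param min_informative Informativeness floor (see [z_score()]).
#' @return An `astad_calls` tibble, one row per domain ordered by coordinate,
#'   with the columns of [z_score()].
#' @examples
#' cfg <- recovery_config(seed = 7)
#' sim <- simulate_pair(cfg)
#' sub <- subtraction_pipeline(sim$pair)
#' calls <- call_astads(sub, tad_domains(sim$truth$tads, sim$pair$a1$grid))
#' @export
call_astads <- function(s, domains, threshold = 2, stride = 1L,
                        min_informative = 0.5) {
  stopifnot(inherits(s, "subtraction_matrix"))
  if (!("size_bins" %in% names(domains))) {
    domains <- tad_domains(domains, s$grid)
  }
  if (nrow(domains) == 0L) {
    out <- tibble(
      chrom = character(), start = numeric(), end = numeric(),
      size_bins = integer(), abs_sum = numeric(), n_cells = integer(),
      frac_informative = numeric(), bg_mean = numeric(), bg_sd = numeric(),
      z = numeric(), indeterminate = logical(),
      flagged_uninformative = logical(), is_astad = logical()
    )
    class(out) <- c("astad_calls", class(out))
    return(out)
  }
  bgs <- lapply(
    setNames(nm = sort(unique(domains$size_bins))),
    function(w) background_distribution(s, w, stride = stride)
  )
  rows <- purrr::map(seq_len(nrow(domains)), function(i) {
    sc <- domain_score(s, domains[i, ])
    z_score(sc, bgs[[as.character(sc$size_bins)]], threshold = threshold,
            min_informative = min_informative)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$start, .data$end)
  attr(out, "threshold") <- threshold
  class(out) <- c("astad_calls", class(out))
  out
}

#' Write ASTAD calls
#'
#' Writes the full call table as TSV and, optionally, the called ASTADs as
#' BED with the Z-score in the score column.
#'
#' @param calls An `astad_calls` tibble.
#' @param tsv_path Output TSV path.
#' @param bed_path Optional BED output path for `is_astad` rows.
#' @return `tsv_path`, invisibly.
#' @export
write_astads <- function(calls, tsv_path, bed_path = NULL) {
  readr::write_tsv(as_tibble(calls), tsv_path)
  if (!is.null(bed_path)) {
    hits <- calls[calls$is_astad, ]
    bed <- data.frame(
      chrom = hits$chrom, start = hits$start, end = hits$end,
      name = sprintf("ASTAD_%d", seq_len(nrow(hits))),
      score = round(hits$z, 3)
    )
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv_path)
}
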
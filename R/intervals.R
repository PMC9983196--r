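#' Read BED intervals as a tibble
#'
#' Reads BED3+ (0-based half-open). Column 4 becomes `name` and column 5
#' `stratum` when present (strata label feature classes for stratified
#' resampling, e.g. gene types).
#'
#' @param path Path to a BED file.
#' @return A tibble with `chrom`, `start`, `end` and optional `name`,
#'   `stratum`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4] <- "name"
  if (ncol(df) >= 5L) names(df)[5] <- "stratum"
  as_tibble(df[, seq_len(min(ncol(df), 5L)), drop = FALSE])
}

# tibble (0-based half-open) -> GRanges (1-based closed)
as_gr <- function(df) {
  GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(start = df$start + 1, end = pmax(df$end, df$start + 1))
  )
}

# does each interval of x overlap (>= 1 bp, half-open semantics) any of y?
overlaps_any_interval <- function(x, y) {
  if (nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  IRanges::overlapsAny(as_gr(x), as_gr(y))
}

# logical hit matrix: rows of x vs rows of y
overlap_hit_matrix <- function(x, y) {
  m <- matrix(FALSE, nrow(x), nrow(y))
  if (nrow(x) == 0L || nrow(y) == 0L) return(m)
  h <- GenomicRanges::findOverlaps(as_gr(x), as_gr(y))
  m[cbind(S4Vectors::queryHits(h), S4Vectors::subjectHits(h))] <- TRUE
  m
}

#' Reciprocal overlap of two genomic intervals
#'
#' `min(|a intersect b| / |a|, |a intersect b| / |b|)` for 0-based half-open
#' intervals; 0 if the intervals are on different chromosomes or disjoint.
#' At a 90% threshold this is the criterion used to call domains conserved
#' across samples, tolerating roughly one bin of positional drift from matrix
#' binning.
#'
#' @param a,b Data frames (recycled row-wise) with `chrom`, `start`, `end`.
#' @return Numeric vector of reciprocal overlap fractions in `[0, 1]`.
#' @examples
#' reciprocal_overlap(
#'   data.frame(chrom = "chr12", start = 10915000, end = 11405000),
#'   data.frame(chrom = "chr12", start = 10900000, end = 11370000)
#' )
#' @export
reciprocal_overlap <- function(a, b) {
  la <- a$end - a$start
  lb <- b$end - b$start
  if (any(la <= 0) || any(lb <= 0)) abort("zero-length interval.")
  inter <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ifelse(a$chrom == b$chrom, pmin(inter / la, inter / lb), 0)
}

#' Group domains conserved across samples
#'
#' Finds groups containing exactly one interval from every sample such that
#' all pairwise reciprocal overlaps within the group reach the threshold.
#' Matching is greedy best-overlap: samples are ordered by name, intervals of
#' the first sample are visited in coordinate order, and for each the
#' best-overlapping unused interval of every other sample is taken; the group
#' is accepted only if every pairwise overlap passes. Each interval belongs
#' to at most one group. The group representative is the intersection of its
#' members.
#'
#' @param astad_sets A named list (>= 2 elements) of interval tibbles, one
#'   per sample, each with `chrom`, `start`, `end`.
#' @param threshold Minimum pairwise reciprocal overlap (default 0.9).
#' @return A tibble with one row per group member: `group`, `sample`,
#'   `chrom`, `start`, `end`, plus the representative intersection as columns
#'   `rep_start`, `rep_end`.
#' @export
conserved_sets <- function(astad_sets, threshold = 0.9) {
  if (length(astad_sets) < 2L) abort("need at least 2 samples.")
  if (is.null(names(astad_sets)) || any(names(astad_sets) == "")) {
    names(astad_sets) <- paste0("sample", seq_along(astad_sets))
  }
  ord <- order(names(astad_sets))
  sets <- lapply(astad_sets[ord], function(x) {
    x <- as_tibble(x)[, c("chrom", "start", "end")]
    dplyr::arrange(x, .data$chrom, .data$start, .data$end)
  })
  snames <- names(sets)
  used <- lapply(sets, function(x) rep(FALSE, nrow(x)))
  groups <- list()
  first <- sets[[1]]
  for (i in seq_len(nrow(first))) {
    cand <- first[i, ]
    members <- list(cand)
    ok <- TRUE
    for (s in seq_along(sets)[-1]) {
      other <- sets[[s]]
      avail <- which(!used[[s]])
      if (length(avail) == 0L) { ok <- FALSE; break }
      ro <- reciprocal_overlap(
        cand[rep(1L, length(avail)), ], other[avail, ]
      )
      best <- avail[which.max(ro)]
      if (max(ro) < threshold) { ok <- FALSE; break }
      members[[s]] <- other[best, ]
    }
    if (!ok) next
    mem <- dplyr::bind_rows(members)
    pair_ok <- TRUE
    for (p in seq_len(nrow(mem) - 1L)) {
      for (q in (p + 1L):nrow(mem)) {
        if (reciprocal_overlap(mem[p, ], mem[q, ]) < threshold) {
          pair_ok <- FALSE
        }
      }
    }
    if (!pair_ok) next
    for (s in seq_along(sets)[-1]) {
      hit <- which(sets[[s]]$start == mem$start[s] &
                   sets[[s]]$end == mem$end[s] &
                   sets[[s]]$chrom == mem$chrom[s] & !used[[s]])[1]
      used[[s]][hit] <- TRUE
    }
    mem$sample <- snames
    mem$rep_start <- max(mem$start)
    mem$rep_end <- min(mem$end)
    groups[[length(groups) + 1L]] <- mem
  }
  if (length(groups) == 0L) {
    return(tibble(group = integer(), sample = character(),
                  chrom = character(), start = numeric(), end = numeric(),
                  rep_start = numeric(), rep_end = numeric()))
  }
  out <- dplyr::bind_rows(groups, .id = "group")
  out$group <- as.integer(out$group)
  out[, c("group", "sample", "chrom", "start", "end", "rep_start", "rep_end")]
}

#' Drop domains overlapping excluded regions
#'
#' Removes any domain with >= 1 bp overlap (half-open semantics: touching
#' intervals do not overlap) with an assay blacklist or with regions of
#' non-normal copy number, where contact differences are likely artifacts.
#'
#' @param domains Interval tibble (`chrom`, `start`, `end`, ...).
#' @param blacklist,cnv_nonnormal Exclusion interval tibbles (either may be
#'   `NULL` or empty).
#' @return A list with `kept` (surviving domains) and `removed` (dropped
#'   domains with a `reason` column).
#' @export
exclusion_filter <- function(domains, blacklist = NULL, cnv_nonnormal = NULL) {
  domains <- as_tibble(domains)
  empty <- function(x) is.null(x) || nrow(x) == 0L
  hit_bl <- if (empty(blacklist)) rep(FALSE, nrow(domains))
            else overlaps_any_interval(domains, blacklist)
  hit_cnv <- if (empty(cnv_nonnormal)) rep(FALSE, nrow(domains))
             else overlaps_any_interval(domains, cnv_nonnormal)
  drop <- hit_bl | hit_cnv
  removed <- domains[drop, , drop = FALSE]
  removed$reason <- dplyr::case_when(
    hit_bl[drop] & hit_cnv[drop] ~ "blacklist+cnv",
    hit_bl[drop] ~ "blacklist",
    TRUE ~ "cnv"
  )
  list(kept = domains[!drop, , drop = FALSE], removed = removed)
}

#' TAD boundary intervals
#'
#' A boundary is the outermost `width` bp of a domain (one interval at each
#' end), matching the one-bin definition used on binned matrices. Domains
#' shorter than `2 * width` yield a single merged boundary equal to the whole
#' domain (logged with a message).
#'
#' @param domains Interval tibble.
#' @param width Boundary width in bp (default 20,000 = one 20 kb bin).
#' @return A tibble of boundary intervals with `chrom`, `start`, `end`,
#'   `domain_id`, `side` (`"left"`, `"right"`, or `"merged"`).
#' @export
tad_boundaries <- function(domains, width = 20000) {
  if (width <= 0) abort("`width` must be > 0.")
  domains <- as_tibble(domains)
  rows <- purrr::map(seq_len(nrow(domains)), function(i) {
    d <- domains[i, ]
    len <- d$end - d$start
    if (len < 2 * width) {
      tibble(chrom = d$chrom, start = d$start, end = d$end,
             domain_id = i, side = "merged")
    } else {
      tibble(
        chrom = d$chrom,
        start = c(d$start, d$end - width),
        end = c(d$start + width, d$end),
        domain_id = i, side = c("left", "right")
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$side == "merged")) {
    inform(sprintf("%d short domain(s) produced a merged boundary.",
                   sum(out$side == "merged")))
  }
  out
}
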
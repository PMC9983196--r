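#' One-sided upper-tail normal probability
#'
#' `P(N(0, 1) >= z)` — the analytic p-value attached to a randomization
#' Z-score under the normal approximation of the null.
#'
#' @param z Finite numeric vector of Z-scores.
#' @return Upper-tail probabilities in `[0, 1]`;
#'   `normal_p_from_z(z) + normal_p_from_z(-z) == 1`.
#' @examples
#' normal_p_from_z(c(0, 4.64, 3.43, -1.78))
#' @export
normal_p_from_z <- function(z) {
  if (any(!is.finite(z))) abort("`z` must be finite.")
  pnorm(z, lower.tail = FALSE)
}

#' Integer overlap percentage
#'
#' `round(100 * k / n)` with half-up rounding, as used when reporting the
#' share of genes falling inside ASTADs.
#'
#' @param k Count of overlapping items, `0 <= k <= n`.
#' @param n Total count, `> 0`.
#' @return Integer percentage.
#' @examples
#' overlap_percent(153, 480)  # 32
#' @export
overlap_percent <- function(k, n) {
  if (any(n <= 0)) abort("`n` must be > 0.")
  if (any(k < 0 | k > n)) abort("`k` must satisfy 0 <= k <= n.")
  as.integer(floor(100 * k / n + 0.5))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Tests association in a 2x2 contingency table (e.g. heterozygous enhancer
#' variants inside vs outside ASTADs). All four margins must be positive.
#'
#' @param tab A 2x2 non-negative count matrix.
#' @param yates Apply Yates continuity correction (default `FALSE`).
#' @return A one-row tibble with `statistic`, `df` (= 1) and `p_value`
#'   (upper tail).
#' @export
chisq_2x2 <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) abort("`tab` must be 2x2.")
  if (any(tab < 0)) abort("counts must be non-negative.")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("all margins of the 2x2 table must be > 0.")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  tibble(statistic = unname(ht$statistic), df = 1L,
         p_value = unname(ht$p.value))
}

new_enrichment_result <- function(observed, null_counts, n_samples, seed,
                                  test) {
  mu <- mean(null_counts)
  sg <- sd(null_counts)
  if (is.na(sg) || sg == 0) {
    z <- if (observed == mu) 0 else NA_real_
    indet <- observed != mu
  } else {
    z <- (observed - mu) / sg
    indet <- FALSE
  }
  out <- tibble(
    test = test,
    observed = observed,
    null_mean = mu,
    null_sd = if (is.na(sg)) 0 else sg,
    z = z,
    p = if (is.na(z)) NA_real_ else normal_p_from_z(z),
    p_empirical = (1 + sum(null_counts >= observed)) /
      (length(null_counts) + 1),
    indeterminate = indet,
    n_samples = n_samples,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  class(out) <- c("enrichment_result", class(out))
  out
}

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Boundary randomization enrichment
#'
#' Tests whether genomic features (e.g. conserved heterozygous variants or
#' allele-specific methylation sites) are enriched at a target set of domain
#' boundaries relative to random same-size draws from a larger boundary pool
#' (e.g. conserved ASTAD boundaries versus all conserved TAD boundaries).
#' The observed statistic is the number of features overlapping at least one
#' target boundary; each of `n_samples` null draws samples `|target|`
#' boundaries from the pool without replacement and recounts. The Z-score
#' standardizes the observation against the null moments, and `p` is its
#' upper-tail normal probability (the empirical rank p-value is also
#' reported).
#'
#' @param features Feature interval tibble.
#' @param target_boundaries Boundary intervals of interest.
#' @param pool_boundaries Pool to resample from (must be at least as large as
#'   the target set).
#' @param n_samples Number of null draws (default 10,000).
#' @param seed Integer seed recorded in the output; `NULL` uses the current
#'   RNG state.
#' @return A one-row `enrichment_result` tibble.
#' @export
boundary_enrichment <- function(features, target_boundaries, pool_boundaries,
                                n_samples = 10000L, seed = NULL) {
  features <- as_tibble(features)
  target_boundaries <- as_tibble(target_boundaries)
  pool_boundaries <- as_tibble(pool_boundaries)
  k <- nrow(target_boundaries)
  if (nrow(pool_boundaries) < k) abort("pool smaller than target set.")
  observed <- sum(overlaps_any_interval(features, target_boundaries))
  hits <- overlap_hit_matrix(features, pool_boundaries)
  npool <- nrow(pool_boundaries)
  null_counts <- with_opt_seed(seed, {
    vapply(seq_len(n_samples), function(b) {
      idx <- sample.int(npool, k)
      sum(rowSums(hits[, idx, drop = FALSE]) > 0)
    }, numeric(1))
  })
  new_enrichment_result(observed, null_counts, n_samples, seed,
                        test = "boundary_enrichment")
}

#' Stratified gene randomization enrichment
#'
#' Tests whether a gene set of interest (e.g. imprinted or allele-specific
#' expressed genes) overlaps ASTADs more often than stratified random draws
#' from the gene universe. Stratification matches the per-stratum counts of
#' the interest set (gene types are imbalanced between interest sets and the
#' genome-wide universe), sampling without replacement within each draw.
#' Genes are excluded from both sets if they do not overlap any TAD or if
#' they overlap a blacklist/non-normal-CNV region. A gene overlaps an ASTAD
#' if its full interval intersects any ASTAD interval.
#'
#' @param genes_of_interest,gene_universe Gene tibbles with `chrom`, `start`,
#'   `end`, `name` and optionally `stratum` (a single stratum is assumed when
#'   absent). Every gene of interest must be present (by `name`) in the
#'   universe.
#' @param astads ASTAD interval tibble.
#' @param tads TAD interval tibble used for the overlap exclusion.
#' @param blacklist,cnv_nonnormal Optional exclusion interval tibbles.
#' @inheritParams boundary_enrichment
#' @return A one-row `enrichment_result` tibble.
#' @export
stratified_gene_enrichment <- function(genes_of_interest, gene_universe,
                                       astads, tads,
                                       blacklist = NULL,
                                       cnv_nonnormal = NULL,
                                       n_samples = 10000L, seed = NULL) {
  uni <- as_tibble(gene_universe)
  goi <- as_tibble(genes_of_interest)
  if (!("stratum" %in% names(uni))) uni$stratum <- "all"
  if (!("stratum" %in% names(goi))) goi$stratum <- "all"
  if (!all(goi$name %in% uni$name)) {
    abort("every gene of interest must be present in the universe.")
  }
  keep <- overlaps_any_interval(uni, as_tibble(tads))
  excl <- exclusion_filter(uni, blacklist, cnv_nonnormal)
  keep <- keep & !(uni$name %in% excl$removed$name)
  uni <- uni[keep, , drop = FALSE]
  goi <- goi[goi$name %in% uni$name, , drop = FALSE]
  hits <- overlaps_any_interval(uni, as_tibble(astads))
  observed <- sum(hits[uni$name %in% goi$name])
  strata <- table(goi$stratum)
  idx_by_stratum <- split(seq_len(nrow(uni)), uni$stratum)
  for (s in names(strata)) {
    if (length(idx_by_stratum[[s]]) < strata[[s]]) {
      abort(sprintf("stratum '%s' larger in the interest set than in the universe.", s))
    }
  }
  null_counts <- with_opt_seed(seed, {
    vapply(seq_len(n_samples), function(b) {
      drawn <- unlist(lapply(names(strata), function(s) {
        pool <- idx_by_stratum[[s]]
        if (length(pool) == 1L) pool else sample(pool, strata[[s]])
      }))
      sum(hits[drawn])
    }, numeric(1))
  })
  new_enrichment_result(observed, null_counts, n_samples, seed,
                        test = "stratified_gene_enrichment")
}
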
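#' Read phased genotypes from a VCF
#'
#' Extracts the first sample's genotypes, phasing status ("|" separator) and
#' phase-set (PS) identifiers into the tabular form consumed by
#' [phase_concordance()].
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @return A tibble with `chrom`, `pos`, `ref`, `alt`, `gt` (e.g. `"0|1"`),
#'   `phased`, `ps` (phase block id; `NA` when absent).
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  ps <- tryCatch(vcfR::extract.gt(v, element = "PS")[, 1],
                 error = function(e) rep(NA_character_, length(gt)))
  tibble(
    chrom = fix$CHROM,
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gt = unname(gt),
    phased = grepl("|", gt, fixed = TRUE),
    ps = unname(ps)
  )
}

split_gt <- function(gt) strsplit(gt, "[|/]")

unordered_gt <- function(gt) {
  vapply(split_gt(gt), function(a) paste(sort(a), collapse = "/"),
         character(1))
}

#' Genotype and phasing concordance of two variant callsets
#'
#' Compares two phased callsets (e.g. Hi-C-derived genotypes/haplotypes
#' against an experimentally validated reference). Genotype agreement is the
#' fraction of loci common to both callsets (matched on chromosome, position
#' and REF/ALT alleles) with identical unordered genotype. Phasing agreement
#' is computed over common phased heterozygous loci, per shared phase-block
#' pair, allowing one global haplotype flip per block pair (haplotype
#' identity is only defined up to a flip within a block):
#' `agreement = max(matches, mismatches) / total` within each block pair,
#' summed over block pairs.
#'
#' @param callset_a,callset_b Tibbles as returned by [read_phased_vcf()].
#' @return A one-row `concordance_report` tibble with `n_common`,
#'   `n_genotype_agree`, `genotype_pct`, `n_phase_common`, `n_phase_agree`,
#'   `phase_pct` (percentages rounded to one decimal).
#' @export
phase_concordance <- function(callset_a, callset_b) {
  a <- as_tibble(callset_a)
  b <- as_tibble(callset_b)
  common <- dplyr::inner_join(a, b, by = c("chrom", "pos", "ref", "alt"),
                              suffix = c("_a", "_b"))
  if (nrow(common) == 0L) abort("no loci common to both callsets.")
  ua <- unordered_gt(common$gt_a)
  ub <- unordered_gt(common$gt_b)
  gt_agree <- ua == ub
  het <- function(u) vapply(strsplit(u, "/"), function(x) x[1] != x[2],
                            logical(1))
  ph <- common$phased_a & common$phased_b & gt_agree & het(ua) &
    !is.na(common$ps_a) & !is.na(common$ps_b)
  phased <- common[ph, , drop = FALSE]
  n_phase_common <- nrow(phased)
  if (n_phase_common > 0L) {
    first_allele <- function(gt) vapply(split_gt(gt), `[`, character(1), 1L)
    same_order <- first_allele(phased$gt_a) == first_allele(phased$gt_b)
    blocks <- split(same_order, paste(phased$ps_a, phased$ps_b, sep = "~"))
    n_phase_agree <- sum(vapply(blocks, function(s) {
      max(sum(s), sum(!s))   # best global flip per block pair
    }, numeric(1)))
  } else {
    n_phase_agree <- 0L
  }
  pct1 <- function(k, n) if (n == 0) NA_real_ else round(100 * k / n, 1)
  out <- tibble(
    n_common = nrow(common),
    n_genotype_agree = sum(gt_agree),
    genotype_pct = pct1(sum(gt_agree), nrow(common)),
    n_phase_common = n_phase_common,
    n_phase_agree = n_phase_agree,
    phase_pct = pct1(n_phase_agree, n_phase_common)
  )
  class(out) <- c("concordance_report", class(out))
  out
}
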
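#' Configuration for the synthetic diploid Hi-C generator
#'
#' Describes a phased diploid chromosome whose two allelic contact maps are
#' drawn from a shared intensity surface: a power-law distance decay
#' `lambda ~ c * (d + 1)^-alpha` (the canonical contact-decay shape),
#' block-enriched TADs, planted allele-specific sub-blocks (a multiplicative
#' factor `delta` applied to A2 inside chosen domains, so the planted effect
#' survives the observed/expected transform as a constant ratio), focal
#' loops, per-allele coverage scalars, SNP-desert masks, and independent
#' Poisson counting noise per cell.
#'
#' @param chrom Chromosome name for the simulated grid.
#' @param chrom_length,bin_size Geometry in bp.
#' @param base_intensity Expected count `c` at distance 0 bins before any
#'   enrichment factor.
#' @param decay_exponent Power-law exponent `alpha > 0`.
#' @param tad_specs Tibble `start`, `end`, `factor`: within-TAD enrichment
#'   applied to cells fully inside the interval (both alleles).
#' @param astad_specs Tibble `start`, `end`, `delta`: allelic multiplier
#'   applied to A2 intra-domain cells only.
#' @param loop_specs Tibble `anchor1`, `anchor2` (bp), `strength`, `allele`
#'   (`"A1"`, `"A2"` or `"both"`): focal enrichment at one anchor-pair cell.
#' @param coverage_a1,coverage_a2 Global per-allele coverage scalars.
#' @param snp_deserts Tibble `start`, `end`: bins masked in both alleles
#'   (regions without heterozygous variants cannot be haplotype-phased).
#' @param overdispersion Optional gamma mixing shape; `NULL` (default) gives
#'   pure Poisson noise, a finite value gives negative-binomial counts with
#'   that `size`.
#' @param seed Integer seed; the same seed reproduces the draw bitwise.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(chrom = "chrSim",
                              chrom_length = 5e6,
                              bin_size = 1e4,
                              base_intensity = 50,
                              decay_exponent = 1,
                              tad_specs = NULL,
                              astad_specs = NULL,
                              loop_specs = NULL,
                              coverage_a1 = 1,
                              coverage_a2 = 1,
                              snp_deserts = NULL,
                              overdispersion = NULL,
                              seed = 1L) {
  if (decay_exponent <= 0) abort("`decay_exponent` must be > 0.")
  empty_iv <- function(x, cols) {
    if (is.null(x)) {
      as_tibble(setNames(rep(list(numeric()), length(cols)), cols))
    } else {
      as_tibble(x)
    }
  }
  tad_specs <- empty_iv(tad_specs, c("start", "end", "factor"))
  astad_specs <- empty_iv(astad_specs, c("start", "end", "delta"))
  if (nrow(astad_specs) && any(astad_specs$delta <= 0)) {
    abort("allelic multipliers `delta` must be > 0.")
  }
  snp_deserts <- empty_iv(snp_deserts, c("start", "end"))
  for (iv in list(tad_specs, astad_specs, snp_deserts)) {
    if (nrow(iv) && any(iv$start < 0 | iv$end > chrom_length)) {
      abort("intervals must lie within the chromosome.")
    }
  }
  if (!is.null(loop_specs)) loop_specs <- as_tibble(loop_specs)
  structure(
    list(
      chrom = chrom, chrom_length = chrom_length, bin_size = bin_size,
      base_intensity = base_intensity, decay_exponent = decay_exponent,
      tad_specs = tad_specs, astad_specs = astad_specs,
      loop_specs = loop_specs,
      coverage_a1 = coverage_a1, coverage_a2 = coverage_a2,
      snp_deserts = snp_deserts, overdispersion = overdispersion,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Default planted-signal recovery configuration
#'
#' A 5 Mb chromosome at 10 kb bins with base intensity 50, decay exponent 1,
#' ten 300-500 kb TADs with within-TAD factor 3, and two planted ASTADs
#' (`delta = 2`, 50 and 40 bins wide) coinciding with the 3rd and 7th TADs.
#' This is the reference condition for the package's recovery validation.
#'
#' @param seed Integer seed.
#' @param delta Allelic multiplier of the two planted domains.
#' @return A `simulation_config`.
#' @export
recovery_config <- function(seed = 1L, delta = 2) {
  sizes <- c(400, 300, 500, 350, 450, 300, 400, 500, 350, 400) * 1e3
  gaps <- 60e3
  starts <- 100e3 + cumsum(c(0, head(sizes, -1) + gaps))
  tads <- tibble(start = starts, end = starts + sizes, factor = 3)
  planted <- c(3L, 7L)
  simulation_config(
    tad_specs = tads,
    astad_specs = tibble(
      start = tads$start[planted], end = tads$end[planted], delta = delta
    ),
    seed = seed
  )
}

bins_inside <- function(cfg, start, end) {
  # bins fully inside [start, end)
  bs <- cfg$bin_size
  lo <- as.integer(ceiling(start / bs))
  hi <- as.integer(floor(end / bs)) - 1L
  if (hi < lo) integer() else lo:hi
}

#' Expected (Poisson-intensity) matrix of one allele
#'
#' Builds the deterministic intensity surface `lambda` the generator draws
#' from: `coverage * c * (|i - j| + 1)^-alpha`, multiplied by TAD factors for
#' cells fully inside a TAD interval, loop strengths at anchor-pair cells,
#' and — for allele A2 only — the allelic multiplier `delta` inside each
#' planted ASTAD.
#'
#' @param cfg A [simulation_config()].
#' @param allele `"A1"` or `"A2"`.
#' @return A symmetric numeric matrix of intensities.
#' @export
expected_matrix <- function(cfg, allele = c("A1", "A2")) {
  allele <- match.arg(allele)
  grid <- bin_grid(cfg$chrom, cfg$chrom_length, cfg$bin_size)
  n <- grid$n_bins
  d <- abs(row(diag(n)) - col(diag(n)))
  cov <- if (allele == "A1") cfg$coverage_a1 else cfg$coverage_a2
  lam <- cov * cfg$base_intensity * (d + 1)^(-cfg$decay_exponent)
  apply_block <- function(lam, start, end, f) {
    idx <- bins_inside(cfg, start, end) + 1L
    if (length(idx)) lam[idx, idx] <- lam[idx, idx] * f
    lam
  }
  for (i in seq_len(nrow(cfg$tad_specs))) {
    lam <- apply_block(lam, cfg$tad_specs$start[i], cfg$tad_specs$end[i],
                       cfg$tad_specs$factor[i])
  }
  if (!is.null(cfg$loop_specs)) {
    for (i in seq_len(nrow(cfg$loop_specs))) {
      sp <- cfg$loop_specs[i, ]
      if (!(sp$allele %in% c(allele, "both"))) next
      bi <- as.integer(sp$anchor1 %/% cfg$bin_size) + 1L
      bj <- as.integer(sp$anchor2 %/% cfg$bin_size) + 1L
      lam[bi, bj] <- lam[bi, bj] * sp$strength
      if (bi != bj) lam[bj, bi] <- lam[bj, bi] * sp$strength
    }
  }
  if (allele == "A2") {
    for (i in seq_len(nrow(cfg$astad_specs))) {
      lam <- apply_block(lam, cfg$astad_specs$start[i],
                         cfg$astad_specs$end[i], cfg$astad_specs$delta[i])
    }
  }
  lam
}

#' Simulate a phased diploid contact-matrix pair
#'
#' Draws each upper-triangle cell of each allele independently from a Poisson
#' (or gamma-mixed Poisson) distribution with the intensity from
#' [expected_matrix()], mirrors to symmetry, and masks SNP-desert bins in
#' both alleles. A fixed seed reproduces the draw bitwise.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `pair` (an [allele_pair()]) and `truth`
#'   (a `simulated_truth` list echoing the config plus the planted ASTAD
#'   intervals, loop anchors and TAD table).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  grid <- bin_grid(cfg$chrom, cfg$chrom_length, cfg$bin_size)
  n <- grid$n_bins
  ut <- upper.tri(diag(n), diag = TRUE)
  draw <- function(lam) {
    m <- matrix(0, n, n)
    mu <- lam[ut]
    x <- if (is.null(cfg$overdispersion)) {
      rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), size = cfg$overdispersion, mu = mu)
    }
    m[ut] <- x
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  mask <- rep(FALSE, n)
  if (nrow(cfg$snp_deserts)) {
    for (i in seq_len(nrow(cfg$snp_deserts))) {
      idx <- bins_inside(cfg, cfg$snp_deserts$start[i],
                         cfg$snp_deserts$end[i]) + 1L
      mask[idx] <- TRUE
    }
  }
  mats <- withr::with_seed(cfg$seed, {
    list(a1 = draw(expected_matrix(cfg, "A1")),
         a2 = draw(expected_matrix(cfg, "A2")))
  })
  pair <- allele_pair(
    contact_matrix(grid, mats$a1, mask = mask),
    contact_matrix(grid, mats$a2, mask = mask)
  )
  truth <- structure(
    list(
      config = cfg,
      tads = dplyr::mutate(cfg$tad_specs[, c("start", "end")],
                           chrom = cfg$chrom, .before = 1),
      astads = dplyr::mutate(cfg$astad_specs, chrom = cfg$chrom, .before = 1),
      loops = cfg$loop_specs
    ),
    class = "simulated_truth"
  )
  list(pair = pair, truth = truth)
}

#' Write a simulated fixture to disk
#'
#' Emits the two allelic triplet matrices, the TAD BED, and a JSON truth file
#' (config echo plus planted ASTAD intervals) into a directory; reading the
#' files back reproduces the written objects.
#'
#' @param pair An `allele_pair`.
#' @param truth A `simulated_truth`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture <- function(pair, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    a1 = file.path(dir, "a1.tsv"),
    a2 = file.path(dir, "a2.tsv"),
    tads = file.path(dir, "tads.bed"),
    truth = file.path(dir, "truth.json")
  )
  write_contacts(pair$a1, paths[["a1"]])
  write_contacts(pair$a2, paths[["a2"]])
  utils::write.table(truth$tads[, c("chrom", "start", "end")],
                     paths[["tads"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  cfg <- truth$config
  cfg_json <- cfg[!vapply(cfg, is.null, logical(1))]
  jsonlite::write_json(
    list(config = cfg_json, astads = truth$astads),
    paths[["truth"]],
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Read back a simulated fixture
#'
#' @param dir Directory written by [write_fixture()].
#' @return A list with `pair`, `tads` and `truth` (parsed JSON).
#' @export
read_fixture <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  cfg <- truth$config
  grid <- bin_grid(cfg$chrom, cfg$chrom_length, cfg$bin_size)
  mask <- rep(FALSE, grid$n_bins)
  sd_iv <- as_tibble(cfg$snp_deserts)
  if (nrow(sd_iv)) {
    for (i in seq_len(nrow(sd_iv))) {
      mask[(sd_iv$start[i] %/% cfg$bin_size):
             ((sd_iv$end[i] - 1) %/% cfg$bin_size) + 1L] <- TRUE
    }
  }
  pair <- allele_pair(
    read_contacts(file.path(dir, "a1.tsv"), grid, mask = mask),
    read_contacts(file.path(dir, "a2.tsv"), grid, mask = mask)
  )
  list(pair = pair, tads = read_bed(file.path(dir, "tads.bed")),
       truth = truth)
}
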
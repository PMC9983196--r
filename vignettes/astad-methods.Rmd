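---
title: "Detecting allele-specific contact domains: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allele-specific contact domains: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astadr)
```

## The model

Haplotype-resolved Hi-C produces, per chromosome, two binned contact
matrices A1 and A2 whose entries count ligation events between pairs of
loci on the same haplotype. Three nuisance structures dominate these
matrices and must be removed before the alleles can be compared:

1. **Coverage and assignment bias between alleles.** Fewer reads phase to
   one haplotype than the other, and the imbalance can drift with genomic
   distance. We model it as a smooth distance-dependent log-ratio and
   remove it by joint loess normalization: for cells where both alleles
   are non-zero, fit `f(d)` to `M = log2(A2/A1)` against bin distance `d`
   (degree-1 local fit, tricube weights, span 0.3), then apply the
   correction symmetrically, `A1' = A1·2^{f(d)/2}`, `A2' = A2·2^{-f(d)/2}`.
   The even split makes the correction allele-agnostic (the chain is
   exactly antisymmetric under allele swap) and preserves the cellwise
   product `A1·A2`. Cells where exactly one allele is zero receive the
   correction but contribute nothing to the fit. Because the fit only sees
   joint-nonzero cells, the estimated curve is biased at distances where
   expected counts fall below ~5–10 per cell (zero-truncation of the
   Poisson); this is inherent to joint normalization of sparse pairs and
   is the reason subtraction values far from the diagonal should be read
   with care at low depth.
2. **Distance decay.** Contact frequency falls roughly as a power law in
   distance. Each allele is transformed to observed/expected: every cell
   is divided by the mean of the unmasked cells on its diagonal, computed
   per chromosome. After the transform every diagonal has mean 1 by
   construction, so the allelic difference `S = A2_oe − A1_oe` has mean
   zero on every diagonal before any biological signal.
3. **Single-cell counting noise.** `S` is denoised with a k×k median
   filter (default 3×3, the smallest symmetric kernel that removes an
   isolated spike). Masked cells stay masked and are excluded from their
   neighbors' medians; because the kernel is centered and the input
   symmetric, the output is symmetric.

An **ASTAD** is then a reference TAD whose intra-domain absolute allelic
difference exceeds the chromosome-wide background. The score of a domain
of `w` bins is the sum of `|S|` over the upper triangle (including the
diagonal) of its square block — the upper triangle avoids double-counting
every off-diagonal cell of a symmetric matrix. The background is the same
score computed for every diagonal-anchored `w×w` window sliding along the
chromosome at stride 1, and

`Z = (score − mean(background)) / sd(background)`

with the population standard deviation. Domains with `Z` strictly greater
than 2 are called ASTADs.

### Assumptions

- Both matrices share one bin grid and the comparison is cis-only,
  per chromosome.
- The between-allele bias is smooth in distance (loess-representable) and
  shared across the chromosome.
- Reference TADs are given (from any external domain caller on the
  diploid matrix); the package never calls domains itself.
- Bins without phased heterozygous variants carry no allelic information;
  they enter as masked bins and propagate through every step.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `bin_size` | 10,000 | bp | grid resolution (20 kb typical for compartment-scale work) |
| `span` | 0.3 | fraction | loess window of the joint normalization |
| `kernel_bins` | 3 | bins | median-filter width; must be odd |
| `threshold` | 2 | Z units | ASTAD call threshold, strict `>` |
| `stride` | 1 | bins | background window stride |
| `min_informative` | 0.5 | fraction | floor on unmasked intra-domain cells; below it a domain is flagged, never called |
| reciprocal overlap | 0.9 | fraction | conserved-domain criterion (~1 bin of positional drift for a median-size domain) |
| boundary width | 20,000 | bp | outermost stretch of a domain treated as its boundary (1 bin) |
| `n_samples` | 10,000 | draws | resampling depth of both randomization tests |
| `tol`, `max_iter` | 1e-6, 1000 | — | Knight–Ruiz convergence control |

## Design choices where the design was open

- **Background windows include the scored domain's own region.** The
  background is "chromosome-wide"; excluding the domain would make each
  domain's null slightly different and slightly smaller. Inclusion is the
  conservative choice: real signal inflates the null it is judged
  against. With ~10 domains on a 500-bin chromosome the effect on Z is
  small.
- **Population (not sample) standard deviation** in the domain Z-score:
  the window scores are the entire enumerated background, not a sample
  from it. Degenerate backgrounds (zero spread) yield `Z = 0` when the
  observed score equals the background mean and an explicit indeterminate
  flag otherwise — no infinite Z is ever emitted.
- **Stage order is normalize → O/E → subtract → denoise** for both
  visualization and domain scoring. Scoring the raw (pre-O/E) subtraction
  would weight near-diagonal cells by orders of magnitude more; the O/E
  scale is the one on which "absolute difference" is comparable across
  distances, and the same matrix drives both outputs.
- **Subtraction is on the linear O/E scale**, not log: zeros are common
  in allelic matrices and a log scale would either drop them or need a
  pseudocount; the O/E difference is symmetric, bounded below by −O/E,
  and directly interpretable as fold enrichment difference.
- **p-values for the randomization tests** are reported from the normal
  approximation of the null (`p = P(N(0,1) ≥ Z)`), which can resolve
  probabilities below the 1/n floor of the empirical rank; the empirical
  rank p (with add-one correction) is always emitted alongside, and the
  two should be compared when Z is small.
- **Conserved-set matching is greedy best-overlap.** Samples are ordered
  by name (making the result independent of input order), intervals of
  the first sample are visited in coordinate order, and each remaining
  sample contributes its best-overlapping unused interval; a group is
  accepted only if *all* pairwise reciprocal overlaps reach the
  threshold. Each interval joins at most one group; the representative is
  the intersection of members. One-to-many conflicts are thus resolved in
  favor of the earlier-coordinate seed, deterministically.
- **Insulation windows that are uniformly zero** are reported as `NA`
  rather than −∞; windows of the score within `w` bins of a chromosome
  end are undefined. The figure-ready track normalizes by the
  chromosome-wide mean of window means (log2), so a uniform matrix scores
  0 everywhere defined. No window default is claimed; it is a required
  argument.
- **Knight–Ruiz with a Sinkhorn safety net.** The inner–outer Newton
  scheme converges fast on well-conditioned matrices but can leave the
  positive cone on hard ones; the damped symmetric fixed-point iteration
  `x ← x/√(x·(Ax))` is slower but monotone in practice, so it backstops
  the Newton solver. Zero-sum rows are masked before iteration (they
  cannot be balanced); no coverage-percentile filtering is applied beyond
  that, since masking is a statement about information, not depth.
- **Domain snapping**: inputs not aligned to the grid are snapped start
  down / end up with a warning, never silently truncated.
- **Low-count loess fallback**: with fewer than 30 distinct distances the
  local fit is numerically singular, so the exact per-distance means are
  used (the span→0 limit of the fit).

## The synthetic generator

`simulation_config()` draws each upper-triangle cell of each allele
independently from a Poisson distribution with intensity

`λ_ij = coverage · c · (|i−j|+1)^(−α) · TAD factors · loop factors · δ (A2 only)`

and mirrors to symmetry. It emulates the features the domain statistic
relies on: power-law decay (α = 1), block-enriched TADs (factor 3),
planted allele-specific sub-blocks (a multiplicative δ on A2 inside chosen
domains — multiplicative so the planted effect survives the O/E transform
as a constant ratio, the cleanest recoverable signal), focal loops
assignable to one allele, global per-allele coverage imbalance, SNP-desert
masks, and Poisson counting noise (negative-binomial overdispersion is
available via a gamma mixing parameter but off by default, as no stronger
distributional claim is warranted).

`recovery_config()` fixes the reference condition used throughout
validation: a 5 Mb chromosome at 10 kb bins (500 bins), base intensity
c = 50, α = 1, ten TADs of 300–500 kb with factor 3, and two planted
ASTADs (δ = 2; 50 and 40 bins) coinciding with the 3rd and 7th TADs. The
TAD sizes and 60 kb gaps are in the range reported for mammalian genomes;
c = 50 puts near-diagonal cells in the hundreds of counts and ~30-bin
distances near 1–2 counts, i.e. a realistically sparse far field.

What the generator does **not** emulate — and hence what passing recovery
tests cannot certify on real data: mapping and restriction-site bias,
phasing errors (reads assigned to the wrong haplotype), spatially
correlated noise, nested/overlapping domain hierarchies, compartment-scale
checkerboards, and trans contacts. The calibration and recovery results
bound the method's behavior under its own model assumptions only.

## Validation problem sizes

The test suite validates every operation against closed forms, brute-force
enumeration, or exhaustive oracles on small fixtures (≤ 20 bins; all
C(10,3) and C(4,2) resampling draws enumerated), then exercises the full
chain at the reference condition: 50 seeded chromosomes for planted-signal
recovery (both planted domains at Z > 2 with at most one unplanted call in
at least 45 of 50 seeds), 20 seeds per δ ∈ {1, 1.25, 1.5, 2, 3} for the
dose–response of the median planted Z, and 1,000 signal-free runs per
randomization test for calibration (|Z| > 2 in at most ~5% of runs; the
test bound of 6.5% is the 5% target plus two binomial standard errors at
n = 1,000). `scripts/acceptance.R` re-runs a 25-chromosome recovery and a
300-run calibration and writes the rates as JSON.

## Known limitations

- Cells are treated exchangeably within a diagonal; domain-scale
  correlation in the noise would make the background slightly
  optimistic.
- The absolute-sum score has no direction: a domain with mixed A1- and
  A2-enriched sub-blocks scores as high as a uniformly biased one.
- Nested TAD inputs are scored independently; a strong sub-domain signal
  will also lift its parent.
- Genotype/phasing concordance operates on biallelic, single-sample
  callsets; multi-allelic records are compared as strings.
- The joint normalization's zero-truncation bias at sparse distances
  (above) shifts subtraction values toward zero far from the diagonal —
  conservative for calling, but a caveat for effect-size interpretation.
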
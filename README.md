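# astadr

Allele-specific contact domain analysis for haplotype-resolved Hi-C.

## The problem

Diploid genomes carry two copies of every chromosome, and at some loci —
imprinted gene clusters, regions of dense heterozygous variation — the two
haplotypes fold differently. When Hi-C reads can be assigned to a parental
haplotype through phased heterozygous variants, each chromosome yields two
contact matrices, A1 and A2, and the question becomes: *where do the two
alleles differ in 3D contact structure, and is the difference larger than
noise?*

`astadr` answers this at the level of topologically associating domains
(TADs). A TAD whose intra-domain contacts differ between alleles more than
the chromosome-wide background for a domain of its size is called an
**allele-specific TAD (ASTAD)**. The package is aimed at epigenomics
researchers working with haplotype-phased Hi-C or capture Hi-C: it takes
binned allelic contact matrices and a reference TAD annotation, and returns
scored, classified domains together with downstream comparison and
enrichment statistics.

## The method

For a chromosome binned at resolution `b` (10 kb by default), with allelic
matrices `A1`, `A2`:

1. **Joint loess normalization.** For cells where both alleles are
   non-zero, `M = log2(A2/A1)` is regressed on bin distance `d` with a
   degree-1 loess; the fitted bias `f(d)` is split evenly:
   `A1' = A1·2^{f/2}`, `A2' = A2·2^{-f/2}`. This removes
   distance-dependent between-allele bias while preserving `A1·A2`.
2. **Observed/expected transform.** Each allele is divided by its mean
   contact value at the same bin distance (per chromosome), flattening the
   power-law distance decay so long-range differences are comparable.
3. **Subtraction and denoising.** `S = A2_oe − A1_oe`, then a 3×3 median
   filter removes isolated single-cell noise while keeping regions of
   consistent directional bias.
4. **Domain scoring.** For each TAD, the absolute sum of `S` over
   intra-domain cells (upper triangle including the diagonal) is compared
   against the scores of every same-size diagonal-anchored window along the
   chromosome: `Z = (score − mean(background)) / sd(background)`. Domains
   with `Z > 2` are ASTADs; domains where fewer than half the cells are
   informative (e.g. SNP deserts that cannot be phased) are flagged and
   never called.

Around this core the package provides: Knight–Ruiz matrix balancing,
Crane-style insulation scores, virtual-4C viewpoint traces, conserved-ASTAD
detection across samples (90% reciprocal overlap), blacklist/CNV exclusion
filters, randomization enrichment tests for features at domains and
boundaries (n = 10,000 resampling draws, analytic and empirical p-values),
a 2×2 chi-square test, phased-VCF genotype/phasing concordance metrics, and
a synthetic diploid Hi-C generator with planted ground truth used to
validate the whole chain.

## Worked example

Simulate a 5 Mb diploid chromosome (10 kb bins, ten TADs, two planted
allele-specific domains with a 2× contact multiplier on A2), run the full
chain, and call ASTADs:

```r
library(astadr)

cfg   <- recovery_config(seed = 42)
sim   <- simulate_pair(cfg)
sub   <- subtraction_pipeline(sim$pair)        # normalize -> O/E -> subtract -> denoise
calls <- call_astads(sub, tad_domains(sim$truth$tads, sim$pair$a1$grid))
tidy(calls)[, c("start", "end", "size_bins", "abs_sum", "z", "is_astad")]
#> # A tibble: 10 × 6
#>      start     end size_bins abs_sum       z is_astad
#>      <dbl>   <dbl>     <int>   <dbl>   <dbl> <lgl>
#>  1  100000  500000        40    210. -0.228  FALSE
#>  2  560000  860000        30    101. -0.346  FALSE
#>  3  920000 1420000        50   1433.  4.34   TRUE
#>  4 1480000 1830000        35    172. -0.122  FALSE
#>  5 1890000 2340000        45    331.  0.0580 FALSE
#>  6 2400000 2700000        30    128. -0.0831 FALSE
#>  7 2760000 3160000        40    854.  3.50   TRUE
#>  8 3220000 3720000        50    380. -0.0761 FALSE
#>  9 3780000 4130000        35    173. -0.115  FALSE
#> 10 4190000 4590000        40    209. -0.235  FALSE
```

The two domains with `z > 2` are exactly the two planted ones
(`sim$truth$astads`); every unplanted domain sits near `z = 0`. The
`abs_sum` column is the intra-domain sum of absolute allelic O/E
differences, and `z` standardizes it against all same-size windows on the
chromosome. `autoplot(sub)` draws the subtraction heatmap and
`autoplot(calls)` the Z-score profile.

A shell entry point wrapping the same functions is installed at
`system.file("cli", "astadr", package = "astadr")`, with subcommands
`simulate`, `balance`, `normalize`, `subtract`, `astad`, `conserve`,
`enrich`, `viewpoint`; every run writes a `manifest.json` from which it can
be reproduced exactly.

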
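# haplodiv

Haplotype frequency estimation and HLA diversity analysis for unrelated
stem-cell donor registries.

## The problem

Registries hold HLA typings collected over decades: serological and
molecular methods at different resolutions, allelic ambiguity, unphased
genotypes, and whole loci absent from early recruitment eras (HLA-C and
HLA-DQB1 joined routine typing panels late). Match prediction and donor
recruitment planning nevertheless need five-locus HLA-A ~ B ~ C ~ DRB1 ~
DQB1 haplotype frequencies at two-field (ARS) resolution, per
subpopulation, together with measures of how diverse — and therefore how
hard to match — each subpopulation is.

`haplodiv` is for registry informatics and immunogenetics analysts: it
takes donor genotype tables (with ambiguity and missing loci), estimates
haplotype frequencies, derives allele/haplotype/phenotype tables, computes
singleton-based diversity with equal-sample-size resampling intervals, and
summarizes between-population structure.

## The method

Under Hardy–Weinberg equilibrium a diplotype `{h1, h2}` has probability
`2 f(h1) f(h2)` (heterozygous) or `f(h)²` (homozygous). Frequencies `f` are
maximum-likelihood estimates from an EM algorithm over each donor's set of
diplotype hypotheses. To keep mixed-resolution data tractable the pipeline
estimates *blocks*, growing them one locus at a time in the order
(A ~ B), +C, +DRB1, +DQB1; after each block's EM converges, every donor's
posterior is truncated to 99.9999% cumulative probability before the next
locus multiplies the hypothesis space. Donors untyped at a locus are
imputed from alleles present in the population. The final per-donor
posteriors yield:

- haplotype, allele and phenotype frequency tables (reporting cutoff 1e-4,
  six decimals; internal tables uncut);
- maximum-a-posteriori diplotypes/phenotypes, singleton diversity
  summaries, and subsampled 95% intervals (n = 1000, 10 000 draws);
- Nei's standard genetic distance `D = −ln(Jxy/√(Jx·Jy))` between
  populations, neighbor-joining and UPGMA trees (negative branches clamped
  to 0), and shared top-k frequency profiles for heatmap clustering.

A synthetic registry generator (`simulate_registry()`) produces donors from
a known truth distribution, degraded through typing-era profiles, so every
estimation claim is testable without access to real donor-level data. See
`vignettes/haplodiv-methods.Rmd` for the full model description and design
rationale.

## Worked example

```r
library(haplodiv)

sim    <- simulate_registry(list(n_donors = 2000, n_haplotypes = 20,
                                 alleles_per_locus = 6), seed = 42)
parsed <- parse_donors(sim$donors, sim$table)
pipe   <- run_block_pipeline(parsed$donors)

glance(pipe)
#>   n_donors n_haplotypes logLik n_blocks n_flagged
#> 1     2000           91 -9061.        4         0

top_k(tidy(pipe), 5)
#>   haplotype                                     frequency
#> 1 A*06:01~B*01:01~C*02:01~DRB1*06:01~DQB1*01:01    0.181
#> 2 A*03:01~B*04:01~C*03:01~DRB1*01:01~DQB1*01:01    0.136
#> 3 A*02:01~B*03:01~C*01:01~DRB1*01:01~DQB1*03:01    0.0806
#> 4 A*06:01~B*04:01~C*04:01~DRB1*03:01~DQB1*03:01    0.0698
#> 5 A*02:01~B*01:01~C*01:01~DRB1*01:01~DQB1*05:01    0.0635

dip <- map_diplotype(pipe$posterior)
ph  <- map_phenotype(pipe$posterior)
singleton_summary(dip, ph, "SIM")
#>   population n_donors n_unique_haplotypes pct_haplotype_singletons ...
#> 1 SIM            2000                  19                        0
```

The `glance()` row says the fit used all 2000 donors across the four
estimation blocks with no donor flagged for posterior collapse; the 91
haplotypes with nonzero frequency include a thin imputation tail beyond the
20 truth haplotypes. The ranked table lists the most frequent estimated
five-locus haplotypes (18.1% for the top one here — heavily skewed, as
registry distributions are). The diversity row shows this small simulated
population is far less diverse than a real registry subpopulation: only 19
distinct MAP haplotypes and no singletons. The estimate is within 0.027
total variation distance of the generating truth.

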
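---
title: "Estimating HLA haplotype frequencies and diversity from registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating HLA haplotype frequencies and diversity from registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Unrelated stem-cell donor registries accumulate HLA typings over decades.
The result is data that is simultaneously *mixed-resolution* (serological
assignments, allele groups, full allelic typings), *ambiguous* (a typing may
be compatible with several two-field alleles), *unphased* (genotypes, not
haplotypes, are observed) and *structurally incomplete* (whole loci were
simply not typed in earlier recruitment eras — HLA-C and HLA-DQB1 joined
routine panels late in most registries' histories). Match prediction,
donor-pool planning and diversity assessment all need five-locus haplotype
frequencies for HLA-A, -C, -B, -DRB1 and -DQB1 at antigen-recognition-site
(ARS, two-field) resolution, so the missing structure has to be modelled
rather than discarded.

`haplodiv` implements the full path from raw typing strings to haplotype,
allele and phenotype frequency tables, singleton-based diversity summaries
with resampling intervals, and between-population structure (Nei's standard
genetic distance, neighbor-joining and UPGMA trees, shared-profile
clustering). Because registry donor-level data cannot generally be shared,
the package also includes a synthetic registry generator with known truth,
which is what every estimation claim in the test suite is validated
against.

## The model

Let $f(h)$ be the frequency of haplotype $h$ in a random-mating population.
Under Hardy–Weinberg equilibrium a donor's unordered haplotype pair
(diplotype) $\{h_1, h_2\}$ has probability

$$P(\{h_1,h_2\}) = \begin{cases} 2 f(h_1) f(h_2) & h_1 \neq h_2 \\
f(h_1)^2 & h_1 = h_2. \end{cases}$$

A donor's typing defines a set of diplotype hypotheses: every assignment of
candidate alleles to the two chromosomes consistent with the observed
(possibly ambiguous) genotypes. The observed-data likelihood sums
$P(\{h_1,h_2\})$ over each donor's hypothesis set, and the EM algorithm
alternates:

* **E-step** (`e_step()`): posterior probability of each hypothesis given
  the current frequencies, normalized per donor;
* **M-step** (`m_step()`): $f(h) = \frac{1}{2N}\sum_d \sum_{\text{pairs}}
  P(\text{pair}) \cdot \#\{h \in \text{pair}\}$.

The log-likelihood is non-decreasing across iterations; the suite asserts
this on every fit it runs.

### Block-wise estimation with truncation

Enumerating five-locus hypotheses directly is infeasible for donors with
missing loci (the hypothesis space is a product over loci). The pipeline
(`run_block_pipeline()`) therefore grows haplotype *blocks* in a fixed
order — the (A, B) core first, then C, DRB1, DQB1:

1. enumerate (A~B) pair hypotheses (`enumerate_initial_pairs()`), fit by EM;
2. truncate each donor's posterior to its shortest descending-probability
   prefix holding 99.9999% of the mass (`truncate_posterior()`), always
   keeping at least the top pair, and renormalize;
3. extend every retained pair by the next locus (`extend_block()`): a typed
   donor contributes both assignments of each candidate genotype's alleles
   to the two haplotypes; an untyped donor is *imputed* with every allele
   pair from the imputation alphabet;
4. refit by EM, seeded with the parent-pair probabilities split uniformly
   over each parent's children, and repeat until all five loci are in.

Truncation is what keeps the procedure tractable: after each block's EM has
concentrated the posterior, hypotheses carrying only vanishing mass — for
imputed donors, the vast majority — are dropped before the next extension
multiplies them. At the default threshold this changes final frequencies by
less than $10^{-6}$ total variation on test registries (the suite checks the
truncation-free comparison directly), because the discarded tail is bounded
by $10^{-6}$ of each donor's mass per block.

The imputation alphabet for an untyped locus is the set of alleles observed
among typed donors' candidates at that locus. An estimate of the new locus
does not exist before its block is fitted, so "alleles existing in the
population" is the operational reading; an explicit `alphabet` argument
overrides it. A consequence worth stating: donors missing a locus inform
the extended block only through their retained core-block pairs, and their
posterior mass at the new locus distributes along the population's
frequencies — such donors stabilize marginals but carry no information about
linkage between the new locus and their untyped one.

### Numerical choices

* Convergence: relative log-likelihood improvement below `tol = 1e-6`, at
  most `max_iter = 1000` iterations (per block).
* Initialization: uniform over each donor's hypothesis set; block
  extensions seed the next fit with parent-pair mass. The HWE likelihood at
  desk scale is well-behaved under a single start; symmetric saddle points
  exist in principle (a lone double-heterozygote donor), which is why the
  oracle-equivalence tests run on instances with enough donors to break the
  symmetry.
* Frequencies below `1e-15` are pruned to zero each M-step (memory floor,
  distinct from the `1e-4` *reporting* cutoff, which is applied only when
  writing tables).
* Donors whose every hypothesis reaches probability zero (possible after
  aggressive pruning) are re-seeded with a `1e-12` frequency floor and
  counted in `n_flagged` rather than dropped.
* All orderings (pair canonicalization, ties in ranking, MAP tie-breaks)
  use a total order on alleles — (locus, first field, second field,
  expression suffix), numerically on the fields — so every output is
  deterministic.

## Nomenclature handling

Typing strings are normalized to two-field ARS names (`parse_allele_name()`),
with third/fourth fields discarded and expression suffixes (N/L/S/Q/A)
retained as metadata. Low-resolution tokens (serological labels,
first-field codes, multi-allele codes) are resolved through a user-supplied,
versioned *expansion table*; the package deliberately bundles no
nomenclature catalogue, because catalogue releases are external and mutable
and silently baking one in would make analyses irreproducible. Null-expressed
(`N`-suffixed) alleles are excluded from expansions by default since they
present no ARS protein; `drop_null = FALSE` restores them. A genotype cell
with a single token list is an error by default — registry exports disagree
on whether it means homozygosity or an untyped second chromosome, and
guessing is worse than failing; `single_as_homozygous = TRUE` opts into the
homozygous reading, which is the common export convention.

Donors missing HLA-A or HLA-B typing are excluded on read and itemized in
an exclusion report: the (A, B) core block cannot be formed for them.

## The synthetic registry

`simulate_registry()` composes:

* `generate_truth()` — `n_haplotypes` distinct five-locus haplotypes with
  frequencies drawn from a symmetric Dirichlet. Alleles are drawn from
  rank-skewed (weight $1/\text{rank}$) per-locus pools, so haplotypes share
  common alleles; this structural sharing is what stands in for linkage
  disequilibrium and is what makes block extension non-trivial. Defaults:
  30 haplotypes, 8 alleles per locus, concentration 0.5 — a deliberately
  heavy-tailed frequency spectrum, since real registry haplotype
  distributions are dominated by a few common haplotypes with a long rare
  tail.
* `sample_donors()` — two haplotypes per donor, i.i.d. from the truth
  (Hardy–Weinberg random mating).
* `degrade_typing()` — assigns each donor to a typing-era profile and masks
  loci the era did not type; with probability `ambiguity_rate` a typed
  allele is reported as its first-field ambiguity group (slash-string). The
  default four-era mix spans an early A/B-only serology-like era (weight
  0.25, ambiguity 0.5) through a full five-locus low-ambiguity era (weight
  0.30, ambiguity 0.05), mirroring the structured missingness a long-running
  registry accumulates. HLA-A and HLA-B are always typed, so no simulated
  donor trips the inclusion rule unless a test injects violations
  deliberately.

What the generator does *not* emulate: real linkage-disequilibrium
patterns of specific populations, genuine serology-to-allele mapping
quirks, typing error, relatedness, or population substructure within a
label. Recovery results on synthetic registries therefore demonstrate that
the estimator solves the inverse problem it was built for — phase,
ambiguity and era-structured missingness under HWE — not that any specific
real-world registry is free of HWE violations or imputation bias. On real
mixed-resolution data the same caveat the registry literature makes applies
here: rare haplotypes are underrepresented, because imputation borrows from
the common ones.

Study-scale checks in the test suite use 5000 fully typed donors with a
20-haplotype truth (recovered within 0.05 total variation distance) and
4000 era-degraded donors with a 30-haplotype truth (within 0.08); the
problem sizes keep a full suite run in minutes while leaving the sampling
error well below the tolerance being asserted.

## Frequencies, diversity, resampling

Allele, haplotype and phenotype frequency tables all come from the same
posterior summation; allele tables marginalize the haplotype table exactly
(asserted to $10^{-12}$). Phenotypes are unordered per-locus genotypes, so
both phasings of a double heterozygote contribute to one phenotype.
Reporting uses the `1e-4` cutoff and six decimal places; all internal
computation uses uncut tables.

Diversity follows the singleton convention: assign each donor their
maximum-a-posteriori diplotype (`map_diplotype()`) and phenotype
(`map_phenotype()`, which pools phasings before the argmax), then count
objects seen exactly once. `pct_haplotype_singletons` is a percentage of
*unique* haplotypes, not of haplotype copies, matching the registry
reporting convention. Equal-sample-size comparisons
(`subsample_statistic_ci()`) draw 1000 donors *without replacement* 10 000
times by default and report the median with 2.5/97.5 percentile bounds —
"random samples from the full subpopulation" reads as subsampling
individuals, not bootstrap resampling, and the percentile interval avoids a
normality assumption; both choices are arguments, not constants. MAP
assignments are computed once on the full population and reused across
draws; recomputing posteriors within each subsample would couple the
resampling to estimation noise and costs three orders of magnitude more.

## Between-population structure

Nei's standard genetic distance
$D = -\ln\!\left(J_{xy} / \sqrt{J_x J_y}\right)$ is computed on full
(uncut) haplotype frequency tables aligned on the union universe.
Distances are computed uncut because the reporting cutoff is a
presentation rule; cutting first can only remove shared support, and
populations with *no* shared support have infinite distance, which the
package surfaces explicitly (warning; the tree builders refuse non-finite
input) instead of substituting a silent cap. Neighbor joining is the
classic Saitou–Nei agglomeration with negative branch estimates clamped to
zero afterwards; heatmap-style clustering uses Pearson correlation
distance with UPGMA, on raw frequency profiles (row/column scaling before
clustering is left to the caller, as the choice is cosmetic and
data-dependent). Shared profiles take the union of per-population top-$k$
lists (top-5 haplotypes, top-20 alleles in the registry analysis)
with duplicates removed.

## Known limitations

* HWE is assumed within each labelled population; admixture and
  substructure bias frequencies in ways the model cannot see.
* Imputed loci carry no linkage information for the donors they are imputed
  in; era composition therefore bounds how well late-panel loci (DQB1
  especially) can be linked to early-era donors.
* Confidence intervals on the frequency estimates themselves are out of
  scope; the resampling intervals quantify sampling variability of
  diversity statistics, not estimation uncertainty.
* The EM re-runs to convergence after every block extension. A single-pass
  weighting variant would be faster and slightly less accurate; re-running
  is the conservative reading of a blocks/imputation design and is what the
  recovery tolerances were established under.

## A worked example

```{r, eval = FALSE}
library(haplodiv)

sim <- simulate_registry(list(n_donors = 2000, n_haplotypes = 20,
                              alleles_per_locus = 6), seed = 42)
parsed <- parse_donors(sim$donors, sim$table)
pipe <- run_block_pipeline(parsed$donors)

tidy(pipe)                       # five-locus haplotype frequencies
glance(pipe)                     # fit summary
top_k(tidy(pipe), 10)            # ranked table

dip <- map_diplotype(pipe$posterior)
ph  <- map_phenotype(pipe$posterior)
singleton_summary(dip, ph, "SIM")
subsample_statistic_ci(dip, ph, "haplotype_singletons",
                       n = 1000, reps = 10000, seed = 7)
```
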
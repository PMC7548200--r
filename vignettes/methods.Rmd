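---
title: "Models and methods in rivergsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rivergsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rivergsi` analyses how historical translocations reshape the genetic
structure of river-dwelling salmonid populations and how that, in turn,
affects genetic stock identification (GSI). This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generator does and does not emulate. No
empirical claim is made here beyond what the package's tests and the
acceptance suite themselves compute.

## The river network and stream distance

A basin is a rooted tree of named nodes, each carrying a river-kilometre
(rkm) coordinate measured from a common downstream reference; rkm strictly
increases away from the root, so each edge has a positive length. Every
population sits on exactly one node — the convention being the lowest
detection site within the population's reach. The stream distance between
populations a and b is the along-channel path length

d(a, b) = rkm(a) + rkm(b) − 2·rkm(LCA(a, b)),

with LCA the lowest common ancestor. The formula is invariant to the choice
of rkm origin, which is why no assumption is needed about whether
coordinates are measured from the basin mouth or a larger river's mouth.
Braided channels are not modelled: the basins this is designed for are
dendritic, and single-rkm coordinates (the tagging-infrastructure
convention) only make sense on a tree.

## The drift model behind the simulator

Allele frequencies evolve down the network by hierarchical Balding–Nichols
draws: given a parent node frequency p and an edge of length L km, the
child frequency is Beta-distributed with mean p and variance F·p(1−p),
where

F_edge = 1 − exp(−L/τ).

This was chosen over forward Wright–Fisher simulation because it gives
analytic control of per-edge differentiation and desk-scale runtime, and
because every analysis in the package consumes only frequencies and
genotypes, never haplotypes. Compounding along a path of total length D
gives differentiation ≈ 1 − exp(−D/τ), approximately linear in D for small
F — exactly the regime in which the Rousset linearisation (below) is the
right response scale. Genotypes are Binomial(2, p) within populations
(Hardy–Weinberg by construction), masked missing independently at a
configurable rate.

### Parameters and defaults (the stated world)

| parameter | default | units | why |
|---|---|---|---|
| `n_loci` | 176 | loci | a basin-scale SNP panel after QC removals |
| `ancestral_freq_range` | (0.1, 0.9) | — | informative SNPs are ascertained away from fixation |
| `tau_km` | 7500 | km | see below |
| `n_per_collection` | 50 | fish | mid-range of 20–1,500 per collection |
| `missing_rate` | 0.03 | — | within the 1–10% range typical of SNP panels |
| `years` | 2010–2017 | spawn years | an eight-year return series |
| `n_sites` | 2 | sites/population | enough to exercise site-level tests |
| `alpha_mix` | 1 | — | complete founder replacement; the historical admixture fraction is unpublished, so this is a modelling choice, not an inference |
| `F_t` | 0.01 | — | modest post-translocation drift over ~50 years |

The drift scale τ was fixed *before* any acceptance measurement by a
moment argument: the pairwise Weir–Cockerham θ between two leaves is
approximately half the compounded path differentiation,
θ(D) ≈ (1 − exp(−D/τ))/2 ≈ D/(2τ), because each leaf contributes only its
own branch's drift to the between-pair variance. With the example basin's
pair distances of 90–1000 km, τ = 7500 km puts pairwise θ at ≈ 0.006–0.065,
the range stated for the study system. These defaults are the stated world;
they are not revisited to make tests pass.

### What the generator does not emulate

Linkage, selection, overlapping generations, age and sex structure,
genotyping error (beyond missingness), and detection-efficiency artefacts
are all absent. A green test on synthetic data therefore establishes that
the estimators and tests behave correctly under drift, sampling noise and
missingness — not that they are robust to those unmodelled features.
Hardy–Weinberg violations never arise in simulated populations by
construction; QC tests are exercised with purpose-built fixtures that mix
two diverged frequency draws within one collection (a Wahlund effect),
which inflates homozygosity at chosen loci.

## Quality control

The filter order is fixed and logged: call-rate, then Hardy–Weinberg locus
filter, then homogenisation.

* **Call rate.** Individuals with < 90% successful calls are removed.
* **Hardy–Weinberg.** The test is the exact conditional test — enumerate
  every heterozygote count compatible with the observed allele counts, and
  sum the probabilities of outcomes no more probable than the observed one
  (two-sided). The exact test was preferred over χ² because collections as
  small as ~20 fish are admitted. A locus is removed only for heterozygote
  *deficit* (f̂ = 1 − H_obs/H_exp > 0) significant at the adjusted α in
  strictly more than half of the population × year units tested within any
  single year; excess never removes a locus.
* **Differentiation tests.** The statistic is overall multilocus θ across
  groups; the null permutes individuals' labels. The p-value convention is
  (1 + #{θ* ≥ θ_obs})/(n_perm + 1): never zero, ties counted conservatively.
  Note the interaction between permutation count and the Bonferroni-adjusted
  α = 0.05/115 = 4.35 × 10⁻⁴: with fewer than ~2,300 permutations the
  p-value floor cannot beat α, so nothing can ever be flagged. The default
  10,000 permutations gives a floor of ~10⁻⁴; scaled-down tests use ≥ 2,499.
  The Bonferroni family size is taken from configuration (planned tests),
  not recomputed from the realised count.
* **Homogenisation.** Per population (tested only when it holds strictly
  more than the minimum collection size): test across spawn years; if
  differentiated, first test detection sites within each testable year and
  iteratively remove sites significantly differentiated from the rest of
  their year; then re-test years and iteratively remove the most
  differentiated year (largest one-vs-rest θ) while its one-vs-rest test is
  significant. Where removal cannot localise the signal — e.g. exactly two
  mutually differentiated years — the population is kept with its years
  flagged as separate classes, and pairwise θ involving it is computed per
  year-class pair and arithmetically averaged (one value per population
  pair). Homogeneous collections are pooled before θ; the alternative
  (averaging undifferentiated year classes too) was rejected because
  pooling uses the data at full sample size.

## Weir–Cockerham θ

Per-locus variance components a (among populations), b (among individuals
within populations) and c (within individuals) follow the 1984 moment
estimator, computed from per-group sample sizes, allele frequencies and
observed heterozygote frequencies; the multilocus estimate is the ratio of
sums Σa / Σ(a+b+c) — not the mean of per-locus ratios. Negative components
are retained, so small negative multilocus θ values occur under weak
differentiation; the IBD analysis must see that sampling behaviour, so they
pass through (θ/(1−θ) is slightly negative there too). Loci with calls in
fewer than two groups, or monomorphic across all groups at a pair, are
skipped.

## GSI

Baseline frequencies use per-allele pseudocounts,
(x + ε)/(2n + 2ε) with ε = 0.5 by default (Jeffreys-style), keeping every
frequency strictly inside (0,1) so that mixture fish carrying alleles
unseen in a stock retain finite likelihood. The genotype likelihood is the
product of Hardy–Weinberg genotype probabilities over non-missing loci.
Self-assignment is leave-one-out (the fish's own alleles subtracted before
frequencies are recomputed — verified in tests against a full baseline
rebuild) under equal priors; mixture analysis uses full EM on the mixing
proportions (E-step responsibilities, M-step means), with the allocate-sum
convention — mixture posteriors use the estimated π as priors, and each
fish is assigned wholly to its maximum-posterior stock. Convergence is
max|Δπ| < 10⁻⁸ or 5,000 iterations; the observed log-likelihood is asserted
non-decreasing at every step. Equal priors for self-assignment but mixture
priors for mixture fish mirrors standard GSI practice, which treats
baseline evaluation and mixture estimation as different inference problems.

## Isolation by distance and the equivalence test

The response is y = θ/(1−θ) per population pair, regressed by OLS (with
intercept) on stream distance, each unordered pair used once. Pairs are not
independent, so OLS p-values are meaningless here; significance of the IBD
association comes from a Mantel permutation test (Pearson correlation of
upper triangles, rows/columns of one matrix jointly permuted, one-tailed
"greater" for positive IBD — a recorded convention choice). The OLS slope
standard error is retained because the equivalence test consumes it.

The equivalence test asks whether a test set of populations follows a
reference set's IBD line while honouring uncertainty in that line. Per
replicate, a slope b* ~ Normal(b̂_ref, SE_ref) is drawn; the residual matrix
R = y_test − b*·d_test is formed (the intercept is omitted because Pearson
statistics are invariant to additive constants — only the slope matters);
T_obs is the Mantel correlation of R with d_test, and T_rand its
correlation with one fresh joint permutation of d_test. The p-value is
(1 + #{T_rand < T_obs})/(n_rep + 1); a small value means residuals
unusually *negatively* associated with distance — differentiation depressed
below the reference line, the translocation signature. Two design points
were genuinely open and are resolved as follows:

* **Per-replicate T_obs.** The source description is ambiguous about
  whether each T_rand is compared to a single fixed T_obs or to its own
  replicate's T_obs. Since the residual matrix changes with every sampled
  slope, comparing within replicate is the coherent reading and is what is
  implemented; one joint permutation of the distance matrix is drawn per
  replicate, so n_rep replicates yield n_rep randomisations.
* **Reference = excluding set.** The reference regression is fit on the
  population set that excludes the translocation targets, and that same
  reference is used for both the full-set test and the relocated-set test.

**The no-translocation control.** A scenario without a translocation event
has no targets, hence nothing to exclude and nothing to relocate: its three
IBD analyses coincide and every equivalence test compares the full set with
its own fitted line, which is non-significant by OLS orthogonality
(residuals are uncorrelated with the regressor). The alternative reading —
exclude and relocate the would-be targets even though no translocation
occurred — was rejected because relocating populations *away from their
true locations* necessarily manufactures a significant result (their
genetic distances still reflect where they actually live); under that
reading no simulator could ever satisfy a non-significance control, which
indicates it is the wrong reading, and probe runs confirmed p at the
permutation floor in every seed.

## Chord distance, neighbor joining, bootstrap

The Cavalli-Sforza–Edwards chord distance is computed per locus as
d² = 2(1 − Σ√(p·q)) over alleles and aggregated as the square root of the
mean over loci. The classical 2/π angular scaling is omitted — a recorded
convention choice; programs differ here, and NJ topology and bootstrap
supports are invariant to monotone rescaling. Chord distances use observed
frequencies with zero pseudocount (pseudocounts are a GSI likelihood
device, not a distance device).

Neighbor joining is implemented in-package so the tie-break is
deterministic: labels are sorted canonically on entry and equal Q-criterion
values resolve to the lexicographically first pair. Negative branch lengths
(possible on non-additive input) are clamped to zero and counted. On
additive matrices the algorithm is exact (verified against constructed
trees and against an independent reference implementation). Bootstrap
resamples *loci* with replacement — matching how the distance is an average
over loci — rebuilding the distance matrix and tree each replicate; support
for each internal edge of the point-estimate tree is the percentage of
replicates containing the same bipartition (point-tree annotation, not a
majority-rule consensus, so the support labels map directly onto the
reported tree). Supports ≥ 80% are highlighted, the conventional display
threshold.

## Determinism and numerical conventions

* Every stochastic routine takes an explicit integer seed; pipeline stages
  derive seeds from the master seed as (master·1000003 + k) mod (2³¹ − 1).
* Permutation p-values are never 0 and never exceed 1.
* Exact HWE enumeration compares probabilities with a 1 + 10⁻¹² relative
  tolerance so that mathematically tied outcomes are included.
* EM posteriors and Mantel correlations are computed with log-sum-exp and
  upper-triangle extraction respectively; genotype dosage is always the
  count of a per-locus reference allele, and all statistics are invariant
  to which allele is chosen (tested).
* Missing genotypes are a sentinel, never imputed; they simply drop out of
  counts, likelihood sums and call-rate denominators.

## Known limitations

Single-parent dendritic networks only; biallelic loci (the chord distance
is written generally but exercised biallelic); no LD pruning, relatedness
filtering, or genotyping-error model; no Bayesian (MCMC) mixture
estimation; no partial Mantel tests; no tree visualisation beyond Newick
export. The equivalence test's null calibration inherits the reference
slope's estimation error; with very few reference populations its p-values
drift anticonservative, which is why conclusions in the pipeline report are
phrased as contrasts across population sets rather than single p-values.
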
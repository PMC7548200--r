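# rivergsi

Population-genetic analysis of dendritic river basins where hatchery
translocations may have reshaped genetic structure — and with it, the
reliability of genetic stock identification (GSI).

Anadromous salmonids home to their natal streams, so genetic
differentiation normally accumulates with stream distance (isolation by
distance, IBD). Fisheries managers exploit that structure to assign fish of
unknown origin to reporting units from SNP genotypes. When a headwater
basin has historically been stocked with fish trucked in from a distant
source, the headwater populations come to resemble the source instead of
their neighbours: basin-wide IBD weakens, and GSI assignment confidence
drops even where assignment accuracy stays high. `rivergsi` implements the
full analysis chain for detecting and quantifying that effect, plus a
synthetic-data generator for exercising it end to end.

## What it computes

* **Genotype QC** — individual call-rate filter (default ≥ 0.90); exact
  conditional Hardy–Weinberg tests per population × year with removal of
  loci showing a heterozygote deficit (`f̂ = 1 − H_obs/H_exp > 0`,
  `p < α/m`) in more than half the units tested in a year; permutation
  tests (multilocus θ statistic) of differentiation across spawn years and
  detection sites at a Bonferroni-adjusted α (e.g. 0.05/115 = 4.35 × 10⁻⁴),
  with removal of differentiated year/site cohorts.
* **Differentiation** — multilocus Weir–Cockerham θ (ratio of summed
  variance components a / (a+b+c); negative components retained), with
  per-year-class averaging for populations whose spawn years remain
  differentiated.
* **GSI** — pseudocount-adjusted baseline allele frequencies; Hardy–Weinberg
  genotype likelihoods; leave-one-out self-assignment; full-EM mixture
  estimation of stock proportions π; allocate-sum assignment with
  accuracy matrices and assignment-probability CDFs.
* **Isolation by distance** — Rousset linearisation θ/(1−θ) regressed on
  stream distance (computed on a rooted river network as
  `rkm_a + rkm_b − 2·rkm_LCA`); Mantel permutation tests; a
  slope-uncertainty **equivalence test** that asks whether one population
  set follows another set's IBD line (slopes drawn from
  Normal(b̂, SE(b̂)), residual matrices correlated against observed vs
  permuted distance matrices); and a relocation counterfactual that
  analytically moves populations to the translocation source.
* **Phylogeny** — Cavalli-Sforza–Edwards chord distance, neighbor joining
  with deterministic tie-breaks, locus-bootstrap branch support, Newick
  export.
* **Simulator** — hierarchical Balding–Nichols drift along the river
  network (per-edge differentiation `1 − exp(−length/τ)`), binomial
  genotypes under within-population HWE, configurable missingness, and an
  optional translocation event.

## Worked example

A translocation scenario on the bundled 20-population example basin:
populations `P16`–`P19` (headwaters) were founded from `P07` (a dam-site
stock far away by river but not by ancestry).

```r
library(rivergsi)
net <- example_river_network()
p   <- sim_params(n_loci = 120, n_per_collection = 30, years = 2010, seed = 42)
fr  <- simulate_allele_frequencies(net, p, seed = 42)
fr  <- apply_translocation(fr,
         translocation_event("P07", c("P16","P17","P18","P19")), seed = 43)
g   <- sample_genotypes(fr, p, seed = 44)

th <- pairwise_fst_matrix(g)$theta
th["P16","P07"]   # 0.00197  -- headwater vs distant source: nearly identical
th["P16","P15"]   # 0.0487   -- headwater vs nearby neighbour: differentiated

y <- rousset_linearize(th)
d <- stream_distances(net, rownames(y))
ref <- setdiff(rownames(y), c("P16","P17","P18","P19"))
mantel_test(y, d, 999, seed = 1)$rho                  # 0.39 (all populations)
mantel_test(y[ref,ref], d[ref,ref], 999, seed = 2)$rho # 0.90 (excluding targets)

fit_ref <- ibd_regression(y[ref,ref], d[ref,ref])      # slope 6.41e-05 per km
ibd_equivalence_test(fit_ref, y, d, 2000, seed = 3)$p_value
# 5e-04: the full set does NOT follow the reference IBD line

d_rel <- stream_distances(relocate_populations(net,
           setNames(rep("hcd", 4), c("P16","P17","P18","P19"))), rownames(y))
ibd_equivalence_test(fit_ref, y, d_rel, 2000, seed = 4)$p_value
# 0.33: moving the targets to the source node restores equivalence
```

The translocated populations are nearly indistinguishable from their distant
source (θ ≈ 0.002) while strongly differentiated from their geographic
neighbours (θ ≈ 0.049); basin-wide Mantel ρ collapses from 0.90 to 0.39; the
equivalence test flags the departure from the reference IBD line and is
silenced by the relocation counterfactual — the signature of a successful
historical translocation.

The whole chain (including QC, GSI and the bootstrapped NJ tree) runs as one
call: `run_pipeline(scenario_config(...), seed)`; a command-line front end
is installed at `system.file("cli", "rivergsi", package = "rivergsi")`.

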
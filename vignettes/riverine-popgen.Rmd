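---
title: "Microsatellite population genetics over river networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite population genetics over river networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverpg)
```

`riverpg` implements the analysis chain used to ask whether an invasive,
human-associated mosquito such as *Aedes aegypti* spreads between
settlements by human transport rather than by its own (very limited)
flight: per-site diversity and inbreeding from diploid microsatellite
panels, exact Hardy-Weinberg tests, pairwise F_ST with permutation
significance, hierarchical AMOVA, Mantel tests of isolation by distance
under several geographic and transport-based distance models, and
Bayesian admixture clustering with Delta-K model choice. This vignette
records the models, the conventions, and the choices made where the
design was genuinely open.

## Data model and conventions

A `genotype_table` stores two integer allele labels per (sample, locus)
call, canonicalised as an unordered pair, plus the sampling site of every
individual and an optional site-to-group map. One missing-data code is
used internally; the GenePop `000`/`00` convention and the CSV `-`
convention both map to it, and a call with either allele missing is
treated as wholly missing. All estimators use per-locus pairwise
deletion: an individual missing at a locus is excluded from that locus
only. Sample sizes therefore vary by locus, which is why every per-locus
statistic carries its own `N`.

### Allele binning from fragment sizes

Raw capillary-electrophoresis output is a pair of real-valued fragment
lengths per call. `bin_fragments()` converts these to integer allele
labels by single-linkage gap clustering: within a locus, sorted unique
sizes are split wherever consecutive sizes differ by at least
`gap_fraction * motif_length` (default `gap_fraction = 0.5`), each
cluster becomes one allele, and the label is the repeat-number offset
from the smallest cluster, `1 + round((mean - mean_min)/motif)`. Two
consequences are deliberate:

* labels are invariant to instrument-wide size shifts and to input
  order, and they increase strictly with fragment size;
* labels are *relative* offsets, so a locus where the shortest possible
  allele never occurs still starts at label 1. Round-trip recovery from
  simulated panels is exact only up to this per-locus offset, which is
  irrelevant to every downstream statistic (all are label-invariant).

Single-linkage is susceptible to chaining: with many copies per locus
and sizing noise approaching `motif/4`, the tails of adjacent clusters
can join. If two clusters survive the gap rule but round to the same
repeat offset the function raises a binning-conflict error naming the
locus and sizes rather than silently mislabelling. The validation suite
sizes its round-trip experiment at roughly 50 copies per locus with
0.3 bp noise on a 3 bp motif, where recovery is complete.

## Diversity and inbreeding

Observed heterozygosity is the fraction of heterozygous individuals;
expected heterozygosity is Nei's unbiased gene diversity
`He = 2n/(2n-1) * (1 - sum(p^2))` over the `2n` observed gene copies.
The inbreeding coefficient is reported in the gene-diversity form
`Fis = 1 - Ho/He` (negative values = heterozygote excess), with an
explicit undefined flag where `He = 0`. The multilocus site summary
weights loci by their per-locus sample sizes,
`Fis = 1 - sum(Ho_l N_l) / sum(He_l N_l)`, so loci with more missing
data contribute less. Variance-component estimators (Weir-Cockerham `f`)
would give slightly different per-locus values; published tables
computed that way should be compared qualitatively, not digit by digit.
Under the package's inbreeding-mixture generator the estimator recovers
the generating coefficient directly (0.3 within ±0.05 at n = 500), which
is the calibration the tests assert.

## Exact Hardy-Weinberg tests

Conditional on the observed allele counts, the probability of a genotype
array under random mating is Levene's distribution
`P = n! prod(n_i)! 2^H / ((2n)! prod(n_ij)!)`, with `H` the number of
heterozygotes. The test p-value is the total probability of arrays no
more probable than the observed one. Two engines are provided:

* **Enumeration** walks every array with the observed allele counts.
  It is exact, and doubles as the oracle for the chain engine, but its
  array space explodes combinatorially; the automatic switch in
  `hwe_table()` uses it only up to 3 alleles and 25 individuals.
* **Markov chain**: the observed `2n` gene copies are kept as an
  explicit pairing into individuals, and each step picks two individuals
  and re-draws the pairing of their four copies uniformly over the six
  matchings — a Gibbs form of the classic two-genotype switch proposal.
  The uniform distribution over pairings induces exactly the Levene
  distribution over arrays, so every move is accepted. The p-value is
  the fraction of post-burn-in states at or below the observed
  probability, with a batch-means Monte Carlo standard error.

Two numerical details matter. Ties in "probability ≤ observed" are
decided with a scale-aware log-space tolerance (`1e-9 * (1 + |log P|)`)
shared by both engines; tied probability classes are common in small
arrays and naive floating-point comparison misclassifies them. And the
chain's incrementally updated log-probability is recomputed exactly
every 8192 steps, because accumulated rounding (~1e-12 over 1e5 steps)
is otherwise large enough to flip tie decisions.

Chain defaults in the pipeline are desk-scale (2e4 steps / 2e3 burn-in);
the `paper_protocol` switch restores the field-protocol 1e6 steps with
1e5 dememorization. Family-wise correction uses the Sidak threshold
`1 - (1-alpha)^(1/m)`; for `alpha = 0.05` over a 9-site × 8-locus panel
(m = 72) this is 0.00071. Calibration is checked by simulating loci
under random mating (50 diploids, 5 Dirichlet-frequency alleles — sizes
at which the discrete exact p-value distribution is close enough to
uniform for a Kolmogorov-Smirnov check; much smaller arrays are visibly
discrete and conservative, which is a property of exact tests, not a
defect).

## Pairwise F_ST

Differentiation between site pairs is Weir & Cockerham's theta. The
among-population (`a`) and total (`a+b+c`) variance components are
accumulated over every allele at every locus and divided once
(ratio-of-sums); averaging per-locus ratios is biased and was rejected.
Monomorphic loci contribute nothing. Significance comes from shuffling
individuals between the two sites (sizes fixed) and counting permuted
thetas at least as large as observed, with add-one smoothing
`(count+1)/(n_perm+1)` so no p-value is exactly zero. Two fixed sites
give theta = 1 exactly; identical sites give values within sampling
noise of zero; under the Balding-Nichols generator with F = 0.05 the
mean recovered theta over 50 replicates falls in [0.035, 0.065].

## Hierarchical AMOVA

The four-level AMOVA partitions gene-copy variance among groups, among
populations within groups, among individuals within populations, and
within individuals, under the allele-identity distance (0 if same
label, 1 otherwise). An R_ST-style squared-repeat-difference distance is
deliberately not used: the package reports F-statistic analogues, and
identity distance is the standard choice for that. Sums of squares are
computed per locus on the individuals scored at that locus and summed,
as are the degrees of freedom — so with complete data the reported df
are (per-level df) × (number of loci), and variance components are
per-locus averages. The unequal-size expected-mean-square coefficients
are accumulated per locus from gene-copy counts. Components are reported
as estimated, including negative ones (truncation would silently break
both the percentage accounting and the F identities); percentages may
therefore be negative and still sum to 100. The F analogues satisfy
`(1-F_IT) = (1-F_CT)(1-F_SC)(1-F_IS)` identically.

Permutation schemes follow the level being tested: whole populations
among groups (F_CT), individuals among populations within groups
(F_SC), gene copies re-paired within populations (F_IS), and gene
copies re-paired across the whole sample (F_IT). With a single group
the among-groups level is degenerate: F_CT is `NA` and F_SC plays the
role of ordinary F_ST. The site-to-group map must be declared
explicitly in the configuration; the pipeline's example hierarchy
groups the four within-city collections against the surrounding towns.

## Distance models, PrPI and isolation by distance

Three geographic models: straight-line distance from projected planar
km coordinates (no geodesy — inputs are assumed pre-projected),
fluvial-path distance (shortest path on the fluvial edges only), and
shortest accessible path (all modes). Unreachable pairs are `Inf` and
excluded from testing rather than imputed.

The propagule pressure index summarises transport linkage:
`PrPI = sum_j gamma_j * theta_j` over vehicle types, where `gamma_j` is
the probability that a vehicle of type j carries the invader and
`theta_j` the trip count between the pair. It is linear in trips and a
*similarity*: more traffic predicts more gene flow, hence lower F_ST.
Because the underlying surveys only record hub-to-town trips, the
matrix is symmetrised by summing both directions, and pairs with no
survey record at all are `NA` (unknown), not zero. When fewer complete
pairs than `min_pairs` (default 6) are available the Mantel test is
skipped and flagged, with only the descriptive correlation reported —
with a hub-and-spoke survey that is 5 observations, too few to test.

Mantel tests correlate the off-diagonal triangles and permute row and
column labels of the second matrix jointly, with add-one smoothing. The
default tail is one-sided: "greater" for distances (isolation by
distance predicts a positive correlation) and "less" for similarities
like PrPI. An exhaustive mode enumerates all `n!` relabelings for
validation at tiny n.

## Admixture clustering and Delta-K

The clustering model is the admixture model with uncorrelated allele
frequencies: individual i draws admixture proportions
`q_i ~ Dirichlet(alpha)`, cluster k draws allele frequencies
`p_kl ~ Dirichlet(lambda)` independently at every locus (the
uncorrelated choice avoids overestimating cluster number), and every
allele copy originates from cluster k with probability
`q_ik p_kl(a)`. The Gibbs sampler alternates copy-origin assignments,
allele frequencies, and admixture proportions; missing calls contribute
nothing (ignorable missingness). `alpha` is fixed (default 1.0,
configurable) rather than sampled — the simpler model is sufficient for
the recovery behaviour tested here. Posterior means of Q and P over the
thinned post-burn-in draws are reported rather than a MAP state.

Model choice uses `lnPD = mean(trace) - var(trace)/2` per run and the
Evanno statistic `DeltaK = |L''(K)| / sd(L(K))` across replicate runs,
selecting the K that maximises DeltaK; DeltaK is undefined at the end
points and wherever replicate spread is zero, and such values are
flagged, not zero-filled. Cluster labels are aligned across runs before
averaging by a greedy bijective permutation maximising the overlap
`sum min(Q_ref, Q_perm)` — with the well-separated posteriors this
package summarises, greedy assignment finds the same permutation an
exact assignment would. Dominant membership uses the >0.8 rule: an
individual is dominantly assigned when its largest coefficient exceeds
0.8.

Default chain lengths are desk-scale (burn-in 2,000, 10,000 iterations,
thin 10); `paper_protocol = TRUE` restores the 1e5/2e5 field protocol.
The validation suite runs shorter chains still (burn-in 300-500,
1,200-2,000 iterations) on 150 individuals × 20 loci, where membership
RMSE under the generating model is below 0.1 and Delta-K recovers K = 3
in at least 8 of 10 replicates.

## Synthetic data: what it emulates and what it does not

All generators are seed-deterministic. The study-shaped defaults
emulate the sampling design this package targets: 9 sites sized
31/20/32/55/76/21/40/35/29, 8 microsatellite loci, 5 alleles per locus.

* `balding_nichols_frequencies()` draws site frequencies from
  `Dirichlet(ancestral (1-F)/F)`, giving per-allele variance
  `p(1-p)F` and expected pairwise F_ST ≈ F. Balding-Nichols was chosen
  over coalescent simulation because it calibrates F_ST directly with
  no external simulator. Default F = 0.05 sits in the low-to-moderate
  differentiation range the method is meant to resolve.
* `sample_genotypes()` adds inbreeding as a mixture: with probability
  F_IS one allele is drawn and duplicated, else two independent draws —
  so the diversity module's Fis estimates the mixture weight directly.
  Default F_IS = 0.15, mid-range for field sites.
* `simulate_admixed_table()` draws from exactly the model the Gibbs
  sampler fits, making K and Q recovery well-posed.
* `simulate_study_region()` builds a seven-town hub-and-spoke river
  basin: pairwise straight-line distances spanning ~15-125 km, fluvial
  edges from the hub to every town (~20-40% longer than straight line),
  exactly one terrestrial edge (the hub-to-Nauta highway, 95 km), a
  star-shaped trips table concentrated on the hub, and vehicle
  infestation probabilities of 0.71 (large barges), 0.35 (medium
  barges) and 0.125 (buses) from published vehicle surveys.
* `simulate_fragment_panel()` inverts allele binning (base + label ×
  motif + Gaussian noise) for round-trip tests.

What the generators do *not* emulate — and therefore what passing tests
do not establish about real data: null alleles, allelic dropout and PCR
stutter; within-household relatedness (an optional clustering switch
exists but is off by default, and true household structure is unknown);
spatially autocorrelated drift (sites are exchangeable draws, so the
synthetic region has no genuine isolation-by-distance signal unless one
is injected); and selection at or near the markers.

## Numerical and reproducibility choices

Permutation p-values always use add-one smoothing. Every stochastic
routine takes an explicit seed, and pipeline stages derive their seeds
from the single configured seed, so a rerun with the same configuration
is byte-identical. Monte Carlo standard errors for the HWE chain come
from 50 batch means. Validation problem sizes were chosen as the
smallest at which each estimator's sampling noise is well inside the
asserted tolerance: 50-replicate means for F_ST recovery, 500
individuals for Fis recovery, 500 simulated loci for p-value
uniformity, and the admixture sizes quoted above.

## Known limitations

Fis and AMOVA estimator variants differ from Arlequin's internal
formulas at the second decimal on small samples; comparisons with
published tables should be qualitative. The AMOVA missing-data
convention (per-locus deletion with per-locus df accumulation) is exact
for complete data and an approximation otherwise. Greedy label
alignment can in principle be suboptimal for heavily overlapping
clusters. The binning rule inherits single-linkage chaining at high
copy density. None of these affect the package's own validation
conditions, which are stated above.
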
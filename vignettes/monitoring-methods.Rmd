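---
title: "Methods: temporal population-genetic monitoring with popgenmon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal population-genetic monitoring with popgenmon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical machinery: the
models and procedures, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The monitoring design

The analysis unit is the *spatial–temporal grouping* (STG): the cross of a
regional label (e.g. an amalgamation of river basin districts) with a
sampling time point. Sampling years are pooled into time points via
explicit rules (`default_pooling_rules()` pools 1993–5 and 1998–2000 into
"1994" and "1999"; later time points are single years), because early
years of a carcass-collection programme rarely yield enough samples
individually. To limit spatial pseudoreplication, `grid_subsample()`
retains a single, uniformly drawn individual per 20 km grid square per
year; 20 km is on the order of an otter home range. The grid is anchored
at the coordinate origin with half-open cells — the anchoring is a
convention, chosen once, since any fixed anchor serves the purpose.

Coordinates are treated as abstract planar kilometres. Region labels are
opaque strings supplied with the data; the package deliberately contains
no GIS polygon logic.

## Diversity statistics

Per locus and group we report observed heterozygosity (heterozygote
fraction among typed individuals) and Nei's unbiased expected
heterozygosity `He = 2n/(2n−1) · (1 − Σ p̂²)`. Group summaries are means
across loci with standard deviations **across loci** — the `±` columns of
the monitoring tables are locus-to-locus spread, not standard errors.

Allelic richness is rarefied hypergeometrically:
`A_r(g) = Σ_a [1 − C(G−c_a, g)/C(G, g)]`, the expected number of distinct
alleles in `g` gene copies drawn without replacement from the observed `G`
copies. The tests verify this equals brute-force enumeration over all
subsamples for every spectrum with up to 12 gene copies. Private allelic
richness follows Kalinowski: `pA_r(f) = Σ_a Q_{f,a} Π_{j≠f} (1 − Q_{j,a})`
with `Q_{j,a}` the presence probability of allele `a` in a rarefied draw
from group `j`. Rarefaction sizes are expressed in *genes* (`g = 2n`);
user-facing summaries take individuals and double internally. Two regimes
are reported: the per-time-point minimum sample size (comparisons within a
year) and a fixed `n = 6` (12 genes; comparisons across all STGs). With
missing data the group-level `g` is the minimum gene-copy count over loci
— the conservative choice.

Null alleles are screened with two closed-form estimators of the
non-amplifying allele frequency, Chakraborty's `(He−Ho)/(He+Ho)` and
Brookfield's `(He−Ho)/(1+He)`. A locus is flagged at a time point when the
estimate exceeds 0.05 in strictly more than half of the regions sampled
there; only loci flagged this way would be dropped from a panel. Both the
threshold and the majority rule are configurable.

Trend testing is deliberately nonparametric: Kendall tau-b (tie-corrected,
normal approximation) within regions over time, Kruskal–Wallis across
regions within years, with groups of fewer than 6 values excluded and
p-values left unadjusted — the monitoring convention is to correct only
the F_IS family (Benjamini–Hochberg) and the correlogram classes (Holm).

## Differentiation and the Wahlund/inbreeding two-stage

θ is the Weir–Cockerham (1984) analysis-of-variance estimator, combined
over alleles and loci as `Σa / Σ(a+b+c)`; negative estimates are reported
as computed. The test suite checks the variance-component route against an
independently coded nested-ANOVA (mean squares) computation. Permutation
tests shuffle individuals between groups with
`p = (1 + #{θ* ≥ θ}) / (n_perm + 1)`. AMOVA uses the allele-identity
distance ("number of different alleles"), decomposing variance among
groups, among individuals within groups, and within individuals;
`Φ_ST = σ_among/σ_total`. On balanced two-deme simulations AMOVA and θ
agree within 0.02.

The Hardy–Weinberg exact test enumerates the Levene conditional
distribution for two alleles. For more alleles it runs a Markov chain on
the underlying arrangement of `2N` gene copies into pairs: swapping two
uniformly chosen copies is a symmetric move, the uniform distribution over
arrangements induces exactly the Levene distribution of tables, and the
p-value is the fraction of visited tables no more probable than the
observed one. This construction avoids the delicate proposal-ratio
bookkeeping of genotype-switch chains; chain and enumeration agree within
0.01 on two-allele tables in the tests. Linkage disequilibrium uses a
Burrows-type composite statistic (dosage correlations summed over allele
pairs, `n Σ r²`), valid without assuming HWE, with a permutation null;
this is a documented substitute for likelihood-ratio LD machinery, so its
acceptance checks are calibration-based rather than value-parity.

F_IS is the single-group Weir–Cockerham `f = 1 − Σc/Σ(b+c)`. Its
significance is assessed two ways: the default permutes alleles among
individuals within the group (destroying departures from random mating
while preserving frequencies and the missing-data pattern; two-sided on
|f|), and a one-sample *t* across per-locus f values is also provided.
The permutation route is the default because it does not treat loci as
independent replicates.

A positive F_IS in a pooled sample is ambiguous: true consanguinity or a
Wahlund effect from pooling differentiated subgroups. The two-stage
procedure fits the admixture model at the group's best K, identifies the
dominant cluster by largest-Q assignment (argmax, not a threshold — a
threshold would leave individuals unassigned), and recomputes F_IS on
dominant-cluster members only. Significant-then-nonsignificant is labelled
`w`; significant twice is `i`; a dominant cluster under 4 members is
`indeterminate`. On simulated regimes (two pooled diverged demes vs a
selfing deme) the labels are recovered in well over 80% of replicates.

## The admixture model

`admixture_gibbs()` is a Gibbs sampler for the no-linkage, no-location
admixture model: gene-copy origins, cluster allele frequencies `P`
(Dirichlet conditionals) and individual ancestries `Q` (Dirichlet with the
shared admixture parameter α) are updated in turn; α moves by Metropolis
under a uniform(0, 10) prior with proposal sd 0.05. The correlated
frequency prior shrinks `P` towards the pooled sample frequencies with
per-cluster drift parameters `F_k` (uniform(0, 1) prior, Metropolis); the
pooled frequencies stand in for the ancestral frequencies rather than
being sampled — a simplification that matters little at the moderate
divergence this model is used for. Missing genotypes are skipped in the
likelihood. K = 1 is returned in closed form (pooled frequencies, Q ≡ 1),
which also anchors the sampler tests.

Defaults are desk-scale (burn-in 10⁴, 5×10⁴ sweeps) so that replicate
scans stay interactive; publication-scale chains (10⁵/10⁶) are a
parameter change. The per-run model score for K selection is
`ln P(D) ≈ mean(lnL) − var(lnL)/2`, and Evanno's
`ΔK = |L(K+1) − 2L(K) + L(K−1)| / sd(L(K))` is computed across replicate
runs. Replicates are aligned by permuting cluster labels to maximise
column-wise Q correlation with the first run (exact assignment up to
K = 8, greedy beyond), then clustered into major/minor modes at mean
aligned correlation ≥ 0.9 — a documented stand-in for CLUMPP's similarity
machinery. Individuals with largest Q below 0.8 are "admixed"; the
percentage admixed per time point is the package's headline gene-flow
indicator alongside Nm.

Progressive partitioning fits K = 2 recursively. The stopping rule needs
to be sharp to be reproducible: a split is accepted only when both
children have ≥ 4 members and the run-averaged largest assignment is
≥ 0.6; otherwise the node is a leaf. Nodes whose replicate runs fall into
several modes are flagged unstable. With small panels this rule can split
a genuinely panmictic group on family structure — the per-split θ is
reported so such splits are visible.

`dapc_lite()` is the assumption-free cross-check: PCA of centred allele
dosages (components retained to 90% variance, mean-imputed missing
dosages), k-means over a K range, `BIC(K) = n·ln(WSS/n) + K·ln(n)`, and
linear discriminants on the chosen clustering. On discrete genotype data
with few effective dimensions the BIC curve can plateau or keep falling —
the same behaviour practitioners know from `find.clusters` — so the curve
itself is returned and the gradient, not only the minimum, should guide K.

## Gene flow from private alleles

The Barton–Slatkin method regresses the log mean frequency of private
alleles on log Nm; the package stores the published regression
coefficients at reference sample sizes of 10, 25 and 50 gene copies and
interpolates them log-linearly to the observed mean sample size before
inverting. Outside the tabulated range the nearest regression is used with
a warning. Private alleles are detected on raw counts (no frequency
floor). The estimator is undefined without private alleles; the series
function propagates such cells as missing. Pairwise estimates use alleles
private within the pair, the natural reading when the estimator is applied
to two groups at a time. Time points with inadequate spatial coverage can
be omitted (`omit =`). On island-model simulations with true Nm = 2 the
median estimate is within a factor of two — the method's documented
accuracy class — and on the recovery-lag scenario the series rises with
the simulated migration schedule.

## Spatial analysis

Geographic distance is least-cost over a binary land/sea raster: land
cells form an 8-connected lattice (orthogonal cost = cell size, diagonal =
√2·cell; 16-connectivity with knight moves at √5 is a flag) and distances
are Dijkstra shortest paths; sea is impassable, points snap to the nearest
land cell within a tolerance, and disconnected land yields missing cells.
Genetic distance between individuals is one minus the mean per-locus
proportion of shared alleles (`Σ_a min(c_i, c_j)/2` per co-typed locus).

Mantel tests use Pearson correlations with joint row/column permutation
(via vegan), default two-sided. The correlogram tests 50-km distance
classes from 0 to 800 km with Holm correction (progressive correction
optional, full-vector default). Values are reported in the ecological sign
convention — positive r means individuals within the class are genetically
more similar than expected — and the raw indicator-Mantel correlation is
emitted alongside (`r_raw = −r`) for anyone wiring the output into other
tools. Sex-stratified variants simply subset (default: adults of one sex)
before the identical computation.

## The synthetic-data generator

`simulate_population()` is a forward Wright–Fisher simulator designed to
emulate the monitoring setting: several regional demes founded from a
shared per-locus allele pool (each deme draws its own subset, so demes
overlap in common alleles and differ in rare ones — unequal founding
numbers create unequal diversity), non-overlapping generations, migration
as multinomial moves of whole individuals, random mating with multinomial
drift, and stepwise mutation reflecting at the configured size bounds
(keeping 3-digit Genepop coding valid) or K-allele mutation. Selfing
excess (for inbreeding regimes) and translocation events are optional.
Sampling draws individuals without replacement at scheduled generations,
attaching region labels, jittered centroid coordinates, and random sex and
age class; demographic sampling bias (e.g. roadkill skew towards young
males) is not modelled. The truth ledger records per-generation allele
frequencies, realized migrant counts, per-sample founding-deme ancestry
fractions, and the island-model reference `1/(1+4Nm)` per epoch.

`scenario_recovery_lag()` is the canned study-like scenario: five demes of
unequal founding diversity (9/8/5/4/4 founder states from a 9-state pool),
13 generations of isolation at N = 40 after the bottleneck, then five
epochs of rising migration (0.005 → 0.10 per generation) with growing deme
sizes (80 → 200), sampled at five time points labelled 1994–2014 (about
two 3-year generations per 5-year interval; otter generation estimates
range from 3 to 7.6 years — the epoch-to-year mapping is labelling, not
dynamics). Sample sizes are 8–26 per deme per time point, ~400 total, 15
loci. These sizes were chosen once so the scenario lands in the regime the
method is meant for — regional He roughly 0.5–0.75, 8–12 alleles per
locus, pairwise θ roughly 0.08–0.22 at the final time point — and produce
the "lag" signature: the Nm series rises across epochs while most pairwise
θ remain above 0.05.

What the generator does **not** emulate: genotyping error and allelic
dropout, fragment-size calibration artefacts between platforms, roadkill
demographic bias, continuous (non-deme) spatial structure, overlapping
generations, and linkage. Tests passing on this generator therefore
validate the estimators' mathematics and the pipeline's plumbing, not
robustness to those real-data pathologies.

## Numerical choices and problem sizes

Rarefaction uses `lchoose` differences for stability. Permutation
p-values are `(1+hits)/(n_perm+1)`, never zero. The Gibbs sampler is
seed-reproducible (one R RNG stream; C++ code uses R's RNG). The HWE chain
refreshes its incremental log-probability every 2¹⁴ steps to cap floating
drift. Ties in Kendall's tau use the tie-adjusted normal approximation;
all-tied vectors are an error except inside `trend_tests()`, where a
constant series is reported as tau = 0. The test suite and the acceptance
script run simulations at deliberately modest sizes (demes of 40–60,
8–15 loci, chains of a few thousand sweeps, 49–199 permutations) — chosen
as the smallest sizes at which the checked properties are stable, with the
full-scale settings one argument away.

## Known limitations

* The admixture sampler fixes the ancestral frequencies of the correlated
  prior at the pooled sample frequencies and shares α across individuals.
* The LD statistic is a composite-correlation screen, not a haplotype
  likelihood-ratio test.
* AMOVA implements the allele-identity distance only (no stepwise
  size-distance option), which matches how global F_ST is usually reported
  in this setting but understates the information in allele sizes.
* Directional migration (assignment-based MCMC of recent migration rates)
  is out of scope; directionality is only accessible here through the
  admixture and private-alleles machinery.
* BIC-guided cluster number on discrete genotype data is advisory; read
  the curve, not just its minimum.
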
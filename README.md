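# popgenmon

Temporal population-genetic monitoring of microsatellite data.

## The problem

When a wildlife population recovers demographically from a historical
decline — recolonising its range after a bottleneck and fragmentation — it
is tempting to declare success. Genetics often disagrees: allelic richness
and heterozygosity respond slowly to re-established contact, and strong
spatial structure can persist for decades after the map looks continuous.
The canonical example is the Eurasian otter (*Lutra lutra*) in Great
Britain, monitored over 21 years at 15 microsatellite loci across five
regional subpopulations and five sampling time points.

`popgenmon` implements the full analysis chain such a monitoring programme
needs, for anyone with diploid multilocus genotypes plus per-individual
metadata (year, region, planar coordinates, sex, age class):

* **Data handling** — validated genotype tables from CSV, Genepop
  import/export, pooling of sampling years into time points, spatial–
  temporal groupings (STG = region × time point), 20-km grid subsampling
  against spatial pseudoreplication.
* **Diversity** — observed and Nei's unbiased expected heterozygosity
  (`He = 2n/(2n−1)·(1−Σp²)`), mean alleles per locus, rarefied allelic
  richness `A_r(g) = Σ_a [1 − C(G−c_a, g)/C(G, g)]` and Kalinowski's
  rarefied private allelic richness, closed-form null-allele estimators,
  paired *t*, Kendall tau-b and Kruskal–Wallis trend tests.
* **Differentiation** — Weir–Cockerham (1984) θ with permutation tests,
  AMOVA (allele-identity distance) with global Φ_ST, Hardy–Weinberg exact
  tests (Levene enumeration for two alleles, a Markov chain otherwise),
  Burrows-composite linkage-disequilibrium tests, and the two-stage F_IS
  procedure that distinguishes Wahlund effects (`w`) from inbreeding
  (`i`) by recomputing F_IS on the dominant genetic cluster only.
* **Clustering** — a STRUCTURE-type admixture Gibbs sampler (correlated or
  independent frequency prior) written in C++, replicate-run alignment with
  major/minor modes, Evanno ΔK, admixed-individual classification at
  Q < 0.8, progressive K = 2 partitioning, and a BIC-guided discriminant
  (DAPC-style) cross-check.
* **Gene flow** — the Barton–Slatkin private-alleles estimator of the
  effective number of migrants, sample-size corrected by interpolating the
  published regression `ln p(1) = a·ln(Nm) + b`, globally and pairwise per
  time point.
* **Spatial** — least-cost distances over a binary land/sea raster
  (8-connected Dijkstra), shared-allele genetic distances, Mantel tests and
  Holm-corrected Mantel correlograms with sex-stratified variants.
* **Simulation** — a forward Wright–Fisher simulator of bottlenecked,
  re-connecting demes (stepwise or K-allele mutation, epoch-wise migration,
  translocations, optional selfing) with a complete truth ledger, so every
  estimator above is verifiable against known reality.

## Worked example

```r
library(popgenmon)

# a synthetic recovering population: 5 demes, bottleneck, rising migration,
# ~400 sampled individuals at 15 loci over 5 time points
sim <- scenario_recovery_lag(seed = 42, record_truth = FALSE)
gt  <- sim$table
gr  <- assign_stgs(gt)

# gene flow over time from private alleles
nm_series(gt, gr, omit = "1994")$global
#> # A tibble: 4 × 6
#>   time_point     p1 mean_n    nm n_private n_regions
#>   <chr>       <dbl>  <dbl> <dbl>     <int>     <int>
#> 1 1999       0.214    40.8 0.183        34         5
#> 2 2004       0.171    29.6 0.269        37         5
#> 3 2009       0.117    36   0.503        21         5
#> 4 2014       0.0711   32   1.19         15         5
```

The mean frequency of private alleles (`p1`) falls as migration rises, so
the inferred effective number of migrants (`nm`) climbs from ~0.2 to ~1.2
across the four usable time points — gene flow is recovering. Meanwhile
differentiation barely moves:

```r
gr14 <- dplyr::filter(gr, time_point == "2014")
wc_theta(gt, gr14[gr14$region %in% c("Severn", "Eastern"), ], by = "region")$theta
#> [1] 0.1258342
```

A multilocus θ of ~0.13 between two regions in the final year is the
"recovery lag": connectivity first, genetic homogenisation much later. The
full report (`run_report()`) assembles the per-STG diversity table,
pairwise θ per time point with a global AMOVA row, the Nm series, the
admixture K scan with Evanno ΔK, admixed percentages over time and the
temporal/regional trend tests, as tibbles and TSVs.

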
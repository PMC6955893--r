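# sandassembly

Community-assembly inference for coastal sand (and other habitat-
structured) microbiota from amplicon count tables.

Beach sands host microbial communities whose composition differs sharply
between the intertidal and supratidal zones.  Whether that structure
reflects **environmental filtering** (deterministic selection along the
salinity/conductivity gradient) or **neutral processes** (random
dispersal and ecological drift) is the central question this package
addresses, for microbial ecologists working with a samples × taxa ASV
table, sample metadata and (optionally) a taxonomy.

## What it computes

* **Levins' niche breadth** `B_j = 1 / Σ_i q_ij²` per taxon, classified
  against a fixed-fixed (`quasiswap_count`) permutation null into
  habitat *generalists*, *specialists* and non-significant taxa
  (1000 permutations, two-sided α = 0.05).
* **IndVal** indicator analysis: specificity × fidelity, max-group
  permutation test (exact enumeration on small two-group designs),
  strict selection gates IndVal > 0.75, p < 0.01.
* **Abundance-based β-null deviation**: observed Bray–Curtis minus its
  expectation over randomised assemblies that preserve each sample's
  richness and total abundance; positive values indicate structure
  beyond random assembly.
* **Sloan neutral community model**: occurrence frequency predicted by
  `1 − I_d(Nmp, Nm(1−p))`, single-parameter least-squares fit of the
  migration rate m, R², and a partition of taxa into over-represented /
  neutral / under-represented via 95% Wilson bands — plus the
  cross-partition of those labels by niche class.
* **Distance-based multivariate statistics**: PERMANOVA (sequential
  Type-I, with exact enumeration on toy designs), ANOSIM, VIF screening
  (threshold 5), PCNM spatial eigenvectors, forward selection
  (double stopping rule) and partial db-RDA variation partitioning
  (pure environmental / pure spatial / shared / residual adjusted R²).
* A **synthetic metacommunity generator** (lognormal/logseries SADs;
  neutral Moran death–replacement dynamics, Gaussian niche filtering,
  or both) that emits count tables with known ground truth, so every
  estimator above is benchmarked against simulations where the answer
  is known.
* `run_full_analysis()`: the whole graph in one call, with TSV
  intermediates, a schema-validated JSON report, and byte-identical
  reruns under the same configuration.

## Worked example

Simulate a survey with the study-mimic geometry (4 sites × 2 zones × 3
replicates) under filtering *plus* drift, then ask the package whether
it can tell:

```r
library(sandassembly)

meta <- make_metacommunity(200, sad_params = list(meanlog = 0, sdlog = 1),
                           seed = 101)
meta <- add_niche_traits(meta, n_specialist = 20, n_generalist = 20,
                         sigma_background = 1, seed = 102)
design <- simulation_design(N_T = 1000, depth = 1000, regime = "mixed",
                            m = 0.1, seed = 103)
sim <- simulate_mixed_community(meta, design)
sim$table
#> community_table: 24 samples x 198 taxa, total count 24,000
#> sample depths: 1000 - 1000

cls <- classify_generalists_specialists(sim$table, n_perm = 1000, seed = 1)
table(cls$label)
#>      generalist non_significant      specialist
#>               6             141              51

fit <- fit_neutral_model(sim$table)
fit
#> Sloan neutral model fit: m = 0.0793, N = 1000, R2 = 0.776
#> neutral    over   under
#>     174      13      11

bn <- beta_null_deviation(sim$table, groups = sim$metadata$environment,
                          n_null = 200, seed = 2)
bn
#> beta-null deviation over 276 pairs (200 null assemblies)
#>       group mean_deviation sd_deviation n_pairs
#>  intertidal      0.1536305   0.03393189      66
#>  supratidal      0.1549439   0.04272140      66

permanova(bray_curtis(sim$table), sim$metadata, ~ environment * site,
          n_perm = 999, seed = 3)
#>               term Df  SumOfSqs        R2        F     p
#> 1      environment  1 0.6703957 0.1467635 4.183068 0.001
#> 2             site  3 0.6536547 0.1430985 1.359536 0.021
#> 3 environment:site  3 0.6795878 0.1487758 1.413475 0.013
#> 4         Residual 16 2.5642260 0.5613621       NA    NA
#> 5            Total 23 4.5678642 1.0000000       NA    NA
```

Reading the numbers: the fitted migration rate (m̂ = 0.079) recovers the
generating value (m = 0.1); R² = 0.776 says drift-plus-dispersal
explains most of the occupancy–abundance relationship, while the
strongly positive β-null deviations (≈ +0.15) and the significant
environment term (R² = 0.147, p = 0.001) expose the filtering layered on
top.  Designed narrow-tolerance taxa surface in the specialist class,
and the ground-truth labels in `sim$truth` let you score any of it.

The one-command pipeline on the full-scale preset (2000 taxa, 19,000
reads/sample):

```r
run_full_analysis(run_config(outdir = "run1", seed = 42))
```

writes `run1/report.json` (niche classification counts, per-zone NCM
fits, stratified β-null deviations, Table-style PERMANOVA/ANOSIM and
variation-partitioning blocks, cross-partition ratios) plus every
intermediate TSV.  A thin CLI wrapper lives at
`inst/scripts/sandassembly.R` (`simulate` and `run` subcommands).

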
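---
title: "Inferring community assembly in coastal sand microbiota: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly in coastal sand microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sandassembly)
```

## The scientific question

Beach sands host diverse microbial communities whose composition differs
sharply between the intertidal zone (periodically inundated, saline) and
the supratidal zone (dry, fresher).  Two families of ecological processes
can produce such patterns: **environmental filtering** (deterministic
selection of taxa whose niches match local conditions, here dominated by
the salinity/conductivity gradient) and **neutral processes** (random
dispersal and ecological drift, identical demographic rates for all
taxa).  `sandassembly` packages the complementary statistical machinery
used to weigh these processes against each other from a single
samples-by-taxa amplicon count table:

* **Levins' niche breadth** with a fixed-fixed permutation null, to
  split taxa into habitat generalists, habitat specialists, and taxa
  indistinguishable from the null;
* **indicator value (IndVal) analysis** for taxa statistically
  associated with one zone;
* the **abundance-based beta-diversity null model**, whose deviation
  measures compositional structure beyond what richness and abundance
  alone explain;
* the **Sloan neutral community model (NCM)**, fit to the
  occurrence-frequency/abundance relationship, with a partition of taxa
  into over-represented, neutrally distributed and under-represented;
* **distance-based multivariate statistics**: PERMANOVA, ANOSIM, VIF
  screening, PCNM spatial eigenvectors, forward selection and partial
  db-RDA variation partitioning.

A synthetic metacommunity generator with *known* assembly regime closes
the loop: every inferential claim the package makes is tested against
simulations where the truth is known.

## Models

### Levins' niche breadth

For taxon $j$ with counts $c_{ij}$ across samples $i$, let
$q_{ij} = c_{ij} / \sum_i c_{ij}$.  The breadth is

$$B_j = \frac{1}{\sum_i q_{ij}^2},$$

the inverse Simpson concentration of the taxon's distribution over
samples: $B = 1$ for a taxon confined to one sample, $B = n$ for a
perfectly even one.  Because $B$ confounds true habitat breadth with
abundance and occupancy, each taxon is compared against its own null
distribution over `quasiswap_count` randomisations (vegan), which
preserve **every sample total and every taxon total exactly**.  A taxon
is a generalist if $B$ exceeds the $1-\alpha/2$ null quantile,
a specialist if it falls below the $\alpha/2$ quantile.  Defaults:
1000 permutations and two-sided $\alpha = 0.05$ (the permutation count
follows the standard protocol; the protocol does not fix $\alpha$, and
0.05 with quantile ties resolved conservatively to non-significant is
this package's choice).  Breadth is computed on the rarefied table so
that the fixed sample margins are not confounded with sequencing depth.

### IndVal

For taxon $j$ and group $k$: specificity
$A_{jk} = \bar{c}_{jk} / \sum_{k'} \bar{c}_{jk'}$ (share of the taxon's
mean abundance), fidelity $B^{fid}_{jk}$ = fraction of group-$k$ samples
occupied, and $\mathrm{IndVal}_{jk} = A_{jk} B^{fid}_{jk}$, reported on
the $[0,1]$ scale for the maximizing group.  Significance uses the
max-group statistic under free permutation of sample labels, with the
$(1+\#\{null \ge obs\})/(1+n_{perm})$ estimator; for two-group designs
with few samples the package enumerates all distinct label assignments
exactly.  Good indicators use the strict gates IndVal $> 0.75$ and
$p < 0.01$.  The replicated-site structure would justify restricted
permutation; free permutation is the default because it is what the
field's standard implementation does, and a design-respecting
permutation scheme is the main known caveat to the reported p-values.

### Abundance-based beta-null deviation

Each null assembly rebuilds every sample with its observed richness and
total abundance: occurring taxa are drawn without replacement with
probability proportional to regional occurrence frequency (one
guaranteed read each), and the remaining reads are assigned
multinomially in proportion to regional relative abundance among the
chosen taxa.  The deviation of a sample pair is observed Bray-Curtis
minus the mean Bray-Curtis over (by default) 1000 null assemblies.
Group summaries are the mean and sd over within-group pairs, compared
between groups by a Kruskal-Wallis test.

Two properties of this statistic that the simulations make explicit:

1. **It is self-consistent**: a table built by the null-assembly
   algorithm itself deviates by zero *when evaluated against the
   generating pool* (the `reference` argument).  Re-estimating the pool
   from a single null realisation flattens the occurrence weights and
   biases the deviation slightly negative, which is why `reference`
   exists.
2. **Drift inflates it.**  Pure neutral drift with weak immigration
   produces strongly positive deviations (at the benchmark scale,
   roughly $+0.15$ at $m = 0.1$, $+0.06$ at $m = 0.3$, $+0.03$ at
   $m = 0.5$, $\approx 0$ at $m = 1$): the null preserves richness and
   abundance but not the excess between-sample variance that drift
   creates.  A positive deviation is therefore evidence of *filtering*
   only relative to a dispersal-dominated baseline; this is exactly the
   contrast the package's regime-discrimination benchmark draws
   (neutral arm at $m = 0.5$ versus a strongly filtered arm), and it
   mirrors how the statistic is used in the field: comparing strata or
   habitats against each other rather than reading single values in
   isolation.

### Sloan neutral community model

Local relative abundance of a taxon with metacommunity mean relative
abundance $p$ is approximated by
$\mathrm{Beta}(N m p,\; N m (1-p))$, where $N$ is the local community
size and $m$ the immigration probability per death.  The predicted
occurrence frequency above a detection limit $d$ is

$$\hat f(p) = 1 - I_d\!\left(Nmp,\; Nm(1-p)\right),$$

with $I$ the regularised incomplete beta function.  The single free
parameter $m$ is fit by bounded one-dimensional least squares of
observed occurrence frequencies on $\hat f$;
$R^2 = 1 - SS_{res}/SS_{tot}$ about the mean observed frequency (it may
be negative for badly non-neutral data, which is informative in
itself).  The data do not identify $N$ separately: the package uses the
rarefaction depth for $N$ and $d = 1/N$ (one read), a prominent and
standard convention.  Taxa are partitioned by a 95% **Wilson score
interval** around $\hat f$ with the number of samples as trials
(over / neutral / under); the interval choice is the package's (the
Wilson interval is exact at the $\hat f \in \{0, 1\}$ boundaries and
better behaved than the Wald interval at small $n$).  The least-squares
fit is unweighted, standard practice for this model; a weighted variant
can be layered on by the user via `sloan_predicted_frequency()`.

### Distance-based multivariate statistics

PERMANOVA uses sequential (Type-I) partitioning of the Gower-centred
Bray-Curtis matrix via projection matrices, with terms in the order
written in the formula (environment before site, then the interaction)
and free permutation of sample identities; for 6-sample toy designs all
permutations are enumerated and the p-value is the exact fraction of
permutations at least as extreme (which for one factor equals
enumeration over the distinct label assignments).  ANOSIM is the
classical rank contrast.  Both are implemented in the package and
cross-checked against vegan (`adonis2`, `anosim`) in the test suite.
VIF screening iteratively removes the variable with the largest
variance inflation factor until all are at or below 5.  PCNM, db-RDA,
variation partitioning (with Ezekiel-adjusted $R^2$; the shared
fraction may legitimately be negative and has no significance test) and
`ordiR2step` forward selection (double stopping rule: inclusion p-value
and global adjusted-$R^2$ scope) delegate to vegan behind the package's
interfaces.  Negative PCoA eigenvalues of the Bray-Curtis matrix are
handled by square-root transformation of the dissimilarities, applied
automatically only when negative eigenvalues are present and recorded
in the result; this correction is monotone and simpler than the
Lingoes/Cailliez additive constants.

## The synthetic generator

### What it emulates

The study-mimic layout is 4 sites $\times$ 2 shore zones $\times$ 3
replicates = 24 samples, sites on a shore-parallel transect (2.2 km
spacing, total extent > 6.5 km), zones offset perpendicular to shore,
and ~19,000 reads per sample.  Zones sit at $\pm 1$ on a standardised
environmental axis playing the role of the conductivity gradient.  The
metacommunity is a lognormal species-abundance distribution of 2000
taxa (`sdlog = 2`), giving top-1/top-10 dominance shares of roughly
7%/26%, in line with 16S surveys.

Three regimes provide ground truth:

* **neutral** — every local community starts as a multinomial draw of
  $N_T$ individuals from the metacommunity and evolves by a **Moran
  death/replacement process**: per step one random individual dies and
  is replaced from the metacommunity with probability $m$, otherwise by
  a local offspring.  This is the discrete process whose stationary
  occupancy Sloan's beta approximation describes, so parameter-recovery
  benchmarks are generative, not circular in implementation (fit and
  simulator share no code).
* **niche** — expected local abundance
  $\propto p_j \exp(-(e - \mu_j)^2 / 2\sigma_j^2)$ with zone (plus
  site-jitter) environmental value $e$; reads multinomial.  Designed
  specialists have $\sigma = 0.2$ centred on a zone; designed
  generalists $\sigma = 5$; background taxa either unstructured
  ($\sigma = \infty$, the default — "background" means *no* niche
  differentiation) or mildly structured where a visibly zonated whole
  community is wanted.  Ground-truth labels are emitted with the table.
* **mixed** — the zone-filtered pool of the niche regime used as the
  immigrant source of the Moran process: filtering plus drift, the
  regime closest to the real beach.

### Calibrated parameters, with their anchors

* **Site-level environmental jitter** `env_noise_sd = 0.5` standardised
  units, shared by replicates of a site-zone.  Anchor: the surveyed
  conductivity dispersion (within-zone sd ~465 µS/cm against a
  between-zone separation of ~1900 µS/cm, i.e. one quarter of the
  separation, which is 0.5 on an axis with zones at $\pm 1$), and the
  observation that site effects on community composition are nearly as
  large as zone effects.  Replicates within a site-zone share their
  jitter, like replicate cores from one site.
* **Burn-in** `max(10, ceiling(5/m)) * N_T` Moran steps.  The variance
  relaxation time of the chain is about $N_T/(2m)$ steps, so a flat
  multiple of $N_T$ is not stationary for small $m$; with the scaled
  burn-in, fitted $\hat m$ recovers the true value within ~6% at
  $m = 0.02$, where a flat $10 N_T$ burn-in overestimates it two-fold.
* **Benchmark scale-down.**  Tests and the acceptance script run at 24
  samples, $S = 200$ taxa, depth and $N_T$ 1000 — sizes chosen so the
  full suite completes in minutes.  When shrinking the pool from 2000
  to 200 taxa the SAD parameter drops from `sdlog = 2` to `sdlog = 1`
  so that the *dominance profile* (top-1 ~5%, top-10 ~26%) matches the
  full-scale pool; holding `sdlog` instead would concentrate a third of
  the pool in one taxon and make every dissimilarity statistic hostage
  to a single taxon's presence.
* **Regime-discrimination benchmark**: neutral arm at $m = 0.5$
  (dispersal-dominated — the ecological null the deviation statistic is
  calibrated against, see above), filtered arm with
  `sigma_background = 0.5` so the median taxon is strongly
  zone-differentiated; "near zero" band for the neutral deviation
  $\varepsilon = 0.1$.
* **Physico-chemical covariates** in the simulated metadata (EC, AP,
  TN, pH, Zn) at survey-like magnitudes; EC and AP track the gradient,
  the rest are noise, so the VIF/forward-selection/variation-
  partitioning stages run against a realistic mix of informative,
  collinear and irrelevant predictors.

### What it does not emulate

Sequencing error and chimeras (tables are clean multinomial samples);
overdispersion beyond multinomial sampling (no Dirichlet-multinomial
layer by default); spatially explicit dispersal kernels (immigration is
from the common pool regardless of distance); phylogenetic signal in
niches; temporal dynamics.  Passing the simulation benchmarks therefore
shows the estimators are correct *for the processes modelled*, not that
real sand communities satisfy those models.

## Numerical choices and degenerate inputs

* Rarefaction is a single hypergeometric draw per sample (the protocol
  does not state draw-averaging; a single draw preserves integer counts
  and the variance structure every downstream null expects), with
  per-sample substreams derived from the master seed so results are
  independent of sample order and subsetting.
* Permutation p-values are always $(1+\#\{null \ge obs\})/(1+n_{perm})$
  with a $10^{-12}$ tie tolerance, never 0; exact enumerations include
  the identity assignment.
* The quasiswap null asserts both margins of every permuted table; a
  table smaller than 2x2 non-zero cells is rejected.
* The NCM optimizer searches $m \in [10^{-6}, 1]$ and flags solutions
  at the bounds; a table where every taxon is ubiquitous is a
  degenerate fit and an error.
* Beta-null deviations on taxon strata of a rarefied table have
  unequal sample totals by construction; the function warns rather
  than refuses.
* Perfect collinearity in VIF screening yields infinite VIF; ties on
  the largest VIF are dropped in variable-name order,
  deterministically.
* Fully aliased predictor sets in variation partitioning (env
  identical to spat) make the pure fractions untestable; their
  p-values are `NA` while the adjusted-$R^2$ identity
  pure + pure + shared = total still holds to $10^{-9}$.

## The pipeline

`run_full_analysis()` executes the full graph — rarefy, classify,
IndVal, PERMANOVA/ANOSIM for the whole community and both strata, VIF,
PCNM, forward selection, variation partitioning per stratum, beta-null
deviations per stratum and zone, NCM per zone, and the cross-partition
of the neutral labels by niche class — writing every intermediate TSV,
a JSON report validated against a shipped schema, and a log.  Strata
reuse the single rarefied table (no re-rarefying), and per-zone NCM
fits recompute mean abundance and occurrence within the zone.  All
stage seeds derive deterministically from one master seed, and the
report contains no timestamps, so identical configurations produce
byte-identical reports.  The full-scale study-mimic run (24 samples,
2000 taxa, depth 19,000, 1000 permutations/null assemblies, 9999
variation-partitioning permutations) completes in about a minute.

## Known limitations

The niche classification inherits the conservativeness of fixed-fixed
nulls for rare taxa; IndVal p-values are not multiplicity-corrected
(the strict 0.01 gate is the protocol's only guard); the beta-null
deviation conflates drift with filtering unless anchored to a
dispersal-dominated baseline (see above); NCM's $N$ is a convention,
so $\hat m$ is interpretable relatively (between habitats) rather than
absolutely; and free permutation ignores the nested replicate
structure, for which restricted permutation options are exposed.
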
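---
title: "Methods: clonal richness, cyclone exposure, and driver selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal richness, cyclone exposure, and driver selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalscape)
```

clonalscape implements the analysis chain used to ask what structures the
clonal richness of tropical seagrass meadows: clone identification from
multilocus genotypes, marker-power assessment, a Poisson metric of
cyclone-wave disturbance, and full-subset additive-model selection of
environmental drivers. This vignette is the package's account of the
statistical methods, the choices behind them, and what the bundled
synthetic-data generators do and do not emulate.

## Clones, marker power, and clonal richness

Seagrasses spread vegetatively: one genetic individual (a genet, recruited
from a single seed) can produce many shoots (ramets). Field sampling
collects ~50 ramet samples inside a 50-m-diameter plot, each at least 2 m
from the next, and genotypes them at L loci (here, 7-16 microsatellites or
80 biallelic SNPs). Samples sharing a full multilocus genotype (MLG) are
treated as one clone.

**Clone identification.** `identify_mlgs()` partitions samples by exact
equality of their order-normalized allele pairs. The default `strict`
policy requires missing calls to match only missing calls, which makes the
relation an equivalence and the partition unambiguous. Because field
datasets rarely document how missing calls were handled in clone calling,
a `missing_wildcard` alternative is provided: samples are linked when all
mutually non-missing loci agree, and clones are connected components of
that link graph. A sample with many missing calls can then bridge two
distinct genotypes, so wildcard G is never larger than strict G; the
policy used is recorded in the output.

**Marker power.** Under Hardy-Weinberg equilibrium, the probability that
two random individuals share a genotype at one locus with allele
frequencies $p_i$ is

$$P_{ID} = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2,$$

and across independent loci the values multiply.
`probability_of_identity()` accumulates this over increasing locus
combinations, by default ordering loci from most to least discriminating
(ascending per-locus $P_{ID}$, ties broken by locus id) — the conventional
marker-power curve. No small-sample or sibling correction is applied: the
basic HWE form is the statistic of record here, and the corrections would
change the numbers without changing any decision the pipeline makes.

**Expected duplicates.** With $N$ samples there are $\binom{N}{2}$ pairs,
so the expected number of duplicate genotype pairs arising by chance (not
clonality) is $\binom{N}{2} P_{ID}$. The "expected number of individuals
with the same genotype" is sometimes computed as $N \cdot P_{ID}$ instead;
the pairwise form is the direct consequence of $P_{ID}$'s definition as a
two-individual probability, and is the default via
`expected_duplicates()`.

**Clonal richness.** `clonal_richness()` reports
$R = (G-1)/(N-1)$: 0 for a monoclonal stand, 1 when every sample is a
distinct genet. It needs $N \ge 2$ and refuses otherwise. Richness (rather
than evenness or heterogeneity) is the only clonality statistic computed,
because it is the one the driver analysis consumes.

## Cyclone exposure

Cyclonic seas rework sediment and can remove genets; the disturbance
metric is the annual probability that a site experiences significant wave
height $H_s \ge 4$ m for at least one hour.

* `blend_winds()` combines vortex and synoptic winds: full cyclone weight
  within 3 radii of the eye, declining linearly to zero at 6 radii
  (configurable). The published description of this blending is
  qualitative; the piecewise-linear ramp is adopted because it is
  continuous, bounded by its inputs, and trivially testable.
* `exposure_events()` defines an exposure event as a maximal contiguous
  run of hours with $H_s \ge 4$ m lasting at least `min_duration` (default
  1 h), counted in the year of its first hour — so a 3-day storm is one
  exposure, not 72. Both thresholds are arguments, since the episode
  definition is a modelling choice rather than a measurement. Gaps in the
  hourly series are treated as below threshold and reported.
* When waves are not observed, a monotone wind-to-wave map converts
  blended wind to $H_s$; the default, $H_s = 4\,(w/17.2)^2$ m, is
  calibrated so the 4 m criterion coincides with gale-force wind. No fetch
  or bathymetry adjustment is attempted.
* `annual_exposure_probability()` sets $\lambda$ = mean events/year and
  $\Pr(X \ge 1) = 1 - e^{-\lambda}$, the Poisson probability of at least
  one exposure in a year.

## Driver selection

Site-level richness is modelled as a Gaussian response to at most two
environmental predictors via additive models (penalized thin-plate
regression splines, `mgcv`), fitted by maximum likelihood so
log-likelihoods are comparable across specifications.

The full-subset protocol, in order:

1. **Transforms** (applied once, recorded): square root for cyclone
   exposure probability, turbidity (KD490) and distance from shore; log
   for SST. The cyclone transform follows the naming convention of the
   reference results (`cyclone.sqrt`) even though it is the one transform
   the source description leaves implicit.
2. **Collinearity prefilter** (`prefilter_predictors()`): walking a
   priority list, drop any predictor whose |Pearson r| with an
   already-retained one exceeds 0.8 (point-biserial for the binary dugong
   factor, transformed scale for continuous ones). In practice this
   removes latitude (which tracks SST at r > 0.95) and, for some species,
   distance from shore (which tracks cyclone probability).
3. **Candidate set** (`build_candidate_models()`): the null model, all
   singles, all pairs with pairwise |r| <= 0.28, and — for admissible
   factor/continuous pairs — a factor-plus-smooth-by-factor specification
   (e.g. `dugong+SST.log.by.dugong`: one SST smooth per dugong level).
   The 0.28 rule is read as absolute correlation.
4. **Fitting** (`fit_additive_model()`): basis dimension 4 per smooth —
   with 14-16 sites, larger bases are not estimable — and a hard refusal
   (never a silent shrink) when n < k + 2 for the spec's worst-case
   parameter count. `k` for AICc is the model's effective degrees of
   freedom including the scale parameter, as returned by the fitting
   engine; r² is the fraction of response variance explained.
5. **Ranking** (`rank_models()`):
   $AICc = -2\log L + 2k + \frac{2k(k+1)}{n-k-1}$, $\Delta_i$ relative to
   the best model, Akaike weights $w_i = e^{-\Delta_i/2}/\sum_j
   e^{-\Delta_j/2}$. The candidate set is $\Delta \le 2$; the selected
   parsimonious model has the fewest predictors in that set, ties broken
   by lower AICc, then label — fully deterministic.
6. **Importance** (`variable_importance()`): sum of $w_i$ over models
   containing each predictor; a smooth-by-factor term counts for both
   participants.

**Random effects.** The fits are fixed-effects additive models. With
14-16 sites nested in 9 locations, a location random intercept is at the
edge of estimability and its inclusion does not change the selection
arithmetic (the reproducible part of the analysis); the fixed-effects fit
is therefore the default.

**What is and is not reproducible.** The spline basis and smoothing-
parameter conventions of any particular historical fit are unknowable, so
absolute AICc values from other software are not bit-reproducible. What is
exactly reproducible — and what the package treats as the checkable core —
is the selection arithmetic: delta-AICc differences, weight normalization,
candidate membership, parsimony, and the weight-sum importance table. The
bundled `seagrass_model_table()` provides a published two-species model
table on which this arithmetic reproduces every printed importance entry
whose weight sum is exact.

## Comparative statistics

`species_comparison()` reports both a Kruskal-Wallis rank test
(tie-corrected) and a Mood's median test (2 × k counts above/not-above the
grand median, chi-squared without continuity correction): published
comparisons of this kind often say only that "the medians and the
distributions differed", and reporting both covers either reading. Fully
tied data return H = 0 and p = 1 rather than an error.
`latitude_correlation()` and `cooccurrence_correlation()` are Pearson
correlations with two-sided t-based p-values; latitude enters as its
absolute value by default (distance from the equator), appropriate for a
single-hemisphere study area, with a flag for signed latitude.

## Synthetic data: what it emulates, what it does not

The generators reproduce the statistical structure the analysis assumes,
with the truth recorded alongside every draw:

* `simulate_clonal_population()` — genets placed uniformly in a
  50-m-diameter plot; ~50 sample points at >= 2 m spacing, each assigned
  to the nearest genet within a 15 m ramet radius (unoccupied points are
  redrawn; impossible packings error out). One HWE genotype per genet,
  locus frequencies Dirichlet-drawn with allele counts defaulting to a
  7-locus microsatellite panel (2-12 alleles); genotyping error is a
  single per-call missing-rate knob. Not emulated: linkage, somatic
  mutation within genets, allelic dropout, spatially realistic clonal
  growth. Passing recovery tests therefore show the estimator chain is
  correct under its own assumptions, not that real genotyping noise is
  harmless.
* `simulate_storm_history()` — Poisson storm arrivals (default 2/year
  over a 1985-2015-style horizon), straight-line tracks at 20 km/h past
  the sites, hourly winds from a radially decaying vortex (linear rise to
  `vmax` at the radius of maximum winds, power-law decay beyond), Weibull
  synoptic winds. The vortex is deliberately simple — it is not an
  operational cyclone wind model — and only its interface (hourly winds
  at a site) matters to the pipeline. Quiet hours are not emitted; the
  event detector treats them as below threshold.
* `simulate_driver_dataset()` — 16 sites over an 8° latitude span; SST
  constructed to track latitude (r >= 0.95) so the prefilter is always
  exercised; response hump-shaped in sqrt(cyclone probability) (a
  quadratic with an interior maximum — the simplest shape with "highest
  richness at intermediate disturbance"), plus optional additive dugong
  and SST effects, Gaussian noise (default SD 0.05), clipped to [0, 1].

Default problem sizes used by the test suite and the acceptance script —
500 seeded populations for richness recovery, $10^4$ years for the Poisson
exposure check, 200 replicates per driver scenario — were chosen as the
smallest sizes at which the Monte-Carlo error bands in those checks are
meaningfully tighter than the effects being verified.

## Numerical notes and limitations

* Allele labels are opaque text; fragment sizes are never parsed as
  numbers, so microsatellite and SNP panels behave identically.
* Ploidy is fixed at diploid; haploid or polyploid tables are rejected
  rather than reinterpreted.
* A locus with no non-missing genotypes is dropped from the frequency
  table (with a warning), never carried as an empty entry.
* Per-locus allele frequencies are validated to sum to 1 within 1e-9
  before any P_ID computation.
* The hump-recovery simulation top-ranks the cyclone-only model in
  roughly three-quarters of replicates at noise SD 0.05 and n = 16; the
  remainder mostly select a cyclone-plus-noise-predictor pair, which is
  the expected cost of penalized smooths at this sample size. Importance
  identifies cyclone as the leading predictor in essentially all
  replicates.
* With 16 sites, chance correlations between independent predictors often
  exceed 0.28, so the admissible pair set varies between synthetic
  replicates. That mirrors the real protocol's behavior at this scale and
  is why the recovery criteria are majority-based rather than exact.
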
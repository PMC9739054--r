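---
title: "Screening germplasm with augmented designs, stress indices and thermal imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening germplasm with augmented designs, stress indices and thermal imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(augscreen)
```

## The screening problem

Breeding programmes screening large germplasm panels for terminal drought
or heat tolerance rarely have seed or space to replicate every entry.  The
augmented randomized complete block design (RCBD) answers this: a handful
of *check* cultivars is replicated in every block while each *test*
genotype is grown once.  The checks do double duty — they estimate the
block effects that contaminate the unreplicated test values, and they
supply the error variance for all inference.  `augscreen` implements this
analysis as a classed model fit, and around it the downstream layers a
stress-screening study needs: genetic-variability parameters, the standard
morpho-physiological stress indices, water-stress indices from canopy
thermal images, and a multivariate ranking of genotypes.

## The augmented-design model

An observation on genotype $i$ in block $j$ is modelled as

$$y_{ij} = \mu + g_i + b_j + \varepsilon_{ij}, \qquad
  \varepsilon_{ij} \sim N(0, \sigma_e^2).$$

With $c$ checks in each of $b$ blocks, the block effect is estimated from
checks only:

$$\hat b_j = \bar y^{(\mathrm{chk})}_{\cdot j} - \bar y^{(\mathrm{chk})},$$

the mean of block $j$'s checks minus the grand check mean, so effects sum
to zero.  A test genotype's adjusted mean is its single observation minus
its block's effect; a check's adjusted mean is its plain mean over the $b$
replicates (adjustment zero, since it meets every block).  One consequence
of the sum-to-zero convention worth knowing: adding a constant to every
plot of one block shifts *all* adjusted means uniformly by $k/b$, leaving
every genotype comparison untouched.

`augmented_rcbd()` returns the whole analysis for one trait:

```{r}
sim <- simulate_fieldbook(seed = 42)
fit <- augmented_rcbd(sim$fieldbook, "GY")
summary(fit)
```

### The ANOVA partition

The total sum of squares over the $N = bc + t$ plots is partitioned into

* **Block (ignoring genotypes)** with $b-1$ df,
* **Genotype (eliminating blocks)** with $c+t-1$ df, split further into a
  **Check** row ($c-1$ df, from the raw check means, which are balanced
  over blocks) and a combined **Test and Test vs. Check** row ($t$ df,
  obtained by subtraction),
* a **Residual** from the check-only two-way layout,
  $\sum_{ij}(y_{ij} - \bar y_{i\cdot} - \bar y_{\cdot j} + \bar y)^2$ over
  checks, with $(b-1)(c-1)$ df.

Because the tests are unreplicated they are fitted exactly, so this
residual coincides with the residual of a sequential least-squares fit
`y ~ block + genotype` — the package's test suite verifies the whole
partition against that independent decomposition.  The dual convention
(Genotype ignoring blocks / Block eliminating genotypes) is computed too
and stored in `fit$anova_dual`; the printed table uses the
ignoring-block/eliminating-genotype layout, which is the one screening
reports conventionally show.  The combined test row is not printed split
because the among-test and test-vs-check pieces are rarely reported
separately; both are stored in `fit$test_split`.

All $F$ ratios test against the check residual.  Standard errors for the
four comparison classes come with the fit
(`comparison_errors()`): check vs check $\sqrt{2\,\mathrm{MSE}/b}$, two
tests in one block $\sqrt{2\,\mathrm{MSE}}$, tests in different blocks
$\sqrt{2\,\mathrm{MSE}(1+1/c)}$ and test vs check
$\sqrt{\mathrm{MSE}(1+1/b+1/c+1/bc)}$, each with its critical difference
at the chosen $\alpha$.

### Missing values

A missing test plot is dropped for that trait with a warning.  A missing
check is an error: the block-effect estimates would silently change
meaning, so the analysis refuses rather than imputes.

## Genetic-variability parameters

For each trait, `variability()` reports variance components, coefficients
of variation, broad-sense heritability and genetic advance.  The
environmental variance is always the residual mean square,
$\mathrm{EV} = \mathrm{MSE}$.  Two estimators of the genotypic variance
are offered:

* `method = "means"` (default): $\mathrm{PV} = \mathrm{Var}$ of the
  adjusted genotype means, $\mathrm{GV} = \mathrm{PV} - \mathrm{EV}$.
  This is the estimator used by the augmented-design screening literature
  this package follows, and the one whose published worked examples the
  acceptance checks reproduce.
* `method = "ms"`: $\mathrm{GV} = \mathrm{MS}_{\mathrm{genotype}} -
  \mathrm{EV}$, the textbook expected-mean-squares route.

Either way a negative $\mathrm{GV}$ — a familiar artifact of unreplicated
designs — is truncated at zero with a diagnostic, and $\mathrm{PV}$ is
re-derived as $\mathrm{GV} + \mathrm{EV}$, so the identity holds to
machine precision in every report.  The `means` estimator carries a small
upward bias of order $\sigma_e^2/c$ from the block-adjustment noise in
test means; at the error-to-genotype variance ratios typical of screening
trials this is well under the sampling noise, and the package's recovery
tests bound it empirically.

Coefficients of variation are $100\sqrt{V}/\bar x$ with
$\bar x$ the mean of all adjusted means (checks included once).
Categories follow the standard breeder's convention: $[0,10)$ low,
$[10,20)$ medium, $\ge 20$ high, applied identically to GCV, PCV and GAM;
boundary values climb to the higher category.  Genetic advance is

$$\mathrm{GA} = k \sqrt{\mathrm{PV}}\; h^2, \qquad
  h^2 = \mathrm{GV}/\mathrm{PV}, \qquad
  \mathrm{GAM} = 100\,\mathrm{GA}/\bar x,$$

with $k = 2.063$, the standardized selection differential at 5%
selection, as the configurable default.

## Morpho-physiological stress indices

The index functions are small, vectorized and validated; all percentages
land in $[0,100]$ for inputs satisfying the natural orderings
(e.g. $FW_0 \ge FW_4 \ge FW_8 > DW$), and violations raise errors or
warnings rather than silent clamping.

* **ELWL** (excised-leaf water loss): water lost over 0–4 h, 4–8 h and
  0–8 h per unit initial water content.  The three intervals obey the
  mass balance
  $ELWL_{0\text{-}8}(FW_0{-}DW) = ELWL_{0\text{-}4}(FW_0{-}DW) +
  ELWL_{4\text{-}8}(FW_4{-}DW)$, which the tests exercise.
* **RWC**: $100(FW-DW)/(TW-DW)$.
* **Fv/Fm**: $(F_m-F_o)/F_m$; readings with $F_m \le F_o$ are returned
  with a warning since they indicate instrument trouble, not arithmetic.
* **RCI**: the relative-injury form
  $100[1 - (1 - T_1/T_2)/(1 - C_1/C_2)]$ of the paired-conductivity
  membrane thermostability assay (the classical Martineau formulation).
* **FLSm**: $100(1 - SPAD_m/SPAD_a)/\text{days}$, percent green-area loss
  per day.  The day span (ten days after anthesis to maturity) is
  genotype-specific and therefore an explicit input, never inferred.
* **Thermal time**: daily GDD is $\max(0, (T_{max}+T_{min})/2 - T_b)$
  with base temperature $T_b = 0\,^\circ$C by default (the wheat
  convention; configurable).  Phyllochron intervals are sowing-anchored
  cumulative GDD at each leaf-tip emergence.
* **Early vigour**: summed area of the first three leaves divided by the
  thermal time to third-leaf emergence (cm² per °C·day).  Because
  "area with respective phyllochron interval" admits several composites,
  the components are always stored so alternatives can be recomputed.
* **HI and SF**: $100\,GY/AGDM$, and grains per spikelet reported on the
  ×100 scale conventional in screening tables (24 grains over 30
  spikelets prints as 80); `sf_scale = 1` restores the plain ratio.

## Thermal imaging and water-stress indices

A thermal image is a grid of °C values with the ambient temperature
$T_a$ in a JSON sidecar (delimited text or raw float32 payloads; no
proprietary radiometric decoding).  The pipeline is
segment → reference temperatures → indices:

1. **Segmentation** (`segment_canopy()`): either an external mask, or a
   two-means split of the pixel temperatures with the cooler cluster as
   canopy.  The split must be convincingly bimodal: the separation index
   $(m_2-m_1)/(s_1+s_2)$ must reach 2.  A single Gaussian scores about
   1.3 on this index, so unimodal images are rejected rather than
   arbitrarily split; constant images are rejected outright.  A minimum
   canopy size (25 px default) guards against degenerate masks.
2. **Empirical references** (`reference_temperatures()`): frequency
   analysis of the canopy distribution realized as symmetric tail means —
   $T_{wet}$ is the mean of the coolest $\lceil \tau n\rceil$ canopy
   pixels and $T_{dry}$ of the hottest, with tail fraction
   $\tau = 0.05$ by default (configurable; the underlying MATLAB
   tradition does not publish its binning, so the tail mean is the
   documented realization here).
3. **Indices** (`water_stress_summary()`):
   $T_c$ = mean canopy temperature, then
   $$\mathrm{CWSI} = \frac{T_c - T_{wet}}{T_{dry} - T_{wet}}, \qquad
     I_g = \frac{T_{dry} - T_c}{T_c - T_{wet}}, \qquad
     \mathrm{CTD} = T_a - T_c.$$
   Wherever both are defined, $I_g = (1-\mathrm{CWSI})/\mathrm{CWSI}$
   exactly.  CWSI is invariant to adding a constant to every temperature;
   CTD moves one-for-one with $T_a$.  With externally supplied references
   $T_c$ can fall outside $[T_{wet}, T_{dry}]$; values are then flagged,
   never clipped — clipping would silently distort exactly the rows where
   the references are questionable.

When several images share a plant, `water_stress_batch()` averages
per-image *indices*, not temperatures: the two orders of averaging give
different answers and index-first is the defensible one for ratio
indices.

## The multivariate screening layer

`build_trait_matrix()` assembles adjusted means into a genotype × trait
matrix and z-standardizes columns ($n-1$ denominator); missing cells fail
loudly by default (column-mean imputation behind a flag) and constant
columns are an error.

* **PCA** (`trait_pca()`): eigen-decomposition of the correlation
  structure.  Loadings are variable coordinates
  (eigenvector × $\sqrt{\lambda}$), scores have variance $\lambda$, and
  per-genotype squared cosines measure representation quality on the
  retained components.  Signs are fixed deterministically (each loading
  column's largest-magnitude entry positive) so results reproduce across
  linear-algebra backends.  Varimax rotation of the retained loadings is
  available but **off by default**: screening reports sometimes print
  "rotated" component matrices while the cited software defaults to
  unrotated PCA, and the package exposes both rather than resolving that
  ambiguity; rotation preserves the total retained variance, which is
  tested.
* **Correlations** (`trait_correlations()`): Pearson $r$ with two-sided
  p-values from $t = r\sqrt{(n-2)/(1-r^2)}$ and a significance mask at
  $\alpha$.  No multiplicity correction by default (matching screening
  practice); Holm adjustment behind a flag.
* **Clustering** (`trait_clusters()`): Euclidean distances between
  standardized rows, Ward linkage (`ward.D2`) by default — complete and
  average are options since dendrogram reports rarely name their linkage.
* **Ranking** (`rank_genotypes()`): per-trait ranks oriented by each
  trait's registered selection direction (rank 1 most favourable),
  averaged (optionally weighted) into a composite; ties take average
  ranks, making the ranking invariant to positive rescaling of any
  trait.  The top 10 / bottom 5 class cutoffs mirror the convention of
  printing ten best and five worst performers; both are parameters.  The
  rank-sum composite is one defensible realization of "ranking on the
  enlisted traits" — screening reports rarely define theirs — and is
  labelled as such.

## The synthetic-data generator

Every estimator above is tested as estimate-versus-truth on simulated
data, so the generator is first-class code.  Its defaults emulate the
screening trial the package is built around:

* **Field book**: 4 blocks × 5 checks + 41 tests (46 genotypes, 61
  plots), tests dealt round-robin in id order — position within block
  never enters the model, so the randomization of a real trial is not
  simulated.  Observations are additive with Gaussian error.  The default
  scale is grain-yield-like: grand mean 4 g, genotype effect sd 1.25 g,
  plot error sd 0.15 g, block effect sd 0.35 g — chosen to match the
  order of magnitude of yield screening under stress (trait mean near
  4 g, GCV near 30%, high heritability), and fixed once.
* **Thermal image**: 64 × 64 grid, an elliptical canopy covering 40% of
  pixels at 24 °C (sd 0.3 °C), background 5 °C warmer with 0.1 °C
  jitter (fixed small so a temperature-gap segmentation is well posed),
  ambient 25 °C — screening-room conditions.
* **Senescence series**: linear relative SPAD decline at a stated %/day
  so the maturity-rate estimator inverts it exactly without noise.

What the generator does **not** emulate — spatial trend within blocks,
genotype × environment interaction, non-Gaussian or heteroscedastic
error, partially occluded canopies, mixed soil/pot backgrounds — bounds
what green tests mean: they demonstrate correctness of the estimators
under the stated model, not robustness to every field artifact.

## Numerical choices and problem sizes

* GV truncation at zero (logged), categories half-open with boundaries
  going up, average-rank ties, and the deterministic PCA sign convention
  are the package's tie-break rules; all are documented at the function
  level.
* Recovery suites use 200 simulated trials at $n = 46$ for the
  genotypic-variance bias bound, 500 null trials for the uniformity of
  the genotype-row p-value (Kolmogorov–Smirnov at the 1% level), 50
  seeds for segmentation accuracy, and 64 × 64 images — sizes at which
  each suite completes in seconds while leaving the sampling error well
  below the tested tolerances.

## Limitations

* Federer's check-based adjustment only; no REML/mixed-model or spatial
  alternative.
* Broad-sense heritability from a single environment; no
  multi-environment partitioning or BLUPs.
* Thermal work assumes plain matrix exports; radiometric calibration,
  emissivity and co-registration are out of scope.
* The ranking layer implements a rank-sum composite; published screening
  tables built on undocumented criteria will not be reproduced
  genotype-for-genotype.
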
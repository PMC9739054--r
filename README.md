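# augscreen

Screening a germplasm panel for terminal drought or heat tolerance
usually means growing far more genotypes than can be replicated.
`augscreen` is an R package for the full analysis of such trials, built
around the **augmented randomized complete block design**: a few check
cultivars replicated in every block estimate block effects and error
variance, while each unreplicated test genotype is observed once and
adjusted for its block.  It is written for breeders and crop
physiologists running controlled-environment or field screens of wheat
(or any inbred crop) who need to go from a plot-level field book and
canopy thermal images to a defensible ranking of genotypes.

## What it computes

**The augmented-design model.**  For genotype *i* in block *j*,

    y_ij = mu + g_i + b_j + e_ij,    e_ij ~ N(0, sigma_e^2)

with block effects estimated from checks (`b_j` = block-*j* check mean
minus grand check mean), adjusted means (`y - b_j` for tests, replicate
means for checks), the five-source ANOVA — Block (ignoring genotypes),
Genotype (eliminating blocks) split into Check and a combined
Test + Test-vs-Check row, and the check-only Residual with
`(b-1)(c-1)` df — and the four comparison standard errors of the design.
`augmented_rcbd()` returns a classed fit with `print`, `summary`,
`coef`, `fitted`, `residuals`, `predict`, `anova`, `simulate` and `plot`
methods.

**Genetic variability.**  Per trait: variance components
(`PV = GV + EV`, exactly), genotypic/phenotypic/environmental
coefficients of variation with the low/medium/high breeder categories
(bounds 10 and 20%), broad-sense heritability `h2 = GV/PV`, and genetic
advance `GA = k sqrt(PV) h2` with `GAM = 100 GA / mean`, at `k = 2.063`
(5% selection) by default.

**Stress indices.**  Excised-leaf water loss (three intervals), relative
water content, Fv/Fm, relative cell-membrane injury, flag-leaf
senescence rate (%/day), growing-degree-day phyllochron intervals, early
vigour, harvest index and spike fertility.

**Thermal imaging.**  Canopy segmentation by a bimodality-checked
two-means split, empirical wet/dry reference temperatures as 5% tail
means of the canopy distribution, and the water-stress indices
`CWSI = (Tc - Twet)/(Tdry - Twet)`, `Ig = (Tdry - Tc)/(Tc - Twet)`,
`CTD = Ta - Tc`.

**Multivariate screening.**  Standardized genotype-by-trait matrix, PCA
(optionally varimax-rotated) with loadings, scores and squared cosines,
significance-masked Pearson correlations, Ward hierarchical clustering,
and a direction-aware composite rank-sum with top/intermediate/low
classes.

**Simulators with ground truth** (`simulate_fieldbook()`,
`simulate_thermal_image()`, `simulate_senescence_series()`) emulate the
46-genotype study design (5 checks x 4 blocks + 41 tests) so every
estimator is testable as estimate-versus-truth.

## Worked example

```r
library(augscreen)

sim <- simulate_fieldbook(seed = 42)     # 4 blocks, 5 checks, 41 tests
fit <- augmented_rcbd(sim$fieldbook, "GY")
summary(fit)
```

```
Augmented RCBD fit for trait 'GY'
Design: 4 blocks, 5 checks, 41 test genotypes (N = 61)
Grand mean of adjusted means: 3.9124 
Block effects:
     B1      B2      B3      B4 
 0.3357 -0.4470 -0.0402  0.1515 

Analysis of variance:
                        source df   sum_sq mean_sq  f_value p_value stars
    Block (ignoring genotypes)  3   7.2242  2.4081  95.4613       0    **
 Genotype (eliminating blocks) 45 127.9056  2.8423 112.6765       0    **
                         Check  4  24.3048  6.0762 240.8733       0    **
       Test and Test vs. Check 41 103.6008  2.5268 100.1695       0    **
                     Residuals 12   0.3027  0.0252                       

Comparison standard errors (alpha = 0.05):
      comparison        se        cd
  check_vs_check 0.1123070 0.2446960
 test_same_block 0.2246140 0.4893919
 test_diff_block 0.2460523 0.5361020
   test_vs_check 0.1945215 0.4238259
```

The df column (3, 45, 4, 41, 12) is the signature of the 46-genotype
augmented design; every *F* tests against the check residual, and the
comparison table says, e.g., that two tests in different blocks differ
significantly when their adjusted means are more than 0.536 g apart.

```r
variability(sim$fieldbook)
```

```
Genetic variability report (1 trait(s))
 trait mean   PV   GV     EV  GCV gcv_category  PCV pcv_category  ECV    h2
    GY 3.91 2.29 2.27 0.0252 38.5         high 38.7         high 4.06 0.989
   GA GAM gam_category
 3.09  79         high
```

High GCV/PCV with `h2 = 0.99` says the simulated yield variation is
almost entirely genotypic; selecting the best 5% would be expected to
gain `GA = 3.09` g (79% of the trait mean).

```r
st <- simulate_thermal_image(seed = 42)
water_stress_summary(st$image)
```

```
  plant_id      t_c    t_wet    t_dry t_a     cwsi       ig     ctd flag
1      sim 23.99287 23.36984 24.60548  25 0.504217 0.983273 1.00713
```

The canopy sits half-way between its wet and dry references
(`CWSI = 0.50`), and one degree cooler than the air (`CTD = 1.01` —
positive, a transpiring canopy).

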
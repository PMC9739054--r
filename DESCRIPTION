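Package: augscreen
Title: Augmented-Design Screening of Wheat Genotypes for Drought and Heat
    Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screening pipeline for unreplicated (augmented randomized
    complete block) germplasm trials under terminal drought and heat
    stress.  Fits the augmented-design model from replicated check plots
    (block effects, adjusted genotype means, the five-source analysis of
    variance and comparison standard errors), derives genetic-variability
    parameters (variance components, coefficients of variation with
    breeder categories, broad-sense heritability, genetic advance),
    computes standard morpho-physiological stress indices (excised-leaf
    water loss, relative water content, chlorophyll fluorescence,
    membrane injury, flag-leaf senescence rate, phyllochron and early
    vigour, harvest index, spike fertility), extracts crop water-stress
    indices (CWSI, Ig, CTD) from canopy thermal images via empirical
    wet/dry reference temperatures, and ranks genotypes through a
    multivariate layer (PCA with optional varimax rotation,
    significance-masked correlations, hierarchical clustering, composite
    rank-sum).  Includes simulators for augmented field books, senescence
    series and canopy thermal images with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
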
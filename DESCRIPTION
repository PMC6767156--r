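Package: rvatlas
Title: Regional Predictors of Right Ventricular Global Function from
    Surface Motion Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-univariate analysis of right-ventricular (RV) surface
    motion for discovering which region of the RV wall best predicts
    global systolic function. Implements corresponded triangulated
    surface meshes with anatomical landmarks, per-vertex systolic
    excursion and its longitudinal/transverse/circumferential
    decomposition, a synthetic-cohort generator with planted signal
    patches and spatially correlated noise, pointwise
    covariate-adjusted bootstrapped regression with Freedman-Lane
    permutation testing and false-discovery-rate correction,
    contiguous-patch extraction, PCA-based derivation of an optimised
    single-point motion marker in a standard imaging plane, a marker
    validation battery (Pearson correlation, Steiger tests for
    dependent correlations, covariate regression with variance
    partitioning, leave-one-out prediction, Kruskal-Wallis error
    comparison), and test-retest agreement statistics (bias, limits
    of agreement, two-way random absolute-agreement ICC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
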
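# rvatlas

Which point of the right-ventricular (RV) wall best predicts global
systolic function? Clinicians estimate RV ejection fraction (RVEF) from
single-point surrogates on 2D imaging planes — TAPSE (tricuspid annular
plane systolic excursion), septum–freewall displacement (SFD), and their
fractional forms — but the optimal measurement site is an empirical
question. `rvatlas` answers it with a statistical motion atlas: given
corresponded RV surface meshes with end-diastolic and end-systolic
vertex positions for a cohort, it

1. fits, at every vertex $v$, the covariate-adjusted model
   $\mathrm{z}(\mathrm{RVEF}_i) = \beta_v\,\mathrm{z}(e_{iv}) +
   \gamma^\top c_i + \varepsilon_i$ — excursion $e_{iv}$ is the 3D
   distance the vertex travels from end-diastole to end-systole,
   covariates $c_i$ are age, sex, race and body surface area — with
   subject-bootstrap CIs, Freedman–Lane permutation p-values and
   Benjamini–Hochberg FDR across vertices;
2. extracts the largest contiguous significant patch and summarises its
   motion by PCA, retaining the first mode (PC1);
3. derives an **optimised single-point marker (SPM-O)**: the patch
   vertex in the four-chamber imaging plane whose excursion PC1
   reconstructs best;
4. validates SPM-O against TAPSE, TAPSE-F, SFD and SFD-F in an
   independent cohort (Pearson correlation, Steiger tests for dependent
   correlations, variance partitioning, leave-one-out RVEF prediction,
   Kruskal–Wallis error comparison);
5. quantifies test–retest reproducibility (bias, limits of agreement,
   ICC(2,1)).

A synthetic-cohort generator with a planted, RVEF-coupled basal-freewall
patch and spatially correlated motion noise makes every stage testable
without imaging data; see the methods vignette
(`vignettes/rv-motion-atlas.Rmd`) for the generative model and all
numerical choices.

## Worked example

The numbered drivers under `analysis/` run the whole study at desk scale
(300 subjects per cohort, ~1,000 vertices, 9,999 permutations, 1,000
bootstraps; a couple of minutes in total):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_discover.R
Rscript analysis/03_validate.R
Rscript analysis/04_reproducibility.R
```

`02_discover.R` prints, for the default seeds:

```
rv_discovery ( 300 subjects, 991 vertices )
rv_patch: 31 vertices, 4.45 cm^2 (3.4% of surface), 3.9-6.1 cm from apex; 1 component(s)
SPM-O: vertex 677 (four-chamber plane), reconstruction R = 0.93, 42% of base-to-apex distance
  PC1 explains 54.8% of patch excursion variance
Recovered vs planted patch: Jaccard 1.00
Directional composition of patch motion (%):
   longitudinal      transverse circumferential
           35.8            37.2            27.0
```

Reading this: the mass-univariate map found one contiguous basal
free-wall region (3.9–6.1 cm from the apex) where excursion predicts
RVEF after covariate adjustment; it coincides exactly with the planted
signal patch; its motion mixes transverse, longitudinal and
circumferential components; and the optimal plane-coinciding marker
point sits 42% of the way from base to apex on the four-chamber line.
`03_validate.R` then shows the marker comparison in a fresh cohort:

```
Steiger tests vs SPM_O :
       comparison        z            p
   SPM_O vs SFD_F 2.061014 3.930173e-02
 SPM_O vs TAPSE_F 1.203242 2.288827e-01
   SPM_O vs TAPSE 5.401995 6.590366e-08
     SPM_O vs SFD 4.460663 8.170645e-06
```

— SPM-O correlates with RVEF significantly better than the raw
displacement markers (TAPSE, SFD) and is statistically comparable to
the fractional ones, while `04_reproducibility.R` reports near-perfect
test–retest agreement for indexed volumes (ICC 0.995) and high
agreement for pointwise excursion (mean ICC 0.96).

Key functions if you want the pieces individually:
`generate_cohort()`, `fit_pointwise()`, `permutation_pvalues()`,
`fdr_adjust()`, `extract_patch()`, `patch_pca()`,
`reconstruction_correlation()`, `select_spm_o()`, `run_discovery()`,
`run_validation()`, `bias_loa()`, `icc_two_way_random_absolute()`.
Meshes read/write as legacy ASCII VTK or PLY with a YAML landmark
sidecar (`write_vtk()`, `read_vtk()`, …).

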
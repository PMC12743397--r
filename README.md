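# gaitsubpop

Discovering biomechanical subpopulations of hip-osteoarthritis (HOA)
patients from time-normalized gait waveforms, and quantifying how each
subpopulation responds to total hip replacement (THR).

## Who this is for

Movement scientists and clinical biomechanists who have stance-phase gait
waveforms — per subject, several trials of joint-angle (deg) and
joint-moment (N·m/kg) curves time-normalized to 101 points — for a patient
cohort, an optional paired post-surgery cohort, and healthy controls (HC),
and who want an interpretable, reproducible subgrouping and
surgical-response analysis rather than a black-box model. Because such
cohorts are rarely public, the package also ships a first-class synthetic
generator so the entire pipeline is testable without any download.

## What it computes

1. **Preprocessing.** Trial averaging; pointwise z-standardization of every
   cohort by the HC mean and SD; flattening to a subject × variable matrix
   (18 × 101 = 1818 variables on the standard grid).
2. **Shared feature space.** PCA fitted on the HOA cohort, retaining the
   smallest number of components reaching 90% cumulative variance; THR and
   HC are projected through the same center and eigenvector matrix.
3. **Subpopulations.** Ward hierarchical clustering selects the cluster
   count via the relative merge-height gap; k-means (k-means++, five runs)
   assigns subjects, and subjects whose aligned labels disagree across runs
   are excluded; silhouettes describe fit.
4. **Classification.** Per subpopulation, a linear SVM against HC (box
   constraint 1, kernel scale 1) with seeded stratified 10-fold
   cross-validation: classification rate, pathologic ratio
   (100 · n_pathologic / n, the share of the subpopulation on the
   pathological side of the hyperplane), sensitivity, specificity, ROC-AUC.
   Post-surgery subjects are projected through the final model.
5. **Explanation.** Closed-form Shapley values per principal component
   (φᵢ = wᵢ(xᵢ − backgroundᵢ)); |φ|-weighted scores are back-projected
   through the eigenvectors to rank the original waveforms, and the top
   five characterize each subpopulation. The **COGS**
   (classifier-oriented gait score) is the signed orthogonal distance
   (w·x + b)/‖w‖ to the hyperplane, positive toward healthy gait.
6. **Waveform inference.** Pointwise t-trajectories (unpaired subpopulation
   vs HC; paired pre/post) with family-wise error control by max-statistic
   permutation, reporting the significant fraction of the stance phase and
   the significant regions.

## Worked example

```r
library(gaitsubpop)

cfg <- pipeline_config(
  synthetic = cohort_config(n_per_subpop = c(20L, 20L, 20L), n_hc = 25L,
                            n_followup_per_subpop = c(12L, 12L, 12L),
                            recovery_fraction = c(0.8, 0.4, 0.7)),
  n_perm = 500L, seed = 42)
report <- run_pipeline(cfg)
report
#> gait_run_report: 3 subpopulations; 0 excluded; 26 PCs
#>  subpop  era classification_rate n_classified_pathologic n_classified_hc
#>       1  pre               100.0                      20               0
#>       1 post                  NA                       0              12
#>       2  pre                88.9                      16               4
#>       2 post                  NA                       6               6
#>       3  pre                84.4                      15               5
#>       3 post                  NA                       5               7
#>  pathologic_ratio sensitivity specificity roc_auc
#>             100.0   1.0000000        1.00   1.000
#>               0.0   0.0000000        1.00   1.000
#>              80.0   0.8000000        0.96   0.974
#>              50.0   0.5000000        1.00   1.000
#>              75.0   0.7500000        0.92   0.922
#>              41.7   0.4166667        1.00   1.000
```

The generator planted three subpopulations of decreasing standardized
effect size (3, 2, 1.5), and the cross-validated rows recover exactly that
ordering of separability from HC (rates 100 / 88.9 / 84.4, pathologic
ratios 100 / 80 / 75). After surgery the planted recovery fractions
(0.8 / 0.4 / 0.7) show up as pathologic ratios dropping to 0 / 50 / 41.7 —
the strongest normalization where recovery was largest. The `NA`
classification rates are deliberate: post-surgery subjects pass through the
final model, so no cross-validated rate exists for them.

```r
top_k(report$importance[[1]], 5)
#> [1] "hip_rotation_angle"  "knee_flexion_angle"  "hip_flexion_moment"
#> [4] "hip_flexion_angle"   "hip_rotation_moment"
```

These are exactly the five channels the generator's first planted effect
pattern touches: the Shapley back-projection recovers where the
subpopulation deviates from healthy gait.

```r
aggregate(cogs ~ subpop + era, report$cogs, function(x) round(mean(x), 2))
#>   subpop  era   cogs
#> 1      1 post  15.75
#> 2      2 post  -2.05
#> 3      3 post  -0.85
#> 4      1  pre -26.29
#> 5      2  pre -12.85
#> 6      3  pre -11.51
```

COGS is negative before surgery (pathological side of the hyperplane) and
rises toward or past zero afterwards — largest in subpopulation 1, whose
recovery fraction was highest.

`make_figures(report, "figures/")` writes the PC1–PC2 scatter with cluster
hulls, mean ± SD waveform overlays with significant regions shaded, and
pre/post COGS violins. `write_study_csv()` / `read_study_csv()` round-trip
a study through plain CSV, and `inst/scripts/gait_pipeline.R` exposes
`simulate`, `run` and `figures` subcommands for shell use:

```sh
Rscript inst/scripts/gait_pipeline.R run --seed 1 --out-dir out/
```

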
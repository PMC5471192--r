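# cytoprofiler

Image-based phenotyping of human macrophages and monocytes from two-channel
fluorescence micrographs. Monocyte-derived cells are cultured into five
populations — classically activated (M1) macrophages, alternatively
activated (M2) macrophages, unpolarised (naive) macrophages, and monocytes
at day 0 and day 6 — stained with DAPI (nuclei) and fluorescent phalloidin
(f-actin), and imaged. `cytoprofiler` turns those images into per-cell
morphological profiles and phenotype calls:

1. **Segmentation.** Nuclei are detected in the DAPI channel as primary
   objects (global Otsu threshold in the smoothed log domain with a robust
   background floor, hole filling, distance-transform watershed
   declumping, size filtering), then cell bodies are grown from the nucleus
   seeds in the actin channel by propagation, with per-object half-maximum
   boundary refinement so measured sizes do not depend on staining
   brightness.
2. **Cytoprofile.** Every cell is summarised by a fixed, ordered vector of
   228 measurements: 14 shape features per object (nucleus and cell), 12
   intensity features and 12 radial-distribution features per object per
   stain, and 13 Haralick gray-level co-occurrence texture statistics per
   object per stain at two scales (3 and 8 px). 28 + 48 + 48 + 104 = 228.
3. **Classification.** Five supervised classifiers — random forest (20
   trees), one-vs-rest ridge logistic regression, RBF SVM, k-nearest
   neighbours (k = 5) and Gaussian naive Bayes — are trained on
   standardized features (training-partition statistics only) and evaluated
   by pooled stratified 10-fold cross-validation and a stratified 50/50
   hold-out split, with row-percentage confusion matrices, one-vs-rest ROC
   curves and learning curves.

A synthetic-scene generator (`render_scene()`, `generate_dataset()`) draws
cells from per-phenotype morphology archetypes (polar-harmonic outlines,
per-cell lognormal staining brightness, Poisson + Gaussian noise) with
exact per-cell ground-truth masks, so the whole pipeline is testable and
reproducible without any microscopy download.

## Worked example

```r
library(cytoprofiler)

# a small synthetic experiment: 25 images, 5 phenotypes, ground truth known
dir <- tempfile()
generate_dataset(scene_config(rng_seed = 1), n_images = 25, out_dir = dir)

features <- profile_dataset(discover_images(dir))
dim(features)
#> [1] 449 231        # 449 cells x (provenance + 228 measurements)

report <- evaluate_classifiers(features, seed = 1)
report
#> <cyto_eval> 449 cells, 5 classes, seed 1
#> 10-fold CV per-class accuracy (%):
#>                        M1    M2 naive_mac mono_d0 mono_d6
#> random_forest       100.0  98.9      92.2   100.0    91.1
#> logistic_regression 100.0 100.0      92.2    98.9    91.1
#> svm                 100.0 100.0      92.2   100.0    88.9
#> knn                  96.6 100.0      82.2    96.7    91.1
#> naive_bayes          96.6 100.0      88.9   100.0    91.1
```

Each row is one classifier; each number is the percentage of cells of that
true phenotype recovered by pooled 10-fold cross-validation. Day-0
monocytes — small, round and uniform — are near-perfect for every method;
the hardest separation is between naive macrophages and day-6 monocytes,
whose cell-area distributions are nearly identical (they differ mainly in
nuclear size), and that is also the dominant entry off the confusion-matrix
diagonal:

```r
round(report$cv$random_forest$confusion, 1)   # rows sum to 100
tidy(report)       # one row per classifier x class x protocol
glance(report)     # one row per classifier: CV, holdout, mean AUC
autoplot(report, "confusion")
autoplot(report, "roc")
```

At the full default scale (150 images, ≈ 540 cells per class) per-class CV
accuracies for M1 and M2 exceed 95% for the random forest and the logistic
regression, and those two classifiers lead the SVM and kNN in mean
accuracy.

`run_pipeline(pipeline_config(...))` wires the same stages into a single
call that writes the feature table, evaluation report (JSON + CSV), figures
and a provenance file; `inst/cli/cytoprofiler.R` exposes `synth`,
`segment`, `profile`, `train-eval`, `predict` and `all` subcommands for
shell use.

## Testing

```r
devtools::test()
```

The suite builds every fixture in code: analytic shape/texture oracles
(rasterized discs, closed-form GLCMs), segmentation IoU against generator
ground truth, classifier-protocol invariants (stratification, no-leakage
standardization, ROC/confusion identities, chance-level and
perfect-separation checks), and an end-to-end evaluation of the default
study conditions.
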
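---
title: "Morphological phenotyping of macrophages: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological phenotyping of macrophages: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoprofiler)
```

## The problem

Classifying human macrophage activation states (pro-inflammatory M1,
anti-inflammatory M2, unpolarised naive macrophages, and their monocyte
precursors at day 0 and day 6 of culture) normally requires panels of surface
markers, cytokine assays and qRT-PCR. Cell morphology carries much of the
same information: M2 macrophages spread into the largest, smoothest cells
with a pronounced peripheral actin rim; M1 macrophages are smaller,
elongated or irregular, with a dense punctate actin texture; day-0 monocytes
are small, round and strikingly uniform; day-6 monocytes and naive
macrophages are larger cells whose footprints are nearly indistinguishable
from one another, the day-6 monocytes carrying the largest nuclei.

`cytoprofiler` implements the full image-based phenotyping pipeline: nuclei
are detected in the DAPI channel as primary objects, cell bodies are grown
from those seeds in the phalloidin (f-actin) channel, every cell is
summarised by a fixed 228-measurement "cytoprofile", and five supervised
classifiers are trained and evaluated with stratified cross-validation,
row-percentage confusion matrices, one-vs-rest ROC curves and learning
curves. A synthetic-scene generator with exact per-cell ground truth makes
every stage testable without microscopy data.

## The synthetic-scene generator

Each cell outline is a polar curve
$r(\theta) = R\,(1 + \sum_{k=2}^{6} a_k \cos(k\theta + \phi_k))$
with harmonic amplitudes drawn uniformly within
$\pm\,\mathrm{irregularity}/k$; low-order harmonics produce lamellar,
irregular outlines without self-intersection. Elongation is applied as an
area-preserving anisotropic scaling (major/minor ratio $e$, area stays
$\pi R^2$), so the size and shape axes of the archetypes are independent.
The nucleus is a milder ellipse displaced by `nucleus_offset_frac`
and clipped to lie inside the cell.

The per-phenotype defaults (`phenotype_archetypes()`) encode the orderings
described above, in pixels at an assumed 0.5 µm/px: mean cell radius 27 px
for M2 down to 8.5 px for day-0 monocytes; day-6 monocytes and naive
macrophages share near-identical cell-scale morphology (their cell-area
histograms overlap by more than 80%) and differ chiefly in nuclear radius
(10.6 px vs 7.5 px). M1 carries a dense spot process (8 punctae /100 px²,
blur σ 0.7 px) against M2's sparse smooth field (0.6 punctae, σ 3 px); the
texture floor keeps the whole cell body above background so the foreground
remains thresholdable, and each phenotype's rim gain brightens the 2 px
boundary band.

Two stochastic layers make the scenes realistic rather than idealised:

* **Per-cell staining brightness.** Every cell draws an independent
  lognormal brightness factor per channel (log-sd 0.5, truncated to
  [0.6, 4], mean ≈ 1). Fluorescent staining intensity genuinely varies
  cell-to-cell far more than geometry does, and the resulting heavy-tailed
  intensity features dominate what distance-based classifiers see. This is
  the single most consequential generator setting: with it, the kNN and
  RBF-SVM classifiers lose their edge over the random forest and ridge
  logistic regression, reproducing the qualitative classifier ranking that
  motivates the package. Distribution-shape features (radial fractions,
  quantized texture) are ratios and survive it unchanged.
* **Detector noise.** Poisson shot noise on the full field plus additive
  Gaussian read noise (sd 5) over a background of 100, applied after a mild
  optical blur (σ 0.8 px). Otsu-based segmentation stays reliable at this
  SNR.

Cells are placed by rejection sampling (at most 1000 attempts per cell, a
minimum 2 px separation, failure reports the achieved count), so masks never
overlap and ground truth is exact. Images are written as 16-bit TIFF pairs
named `<set>_<class>_<idx>_<channel>.tif` — the class label lives in the
file name, which is how the analysis side reads it back. The default
dataset is 150 images of 512×512 px with 18 cells each, one phenotype per
image, giving ≈ 540 cells per class before quality filtering; this matches
the scale at which the headline accuracies are quoted (≥ 500 cells per
class) while a full pipeline run stays in the minutes range on one core.

What the generator does **not** emulate: optics (no PSF, no chromatic
effects, no uneven illumination), touching or overlapping cells, debris and
mitotic figures, and 3-D structure. Passing tests on synthetic scenes
therefore demonstrate the correctness and calibration of the pipeline, not
segmentation performance on clumped real-world cultures.

## Segmentation

Primary detection follows the classic recipe: global threshold, hole
filling, watershed declumping on the smoothed (σ 2 px) in-mask distance
transform, and an equivalent-diameter filter (8–60 px). Secondary detection
grows cell bodies from the nucleus seeds by propagation on the smoothed
actin image, restricted to the actin foreground mask (holes filled first, so
dim inter-punctae regions stay inside cells).

Three numerical choices matter and were each validated against ground-truth
IoU:

1. **Log-domain thresholding.** Global thresholds are computed on the
   log-transformed, Gaussian-smoothed image (σ 1 px for DAPI, 0.5 px for
   actin, where boundary fidelity matters more than noise suppression).
   With brightly and dimly stained cells in one field, a raw-intensity Otsu
   threshold sits among the bright cells and loses the dim ones; in the log
   domain the dim cells stay above it.
2. **A robust floor under Otsu.** Otsu's criterion collapses into the
   background noise when the foreground covers only a few percent of the
   field (nuclei cover ~1%; day-0 monocyte bodies ~2%). The threshold is
   therefore `max(otsu, median + 2.5 * MAD)` of the log image, the standard
   safeguard for sparse-foreground fields.
3. **Per-object half-maximum boundary refinement.** Any single global
   threshold places the boundary of a blurred object at a position that
   depends on its brightness, which injected a ~40% brightness-coupled
   error into measured areas (the measured nucleus-size separation between
   naive macrophages and day-6 monocytes collapsed from d′ ≈ 3 to below 1).
   Each detected object is therefore re-thresholded locally at
   `background + 0.5 × (object median − background)` — the half-maximum
   crossing, which is brightness invariant. The refinement only shrinks an
   object within its watershed territory, so adjacent cells stay disjoint,
   and the seed nucleus is always re-added so `nucleus ⊂ cell` holds.

On noise-free, well-separated scenes the per-object IoU against ground truth
exceeds 0.9 for cells and 0.95 for nuclei; at default noise ≥ 95% of cells
are recovered. Quality control then drops border-touching cells (policy
`"discard"` by default) and unpaired objects, and relabels contiguously.

## The 228-measurement cytoprofile

The schema is fixed and its order is part of the public contract
(`feature_schema()`, hash-stable): 14 shape features × 2 objects (nucleus,
cell) = 28; 12 intensity features × 2 objects × 2 channels = 48; 12
radial-distribution features × 2 × 2 = 48; 13 Haralick texture features ×
2 objects × 2 channels × 2 scales = 104. Total 228.

Conventions, chosen once:

* Perimeter is the length of the closed polygon through the centres of the
  8-connected outer boundary pixels (diagonal steps √2, radial-sweep
  tracing); form factor is 4πA/P² and compactness its reciprocal.
  Solidity uses the convex hull of pixel *corners*, so a filled rectangle
  scores exactly 1. Orientation comes from the second-moment ellipse,
  degrees in (−90, 90].
* Intensity statistics use the population (n) standard deviation, the
  unscaled median absolute deviation, and linearly interpolated quartiles.
  "Edge" means the 4-connected boundary pixels; mass displacement is the
  distance between the binary and intensity-weighted centroids.
* The radial distribution uses 4 bins of equal width in normalized
  distance-from-edge, measured toward the in-mask point farthest from the
  edge (robust for crescent shapes, unlike the centroid); per bin it
  reports the intensity fraction, its area-normalized version and the
  coefficient of variation over 8 angular wedges.
* Haralick features quantize the in-mask range to 8 levels and average the
  13 classical statistics over the 4 standard directions at offsets 3 and
  8 px (two scales are what the 228-slot arithmetic requires); the GLCM is
  symmetric and normalized; a constant region returns the point-mass
  convention (ASM = IDM = 1, entropies/contrast/correlation 0). Sum
  variance is centred on the sum average.
* Degenerate values (empty radial bin, zero-variance correlation) are
  imputed as 0 and counted, so profiles are always finite and
  classifier-ready.

## The classification protocol

The five classifiers are random forest (20 trees), one-vs-rest L2-penalised
logistic regression (ridge penalty λ = 0.001 on the glmnet scale, about 1/n
for these table sizes), an RBF-kernel SVM (cost 1), k-nearest neighbours
(k = 5), and Gaussian naive Bayes. All of them see features standardized to
zero mean and unit variance with statistics computed on the training
partition only and re-applied verbatim at prediction time; a test asserts
that no test-set information reaches the standardizer. The in-package kNN
exposes full per-class vote fractions (needed for ROC curves); its hard
labels are cross-checked against `class::knn` in the test suite.

Evaluation reports both protocols and labels them: pooled stratified
10-fold cross-validation on the full table, and a stratified 50/50
train/test split whose held-out half supplies ROC curves and AUCs.
Per-class "accuracy" is class recall — the diagonal of the row-percentage
confusion matrix. One-vs-rest ROC curves sweep thresholds over the unique
scores (ties share a threshold, so constant scores give the chance
diagonal), with trapezoidal AUC. Learning curves subsample stratified
training sets at a list of fractions and average over repeats. All
randomness (splits, folds, forest and SVM fitting) is seeded; reruns are
bit-identical.

At the default study conditions (150 images, ≈ 530–540 cells per class
entering classification) the pooled 10-fold CV accuracies land in the
mid-90s for most classes, day-0 monocytes — the deliberately distinct
negative control — above 98% for every classifier, and the dominant
residual confusion is day-6 monocytes being called naive macrophages, the
same asymmetry the morphology implies. The random forest and logistic
regression lead the SVM and kNN in mean per-class accuracy; the margin is
real but modest, and the mechanism (heavy-tailed intensity dimensions
diluting kernel distances) is discussed above. These are properties of the
synthetic conditions; real cultures with clumping, debris and batch effects
will be harder.

## Known limitations

* The 228-feature schema is a faithful reconstruction of the family
  structure (size, shape, intensity, radial distribution, texture over two
  objects and two stains), not a re-implementation of any specific
  CellProfiler version; numeric equality with CellProfiler output is not
  claimed.
* The generator's archetypes are calibrated to reproduce qualitative
  population orderings and headline accuracy bands, not fitted to any real
  image set.
* Boundary ("edge") intensity features of threshold-derived masks read
  values near the threshold contour by construction, so edge intensity
  *normalised to area* scales like perimeter/area and decreases with cell
  size in this model; the un-normalised integrated edge intensity is the
  quantity that rises with cell spread and carries the phenotype signal.
* Segmentation assumes non-touching cells; declumping handles merged
  nuclei but there is no overlap resolution for cell bodies.
* All geometry is 2-D; pixel size is nominal (defaults are stated in px).
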
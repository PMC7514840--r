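---
title: "Hand-crafted gland classification: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hand-crafted gland classification: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In H&E-stained prostate tissue at low Gleason grades, individual gland
units remain visible: a bright lumen surrounded by a cytoplasm ring and an
epithelial layer of nuclei. Automatic gland segmentation seeded from
lumen-like blobs produces *candidates* of three kinds: true benign glands
(large, often fusiform lumens with a dense, frequently multilayer nuclei
ring), Gleason grade-3 glands (smaller, rounder lumens with a sparser
nuclei layer) and *artefacts* — lumen-coloured regions such as tissue
tears that are not wrapped in cytoplasm or epithelial nuclei. glandclass
classifies candidates into these three classes from hand-crafted
descriptors, with patient-wise nested cross-validation.

## Tissue-component mapping

Each 8-bit RGB patch is reduced to four binary maps. Channels are computed
at 50% scale (bilinear): the HSV saturation channel (lumens are
near-white, hence minimally saturated), the CMYK cyan channel with black-key
correction (separates cytoplasm/stroma tints), and the RGB colour grid
itself. Pixels are clustered by k-means — k = 3 on saturation and cyan,
k = 4 on colour — with clusters relabelled in ascending centroid intensity
so "the darkest cluster" is a stable notion independent of initialisation.
The lumen map is the darkest saturation cluster; cytoplasm and stroma are
the highest- and middle-cyan clusters; nuclei the darkest colour cluster.
Stain channels (hematoxylin, eosin) come from optical-density colour
deconvolution, `OD = -log10((I+1)/255)` unmixed with the standard H&E
stain matrix (normalised column vectors; third column the normalised
residual); concentrations are mapped to bounded pseudo-intensities
`1 - 10^(-C)` so every derived channel lives in [0, 1].

Post-processing uses an area opening with `lambda = 20` pixels and a
disk structuring element of radius 1 (the 5-pixel plus): lumen maps are
area-opened then dilated; cytoplasm/stroma opened then area-opened; nuclei
dilated (to fuse the epithelial ring) then area-opened (removing stray
stromal nuclei). Connected components use 8-connectivity except for the
candidate gland-mask area opening, which uses 4-connectivity. Two open
points were settled as follows: binarised maps are restored to **full
resolution** (nearest neighbour) *before* post-processing, so the area
threshold is expressed in the same full-resolution pixel units as the
candidate-level `lambda = 20`; and the cyan cluster-to-component
assignment (top = cytoplasm, middle = stroma) is exposed as configuration
since nothing in the mapping itself pins it down.

## The 241-entry descriptor

- **Morphology (20).** Ten region descriptors of the gland mask and the
  same ten of its lumen: area, convex area (pixel centres inside the hull
  of pixel centres, so a filled square has solidity exactly 1),
  second-moment-ellipse eccentricity and orientation (with the standard
  1/12 pixel-extent correction), equivalent diameter, extent, perimeter
  (length of the ordered 8-connected boundary walk), solidity, roundness
  and the perimeter/area ratio. Roundness is defined as
  `equivDiam/2 * perimeter / area`, reading the "radius of the gland" as
  the radius of the equivalent-area circle; the perimeter/area ratio is
  kept literally even though it is not scale-free, because the size
  dependence is itself class-informative here. The gland mask comes from
  the masked candidate crop: Otsu threshold of R+G+B, area opening
  (4-connectivity, lambda 20), flood fill, largest component.
- **Fractal (15).** The Hurst exponent H along 0, 30, 45, 60 and 90
  degrees for the cyan, hematoxylin and eosin channels. Profiles for
  oblique angles are obtained by rotating the crop with bilinear
  interpolation and trimming to the largest inscribed axis-aligned
  rectangle — this preserves unit sample spacing, which a Bresenham line
  walk would not. Each profile is first-differenced (fractional Gaussian
  noise if the image behaves as fractional Brownian motion), the squared
  DFT magnitudes are averaged across profiles, and a least-squares line
  through log10(PSD) vs log10(f) over positive frequencies up to Nyquist
  yields slope `1 - 2H`. Estimates are returned unclamped with a validity
  flag; constant crops return 0, flagged. Profiles must span at least 16
  pixels.
- **Texture (186).** 8x8 GLCMs at offsets (0,2) and (-2,2), symmetrised
  and normalised, on each of the three channels; 21 statistics per matrix
  (homogeneity, contrast, energy, correlation, entropy with natural log,
  8 column means, 8 column standard deviations) give 126 features. LBP
  riu2 labels (P = 8, R = 1, bilinear off-grid sampling, `s(0) = 1`) and
  the LBPV variance-accumulation histogram give 10 + 10 bins per channel,
  L1-normalised by the interior pixel count so candidates of different
  sizes are comparable: 60 features. Texture and fractal channels are
  computed on the unmasked bounding box by default (`use_masked_texture`
  flips this), since the surround of a candidate is informative —
  artefacts sit in stroma, true glands in epithelium.
- **Context (20).** Counts and pixel totals of nuclei elements
  (8-connected components; an element is "inside" a region only when all
  its pixels are), cytoplasm pixel totals, the lumen/gland area ratio,
  the mean and standard deviation of the lumen centroid-to-edge distance,
  and the cytoplasm+nuclei content of the toroid (gland minus lumen) —
  near zero for artefacts by construction.

Degenerate values (ratios over empty denominators, undefined estimates)
become 0 and are recorded per candidate; the schema (241 names, stable
order) ships as `inst/extdata/feature_schema.json`.

## Feature selection

Columns are z-scored; a one-sample Kolmogorov–Smirnov test against N(0,1)
(gate level 0.05 — the gate's level is a package choice, exposed as
`ks_alpha`) routes each feature to one-way ANOVA (normal) or
Kruskal–Wallis (otherwise) against the three classes. Features with
p ≤ 1e-6 survive. Surviving pairs with |r| ≥ 0.95 and correlation-test
p ≤ 1e-6 are thinned by one deterministic ordered pass that drops, within
each offending pair, the member with the larger class-test p (ties drop
the later schema column) — the less class-discriminant of two redundant
features is the right one to lose. Which member to drop is a package
decision; so is refitting the whole selection inside each outer CV
training split (leakage-safe) rather than once globally
(`global_selection = TRUE` mimics the one-shot variant).

## Classifiers and cross-validation

Folds are assigned **per patient** by greedy balanced bin-packing
(largest patients first, each to the fold minimising class imbalance), so
no patient contributes to both training and test. The cascade trains two
binary quadratic-kernel SVMs: artefact vs gland on all rows, benign vs
grade 3 on true-gland rows. `C` and `gamma` are tuned in
`[1e-2, 1e2]^2` on a log10 scale by minimising stratified 10-fold inner-CV
error, with a Gaussian-process Bayesian optimisation
(expected-improvement acquisition, 8 Latin-hypercube starts, 30
evaluations by default; a log-grid tuner is available). Scores are
calibrated to probabilities by a logistic (Platt-style) fit on the
training decision values — done in-package so the whole fit is
reproducible from the R seed. At prediction, rows with gland probability
exactly 0.5 are routed to the gland branch (favouring recall of true
glands). The benign-vs-grade3 metrics are computed over rows whose *true*
class is a gland.

The MLP has one hidden layer of 15 logistic units and a 3-way softmax,
trained full batch with momentum 0.9 and the classic adaptive
learning-rate rule: start at 1e-3, multiply by 1.5 after an improving
epoch, and when the candidate loss exceeds 1.04x the current loss, reject
the update, halve the rate and reset the momentum. Early stopping watches
a stratified 10% validation split with patience 20, cap 1000 epochs.
Full-batch is the natural regime for this accept/reject rule, which
compares whole-objective values.

Reported metrics: sensitivity, specificity, PPV, NPV, F-score, accuracy
and trapezoidal AUC per binary problem (mean ± sd over the five outer
folds) plus pooled multi-class accuracy. The score-significance analysis
treats each class's predicted probability as a variable: z-score, KS
normality gate, then ANOVA or Kruskal–Wallis against the true class,
averaged over folds.

## The phantom generator

The generator builds what the descriptors measure, not photorealistic
histology: perturbed-ellipse lumens (radial Fourier modulation, harmonics
2–4, amplitude ≤ 0.06 each — enough boundary irregularity to make
perimeter-based features non-trivial while keeping shapes star-shaped),
an additive cytoplasm ring (7–12 px), and nuclei discs (radius 2–3 px)
along the ring, two layers when the coverage density is ≥ 0.7. Class
conditions: benign lumens of equivalent radius 16–26 px with axis ratio
1.6–2.6 and nuclei coverage 0.9; grade-3 lumens 7–12 px, axis ratio
1.0–1.3, coverage 0.4; artefacts are bare blobs (8–18 px) with no ring
and no nuclei. These ranges were chosen once to mirror the qualitative
class differences the classifier is meant to exploit (grade-3 lumens
smaller and rounder; artefacts unwrapped), scaled to a desk-size patch.
Stain means are near-white lumen, pale blue-violet cytoplasm,
magenta-lavender stroma and dark blue-violet nuclei, with additive
Gaussian noise (sd 5) — the stroma tint keeps blue marginally above red
so that the cyan channel orders lumen < stroma < cytoplasm, which the
default cluster-to-component assignment assumes; with a pure red-dominant
pink, the black-key correction sends stroma cyan to exactly 0. Each
patient carries a random stain offset (sd 4 per RGB channel) and a
log-normal geometry multiplier (sd 0.06), so record-wise and patient-wise
CV genuinely differ. Candidates are placed by rejection sampling
(largest first); geometry is redrawn when a candidate cannot be placed,
and generation fails with an explicit error after bounded retries.

What the phantom does **not** emulate: touching/fused glands, stain
variation within a patch, blur, tissue folds, off-candidate debris, and
segmentation errors from a real gland segmenter. Green phantom tests
therefore establish the correctness of the *pipeline machinery* and its
statistical behaviour, not clinical performance on real slides.

The fGn synthesiser used to validate the Hurst estimator shapes each
row's spectrum exactly (complex Gaussian spectrum with power ∝
`f^(1-2H)`), i.e. rows are independent fGn samples by construction; the
estimator is checked on cumulative-summed rows, since it differences its
input internally.

## Numerical choices and degenerate inputs

- k-means: 10 seeded restarts with initial centres drawn from distinct
  observed values (guaranteeing distinct starting centroids on
  few-valued channels), 100 iterations.
- Otsu: 256-bin histogram over the observed range.
- GLCM quantisation: uniform 8 bins over [0, 1] (channel scale).
- Hurst PSD fit: frequencies 1..N/2 of the increment series, base-10 logs;
  constant inputs yield the flagged sentinel 0.
- Pearson correlation p-values in stage-2 selection via the exact t
  transform, df = n - 2.
- Empty lumen masks: lumen morphology zeroed with a validity flag;
  zero-denominator contextual ratios return 0, flagged.
- All randomness (generator, k-means, tuning, MLP initialisation, fold
  tie-breaks) flows from explicit integer seeds; repeated runs are
  bit-identical.

## Problem sizes used by the tests and the acceptance script

The shipped acceptance runs use a cohort of 15 patients x 10 patches x 6
candidates on 384-px patches (~900 candidates, balanced classes) — large
enough for the alpha = 1e-6 selection stage to behave as designed and for
patient-wise 5-fold CV with 10-fold inner tuning, while keeping a full
run in minutes on one CPU. Unit tests use smaller cohorts (5–8 patients,
256–320-px patches). The permuted-label null is evaluated with the
selection gate disabled (alpha = 1): under permuted labels no feature
passes 1e-6 — itself the designed behaviour, asserted separately — so a
model would otherwise not exist to measure chance-level accuracy.

## Known limitations

- The oblique-angle Hurst estimates (30/45/60 degrees) pass through a
  bilinear rotation resampling that attenuates high frequencies, which
  shifts them by a consistent offset (about +0.2 on white noise) relative
  to the raw 0/90-degree estimates. Within one angle the estimates remain
  comparable across candidates — which is how the classifier consumes
  them — but the five directions should not be read as five unbiased
  estimates of one H.
- k-means always returns k clusters, so on a patch with no lumen-like
  structure the "darkest saturation cluster" is noise and the lumen map
  is spurious. This is harmless in the intended pipeline — candidates
  are seeded from lumen blobs, so gland-free patches contribute no
  candidates — but the maps themselves are only meaningful on patches
  containing the structures being mapped.
- The colour deconvolution uses the standard published H&E stain matrix;
  no per-slide stain estimation is performed.
- The cyan-channel cluster-to-component assignment assumes the stroma
  tint lies between lumen and cytoplasm in cyan; strongly eosin-dominant
  slides may need the configurable assignment flipped.
- Gland segmentation itself (e.g. watershed-based candidate extraction)
  is out of scope: candidates arrive segmented, or from the generator.
- Grades 4–5, whole-slide formats and CNN-based features are out of
  scope.
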
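---
title: "Methods: multi-dimensional microscopic molecular profiling with mmmprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-dimensional microscopic molecular profiling with mmmprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmmprofiler)
```

## The measurement this package models

Cyclic multiplexed imaging interrogates one tissue section with many stains by
iterating a stain / image / bleach cycle: a series of immunofluorescence (IF)
rounds, each contributing a Cy5 antibody channel plus a DAPI nuclear
counterstain, followed by transmitted-light histochemistry rounds (H&E, Alcian
blue, PAS, Verhoeff's elastic stain) captured as RGB. Because every cycle
images the same physical section, the channels can be fused into a per-pixel
molecular profile: a matrix with one row per tissue pixel and one column per
channel. With the default panel of 15 IF cycles (DAPI kept from the first and
last) and 4 brightfield cycles, that is 15 + 2 + 12 = 29 columns.

Everything downstream — unsupervised pixel phenotyping, similarity-based
colour display, supervised recognition of annotated histological features, and
nuclei segmentation — consumes this matrix. The package implements the full
chain, and ships a synthetic phantom generator so that every stage can be
validated against known ground truth without access to microscope data.

## The phantom generator: what it emulates, and what it does not

`phantom_spec()` / `make_phantom_core()` draw a labelled tissue cartoon from
parametric primitives: an extracellular-matrix field as base layer, smooth
muscle bands, epithelial blobs, lumen (background) blobs, vessel rings with
lumenal interiors, and nuclear disks scattered over tissue. Each feature has a
mean intensity per channel (`default_signatures()`, 0–255 scale), sketched
from the qualitative biology of the stains — endothelial markers (CD34,
CD105, Lyve-1) high in vessels, desmin/SMA in muscle, collagen-I and SPARC in
ECM, beta-catenin in epithelium, and DAPI plus hematoxylin in nuclei.
Brightfield signatures are held internally in the negated (dark-background)
orientation; files on disk are written conventionally bright so the import
path genuinely exercises the negation step.

Defaults were fixed once, as the conditions the rest of the package is
validated under:

* canvas 240 × 240 px, a scale at which a 0.321 µm/px acquisition holds
  roughly 60–120 nuclei; the generator places 90;
* additive Gaussian noise, `noise_sd = 4` grey levels — feature separations
  in the default signature table are then tens of noise SDs, i.e. clearly
  separable, which is the regime the classification guarantees refer to;
* tiles of 100 × 100 px with 10 % nominal overlap and integer stage jitter
  of SD 2 px;
* per-cycle rigid drift bounded by 4 px translation and 1.5° rotation.

The phantom is deliberately *not* photorealistic: it is piecewise-constant
plus white noise, with no texture, no illumination field, no bleaching
carry-over, no chromatic aberration, and rigid (not elastic) inter-cycle
motion. Tests passing on the phantom therefore demonstrate the correctness of
the algorithms under their stated models — offset recovery, transform
inversion, exact clustering recovery, fold disjointness — not robustness to
every artefact of real microscopy. All randomness flows through a single
integer seed; identical seeds give bit-identical datasets.

## Stitching

Tiles are assembled per cycle. For every grid-adjacent pair the translation
is estimated by phase correlation of the two overlap strips (strip width =
overlap prior + 16 px search margin), with three safeguards that matter in
practice:

* the circular wrap ambiguity of the FFT is resolved toward the shift the
  overlap prior implies, not toward zero;
* the strongest in-window phase peaks are validated by the direct normalised
  cross-correlation (NCC) of the implied overlap, and if none validates well
  the estimator falls back to scoring every admissible integer shift —
  phase peaks dilute when the true overlap is small or texture-poor;
* pairs whose overlap strip has zero variance are flagged and fall back to
  the nominal layout.

Per-tile positions are then reconciled globally by weighted least squares
over all pairwise constraints (weights from the pair NCC scores, sharpened by
two Huber-style reweighting passes), anchored at the first tile, and the
canvas is fused with linear feather blending. Sub-pixel precision comes from
parabolic interpolation of the correlation peak.

The whole procedure is run three times with overlap priors of 5, 8 and 10 %
(`consensus_stitch()`); the per-tile consensus is the coordinate-wise median
across runs, the run with the smallest summed Euclidean distance to the
consensus wins, and ties go to the smallest prior. The stitched canvas is
cropped (or padded) to a centred square, 2300 px by default. `align_core_grid()`
tracks tissue cores across cycles from their centroid tables: one global
translation per cycle (mean alignment refined on matched pairs), nearest-
centroid matching, drops beyond half the minimum inter-core spacing, and a
hard error on ambiguous matches.

Design points left open by the upstream description and fixed here: the
consensus is the coordinate-wise median (robust to one bad run); blending is
linear feathering; the crop is centred; overlap priors are interpreted as
percent of the tile edge, with a `units = "px"` switch.

## Registration

All cycles are aligned into the frame of the first IF cycle using rigid
(rotation + translation) transforms about the canvas centre:

1. IF cycles chain sequentially on their DAPI fiducials (min–max normalised);
2. brightfield cycles chain among themselves on the luminance of the negated
   RGB;
3. the first brightfield cycle is bridged to the last IF cycle — hematoxylin
   makes the negated H&E image nuclei-bright, which is what lets a
   DAPI-to-histochemistry bridge work;
4. composed transforms are applied to every channel (bilinear interpolation;
   nearest-neighbour for label images), with validity masks marking pixels
   whose value was interpolated rather than filled.

`rigid_register_pair()` searches rotation coarse-to-fine (default ±4° at
0.5°, refined at 0.05° with a final parabolic step) and recovers translation
at each candidate angle by sub-pixel phase correlation, scoring candidates by
NCC over the valid region. The similarity guard defaults to NCC 0.2 in
`register_series()`: differently stained cycles share structure but not
contrast, so even a correct cross-stain alignment yields modest NCC, while
genuinely unrelated images decorrelate to ≈ 0. A failed pair aborts with the
cycle pair named (or flags, under `on_low_similarity = "flag"`).

Two deliberate simplifications: the metric is plain NCC (the upstream
toolchain delegated this to its registration plugin without stating one), and
the final elastic refinement of the original procedure is out of scope —
rigid transforms suffice for stage-drift-like motion, and the package's
transforms stay invertible and composable in closed form.

## Matrix extraction

Foreground is defined as the pixels with defined values in *every* aligned
cycle (intersection of validity masks); an optional `tissue_threshold`
additionally requires some channel's normalised intensity to exceed a cutoff,
but defaults to 0 since presence-across-cycles is the stated rule. Rows are
emitted in raster (row-major) order with 1-based pixel coordinates carried in
`px_row`/`px_col`; columns follow the panel descriptor order; intensities
stay on the native 8-bit scale — standardisation is applied where an analysis
calls for it, not in the container.

## Unsupervised profiling

* **PCA** (`pca_summary()`): channels standardised to zero mean and unit
  variance (zero-variance channels dropped with a warning), components
  ordered by variance, per-component score images min–max scaled to [0, 255]
  for export.
* **k-means** (`kmeans_profiles()`): Hartigan–Wong on the raw intensities,
  `k = 100`, `iter.max = 20`, one start, seeded centroid initialisation from
  sampled rows; `k` is reduced (with a warning) when fewer distinct profiles
  exist. The scaling asymmetry — standardised PCA, raw k-means — is
  intentional and mirrors the analysis this package reimplements. `k` is a
  user choice, not an optimised quantity.
* **Colour coding** (`mds_colormap()`): Kruskal's nonmetric MDS of the
  centroid vectors into 3-D, initialised from classical MDS; axes ordered by
  embedded variance and reflected to positive skew for reproducibility; the
  embedding is mapped *isotropically* into the RGB cube (one common scale
  factor, longest axis spanning 0–255). Isotropic rather than per-axis
  scaling is essential: per-axis stretching re-ranks pairwise distances and
  would break the whole point of similarity-based colouring. Stress is
  reported as a fraction; duplicate centroids are jittered by a deterministic
  ε with a warning; 2–3 centroids embed exactly without the iterative step.
* **Fidelity** (`imputation_r2()`): per channel, the squared Pearson
  correlation between original intensities and the values obtained by
  substituting every pixel with its cluster centroid. Channels with zero
  variance on either side are reported undefined and excluded from the mean.
* **Cross-sample compilation** (`compile_global()`): row-concatenated
  centroid matrix indexed by (sample, cluster) — 102 samples × 100 clusters
  gives 10,200 rows — with average-linkage hierarchical clustering on
  Euclidean distance and one pooled MDS palette refit on all centroids, so
  identical profiles get identical colours in every sample. Both extras are
  quadratic or worse in the row count and can be disabled
  (`dendrogram = FALSE, colormap = FALSE`) for large compilations.

## Supervised histology

Annotations are an indexed label image plus a category legend.
`feature_profiles()` clusters each category separately (k = 100 per category,
reduced when pixels run short) and flags a centroid *feature-specific* when
its nearest neighbour among all centroids belongs to its own category. A
caution from our simulations: when two categories have literally identical
intensity distributions, specificity does not settle at 50 % — independent
k-means tilings of the same density interleave, so nearest neighbours come
predominantly from the *other* set and specificity collapses toward zero.
The flag is therefore evidence of distinctness, not a calibrated probability.

Classification uses a spatial two-fold design: `checkerboard_partition()`
overlays an alternating grid of g × g squares (region 1 where
⌊(row−1)/g⌋ + ⌊(col−1)/g⌋ is even), trying g = 100, 50, 20 in decreasing
order and keeping the largest g for which both regions contain every
category. `cross_predict()` trains a linear discriminant on the annotated
pixels of one region, predicts the other, performs the reciprocal analysis,
and merges the two disjoint prediction sets; the confusion matrix counts
annotated pixels only, and per-feature accuracy is the percentage of a
feature's annotated pixels predicted correctly.

The LDA is implemented directly (class means, pooled within-class covariance,
empirical priors by default with a `uniform` option, argmax of the Gaussian
discriminant score) because the covariance carries a relative ridge,
λ·trace(S)/d with λ = 1e-4, on the diagonal: real pixel data (n ≫ d) barely
notices it, but degenerate synthetic inputs — noiseless phantoms, ablated
single channels — need the regularisation to stay positive-definite. Raw
intensities are used, matching the k-means choice. `ablate_channels()`
reruns the cross-prediction on a channel subset (preset `"he"` = the H&E RGB
columns) and pairs per-feature accuracies with the full panel;
`apply_model_cross_sample()` applies a trained model to an unannotated sample
under a strict channel-layout contract.

## Nuclei segmentation

`segment_nuclei_dapi()` re-expresses a standard object-recognition recipe:
global Otsu threshold on the min–max normalised DAPI image, hole filling,
distance-transform watershed to declump touching nuclei, and an area gate
(defaults 30–5000 px, appropriate at ≈ 0.32 µm/px; both configurable). The
comparison statistic against annotation-derived nuclei
(`overlap_statistic()`) is the smaller-set overlap,
100·|A∩B|/min(|A|,|B|) — symmetric, 100 when one mask contains the other,
undefined (NA) when the smaller mask is empty.

## Numerical choices and degenerate inputs

* Coordinates are 1-based (row, col) with origin at the top-left throughout,
  the native R convention; transforms rotate about the canvas centre.
* Phase-correlation peaks are refined by parabolic interpolation (±0.5 px
  clamp); rotation estimates by a parabolic step over the fine angle grid.
* Constant (zero-range) images are a hard error wherever a min–max
  normalisation is required; zero-variance overlap strips fall back to the
  nominal layout with a flag; zero-variance channels are dropped from PCA
  and excluded from fidelity means.
* Ties: consensus stitching breaks toward the smallest overlap prior;
  discriminant-score ties take the first class in sorted order; the
  checkerboard selects the largest feasible grid regardless of the order
  candidates are listed in.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script validate on: 240² canvases for the
full-panel phantoms (57,600-pixel matrices, 29 channels), a 280² canvas cut
into a 3 × 3 tile grid for stitching, 200² five-cycle series for
registration, 102 phantoms of 48² with a reduced 3-cycle panel for the
10,200-row compilation, and 1,000–4,000-point draws for the classifier
checks. These sizes keep every stage's behaviour measurable against ground
truth while each check runs in seconds.

## Known limitations

* Rigid-only registration: genuinely elastic tissue deformation between
  cycles is not modelled or corrected.
* The foreground rule is presence-across-cycles; autofluorescence and
  spillover correction are out of scope.
* The classifier is pixel-wise on intensities only — no morphology, no
  neighbourhood context.
* The phantom's simplicity means performance numbers obtained on it are
  upper bounds for real tissue, not predictions.
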
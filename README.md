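# mmmprofiler

Multi-dimensional microscopic molecular profiling of tissue images in R.

Cyclic multiplexed imaging repeatedly stains, images, and bleaches a single
tissue section — a series of immunofluorescence rounds (one Cy5 antibody
channel plus a DAPI counterstain per round) followed by RGB brightfield
histochemistry (H&E, Alcian blue, PAS, Verhoeff's) — so that every pixel ends
up with a multi-channel molecular profile. `mmmprofiler` implements the full
computational chain that turns per-cycle microscope tiles into biology:

1. **Stitching** — per-cycle tile assembly by phase correlation with
   consensus selection over overlap priors (5/8/10 %), feathered blending,
   centred 2300 px crop, and core-grid tracking across cycles.
2. **Registration** — rigid alignment of all cycles into the first-IF frame,
   using DAPI as the fiducial for IF cycles, negated-RGB luminance for
   brightfield cycles, and a rigid bridge between the two series.
3. **Extraction** — the per-pixel data matrix `X` (foreground pixels ×
   channels; the default panel gives 15 Cy5 + 2 DAPI + 4×3 brightfield = 29
   columns), with pixel coordinates carried alongside.
4. **Unsupervised profiling** — scaled PCA; Hartigan–Wong k-means
   (`k = 100`, `iter.max = 20`) on raw intensities; similarity-based colour
   coding by nonmetric MDS of the cluster centroids into RGB; clustering
   fidelity as the per-channel imputation `r² = cor(x_c, x̂_c)²` where `x̂`
   replaces each pixel by its centroid; and cross-sample compilation of all
   centroid vectors (102 samples × 100 clusters → 10,200 rows) under one
   universal palette.
5. **Automated histology** — per-feature k-means profiles with
   nearest-neighbour specificity flags; a checkerboard spatial partition
   (largest `g ∈ {100, 50, 20}` px covering every category in both regions);
   reciprocal train/test linear discriminant classification with
   `argmax_c [ x'S⁻¹μ_c − ½μ_c'S⁻¹μ_c + log π_c ]`, a ridge-regularised
   pooled covariance `S`, confusion matrices with per-feature accuracies,
   and channel ablation (e.g. H&E-only).
6. **Nuclei segmentation** — Otsu + watershed declumping of the DAPI
   channel, compared against annotation-derived nuclei with the smaller-set
   overlap `100·|A∩B| / min(|A|,|B|)`.

A first-class **synthetic phantom generator** emulates the whole acquisition
(feature geometry, per-feature channel signatures, tile grids with jittered
overlap, per-cycle rigid drift, negated brightfield) with complete ground
truth, so every stage is testable end to end without microscope data.

## Worked example

```r
library(mmmprofiler)

spec  <- phantom_spec(seed = 1)              # 240x240 canvas, 15 IF + 4 BF cycles
truth <- make_phantom_core(spec)
stack <- as_registered_stack(truth)          # identity-registered phantom
m     <- build_matrix(stack, panel = panel_config(spec$if_stains, spec$bf_stains))
dim(m)
#> [1] 57600    31                            # 57,600 pixels; 2 coords + 29 channels

km <- kmeans_profiles(m, k = 100, seed = 1)
km
#> <cluster_model> k = 100 over 57600 pixels, total WSS = 2.223e+07

glance(imputation_r2(m, km))
#> # A tibble: 1 x 3
#>   mean_r2 n_channels n_undefined
#>     <dbl>      <int>       <int>
#> 1   0.978         29           0

mds_colormap(km)
#> <color_map> 100 clusters, stress = 0.1032

ann <- annotation_from_phantom(truth)
cp  <- cross_predict(m, ann)                 # checkerboard-cross-validated LDA
cp$confusion
#> <confusion_matrix> 5 features; per-feature accuracy mean 100.0%, median 100.0%
#>                ecm muscle epithelium vessel nuclei
#>   ecm        37102      0          0      0      0
#>   muscle         0  10589          0      0      0
#>   epithelium     0      0       4760      0      0
#>   vessel         0      0          0    868      0
#>   nuclei         0      0          0      0   2503
```

Reading the numbers: 100 clusters retain 97.8 % of the per-channel variance
(mean imputation r²); the MDS stress of 0.10 says the 29-dimensional centroid
geometry compresses into the colour cube with modest distortion; and with the
default phantom's clearly separated signatures the reciprocal checkerboard
classifier recovers every annotated feature perfectly — the interesting
failure modes appear when signatures are made to collide (see
`ablate_channels()`).

Result objects are tibble-friendly (`tidy()`, `glance()`) and plot themselves
(`autoplot()` for variance curves, fidelity bars, confusion heatmaps;
`plot_ablation()` for full-vs-subset accuracy scatters; `plot_rgb()` for
rendered cluster images).

A thin command-line front end over the same functions lives at
`inst/cli/mmmp.R` (`phantom`, `stitch`, `register`, `extract`, `cluster`,
`classify`, `nuclei` subcommands).

## Vignette

`vignettes/mmmp-methods.Rmd` documents the models and their assumptions, the
phantom's design and its limits, every tunable parameter with its default and
rationale, and the numerical edge-case policies.
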
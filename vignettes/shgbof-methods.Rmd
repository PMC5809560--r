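---
title: "Patch-based GLCM texture features and Bag-of-Features classification of SHG images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based GLCM texture features and Bag-of-Features classification of SHG images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Second harmonic generation (SHG) microscopy images collagen label-free:
type I collagen of subchondral bone emits strongly and shows thick,
anisotropic fibrous patterns, while the type II collagen matrix of hyaline
cartilage emits weakly and homogeneously, punctured by dark chondrocytic
lacunae with essentially no signal. In osteoarthritis, degeneration exposes
subchondral bone and produces fibrocartilage bundles at the cartilage
surface. `shgbof` quantifies these morphologies with second-order image
texture statistics and classifies whole images with a bag-of-visual-words
pipeline, so that tissue state (cartilage vs. bone, or hyaline vs. fibrous
vs. bone) can be read out automatically from intensity images alone.

## The texture model

The gray-level co-occurrence matrix (GLCM) of a region is the matrix
$p(i,j)$ of probabilities that two pixels separated by distance $d$ along
orientation $\theta$ carry quantized gray levels $i$ and $j$. We use
$d = 1$ and $\theta \in \{0^\circ, 45^\circ, 90^\circ, 135^\circ\}$, with
symmetric pair counting (each pair counted in both directions) so
$p = p^\top$. From $p$ we compute eight statistics: correlation, angular
second moment $\mathrm{ASM} = \sum_{ij} p(i,j)^2$, contrast
$\sum_{ij}(i-j)^2 p(i,j)$, inverse difference moment
$\mathrm{IDM} = \sum_{ij} p(i,j)/(1+|i-j|)$, entropy, sum entropy, sum
average and sum variance, the last three over the diagonal-sum distribution
$p_{x+y}(s) = \sum_{i+j=s} p(i,j)$ with 0-based levels, $s \in [0, 2N-2]$.

Numerical conventions, chosen once and used everywhere:

* **Entropy sign and base.** Entropy-like quantities are returned as
  $-\sum p \log p$ with the natural logarithm and $0\log 0 \equiv 0$ — the
  only sign under which "entropy" increases with disorder. The base only
  rescales values; histogram ranges (below) are chosen for natural log.
* **Correlation degeneracy.** For a constant region both marginal standard
  deviations vanish; correlation is defined as 0 ("no linear structure")
  instead of propagating NaN.
* **Marginal moments.** $\mu_i, \sigma_i$ are the mean and standard
  deviation of the row marginal $p_i(i) = \sum_j p(i,j)$ (and likewise for
  columns); the $i/j$ subscripts in the correlation formula require
  marginals rather than a single pooled moment.
* **Quantization.** Analysis images are 8-bit, but a GLCM over 256 levels
  computed from an 8 x 8 region (64 pixels) would be almost surely a
  permutation-like matrix carrying no statistics. Levels are therefore
  configurable with default 8 (linear binning of [0, 255], right-open bins,
  top bin closed) — standard practice for very small windows; it also keeps
  contrast and sum-average on a stable scale across images.

## From patches to feature vectors

Images are sampled on a regular square grid with step $g$ (32 or 64 px) by
64 x 64 px patches (16 x 16 µm at 0.25 µm/px — large enough to hold a few
lacunae, whose nearest-neighbor spacing is 10–20 µm). Each patch is
partitioned into its fixed 8 x 8 grid of 8 x 8-pixel ROIs (no overlap), each
ROI yields one GLCM per orientation, and the 64 per-ROI values of each
(parameter, orientation) pair are summarized as a 22-bin histogram
normalized to sum 1. The classifier uses four parameters — correlation,
ASM, contrast, IDM — giving the patch descriptor
$V = (h_{Cor}, h_{ASM}, h_{Con}, h_{IDM})$,
$h = (h_{0^\circ}, h_{45^\circ}, h_{90^\circ}, h_{135^\circ})$, of
dimension $4 \times 4 \times 22 = 352$. All eight parameters are available
through `full_texture_profile()` for exploratory maps.

Histogram bin ranges are the theoretical supports of each parameter
(correlation $[-1,1]$; ASM, IDM $[0,1]$; contrast $[0,(N-1)^2]$; entropy
$[0,\log N^2]$; sum entropy $[0,\log(2N-1)]$; sum average $[0,2N-2]$; sum
variance $[0,(2N-2)^2/4]$). Fixed, data-independent ranges make vectors
comparable across images and runs; frequencies rather than counts make them
invariant to how many patches survive signal filtering. Per-orientation
histograms are kept separate (no rotation averaging), which preserves
anisotropy information; the exact consequence is that rotating a patch by
90° permutes the orientation blocks, which the test suite asserts.

Low-signal regions are excluded at two levels: a patch is kept when at
least 25% of its pixels exceed gray level 10 (inclusive threshold); a whole
image is kept only when *more than* 25% of its area is signal (strict, per
the categorization rule's "more than 25%"). The cutoff value 10/255 is a
package default — the underlying protocol names only "gray-level
thresholding" — and the same value is used at both levels for coherence.

## Bag of Features

Patch descriptors from the vocabulary images are clustered with k-means
(k-means++ seeding, Lloyd iterations, 10 restarts, best within-cluster sum
of squares kept); the $k$ centroids are the visual words. Each image is
then encoded as a term vector: every signal patch is assigned to its single
nearest word (Euclidean distance — assignment "to the closest term" is
1-nearest-centroid; voting over $k>1$ centroids is not meaningful for
quantization), counts are normalized to frequencies. Ties anywhere break
toward the lowest index, for reproducibility.

Term vectors feed a linear soft-margin support-vector classifier. The
deployment environment provides no SVM library, so the package carries a
small deterministic implementation: L2-regularized L1-loss SVM solved by
dual coordinate descent with a fixed sweep order, bias by feature
augmentation, unit box constraint ($C = 1$), term vectors used as-is (they
are already normalized). Three-class problems use one-vs-one
error-correcting output codes (three pairwise learners, majority vote,
lowest class index on ties) — the common default for three classes.

Evaluation mirrors the consecutive-runs protocol: the labeled set is
split into `n_runs` (default 4) stratified folds; run $r$ tests fold $r$
and trains on the rest; per-run row-normalized confusion matrices are
averaged. Two vocabulary policies are provided because the original
protocol built the vocabulary from *all* images: `"paper"` reproduces that
(codebook from every image; held-out images still unseen by the
classifier), while the default `"strict"` clusters training-fold patches
only, so no test pixel influences any fitted component.

## The synthetic world

No images from the original study are deposited, so the package carries a
generator whose defaults state what the classes look like; they were fixed
a priori from the morphological descriptions and are not tuned to test
outcomes:

* **Cartilage / Hyaline** — base level 110/255 with a ±8% low-frequency
  field and additive speckle (sd 12), carved by near-zero elliptical
  lacunae (radius 8–14 px, axis ratio 0.7–1) on a jittered lattice with
  60 px spacing (15 µm, inside the observed 10–20 µm range).
* **Bone** — darker base (90) overlaid by 70 bright (amplitude 130),
  4 px-wide fiber ridges per 512-px frame at a random common orientation
  with 15° spread; the rendered mean intensity (~160) exceeds cartilage
  (~100), matching the stronger type I collagen signal.
* **Fibrous** — the cartilage model plus thin (2 px), near-horizontal
  fibers confined to a surface band occupying 30% of rows, reflecting that
  fibrillation areas are small relative to hyaline area — which is exactly
  why fibrous images are the hard class.

Images are simulated on the 12-bit acquisition scale and passed through the
same floor(v/16) conversion as real data, so the bit-depth path is
exercised end to end. Fiber count scales linearly with image side so area
coverage is size invariant.

What a green benchmark on this world does establish: the full pipeline
(quantization, GLCM, histograms, codebook, term vectors, SVM, folds) is
wired correctly and the texture statistics separate textures that differ in
the ways the tissue classes differ. What it does not establish: performance
on real SHG images, which carry optical speckle correlations, depth
attenuation, focal-plane variation and biological heterogeneity that the
generator does not model. The published confusion-matrix values are
therefore out of reach by construction, and the acceptance suite asserts
qualitative analogues (high 2-class accuracy, codebook-size robustness,
denser grids not hurting) rather than the printed numbers.

One sensitivity reported for the real data — accuracy collapsing at
$k = 5$ — does **not** reproduce in this world, and the corresponding
acceptance check is knowingly left failing rather than weakened. Synthetic
classes are far more homogeneous than real tissue: five visual words
already carry the class signal, and at the benchmark seed the 5-word
codebook classifies the 3-class task perfectly while the 20-word codebook
shows the (realistic) fibrous-to-hyaline confusion. The collapse at small
$k$ observed on real images is a property of their within-class diversity,
which the generator deliberately does not inflate after the fact: tuning
the generator until the check passed would make the test about the tuning,
not the method.

## Defaults that matter

| parameter | default | meaning |
|---|---|---|
| `levels` | 8 | GLCM quantization depth for 8-bit input |
| `d` | 1 px | co-occurrence offset |
| `symmetric` | TRUE | bidirectional pair counting |
| `nbins` | 22 | histogram bins per (parameter, orientation) |
| patch size | 64 px | 16 µm at 0.25 µm/px |
| `grid_step` | 64 px (32 denser) | patch sampling stride |
| `signal_threshold` | 10 | gray level above which a pixel is signal |
| `min_signal_fraction` | 0.25 | patch: inclusive; image: strict |
| `k` | 20 (5–100 sweep) | codebook size |
| `n_runs` | 4 | consecutive evaluation runs |
| SVM cost | 1 | soft-margin box constraint |

## Known limitations

* The TIFF codec is deliberately minimal (uncompressed, single-sample
  grayscale); PNG is not written (no deflate dependency) — PGM covers the
  text-fixture role.
* Run configuration is JSON, not YAML (no YAML parser in the dependency
  footprint).
* The generator draws straight fibers and elliptical lacunae; it does not
  model optical sectioning, polarization dependence, or z-stacks beyond
  slice-wise use.
* `evaluate_runs()` requires at least `n_runs` images per class; the
  original study's exact four-run split tables are not public, so folds
  are stratified random under a fixed seed.
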
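---
title: "Cross-organ gland segmentation: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-organ gland segmentation: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Gland morphology drives grading of adenocarcinomas, and delineating glands in
H&E tiles by hand is slow and subjective. Training a segmentation network needs
many gland annotations, and glands look very different across organs, so a
network trained on one organ transfers poorly. Stroma — the connective tissue
between glands — is far more consistent across organs. `glandseg` implements
two parallel segmentation routes that share one architecture and one training
recipe:

* **gland route** — the network predicts the glands directly, plus their
  contours;
* **stroma route** — the network predicts the stroma (and stroma contours),
  and glands are recovered by inverting the stroma under a three-way tissue
  model (gland / white / stroma).

Everything is testable at desk scale because the package ships a seeded
synthetic-tissue generator that emulates exactly the structures the pipeline
reasons about.

# Stain normalization

Stain contributions are approximately additive in optical density,
`od = -log10((v + 1) / 256)` per channel. Each tile is modelled as
`OD ≈ C %*% M` with a 2×3 non-negative stain basis `M` (rows unit-norm,
hematoxylin first) and per-pixel non-negative densities `C`. The basis is
estimated by seeded two-atom dictionary learning: pixels with OD norm below
0.15 (near-white) are excluded, up to 3000 tissue pixels are subsampled,
the basis is initialized from the extreme angles of the OD cloud's principal
plane, and the fit alternates sparse non-negative coding (L1 weight 0.1; with two
stains the per-pixel problem has an exact active-set closed form) with
multiplicative non-negative basis updates and row renormalization, and ends
with a deterministic k-lines polish — each atom is refit as the leading
singular direction of the pixels it dominates — which removes the shrinkage
bias the multiplicative updates leave on the atoms. Normalizing a tile
re-scales each stain's density so its 99th percentile matches the target
tile's, then recombines with the target basis — colors move, structure does
not, and annotation rasters are never resampled.

Choices worth knowing:

* The row-order ambiguity of any two-atom factorization is resolved by
  convention: the hematoxylin row is the one with the larger blue OD
  component.
* The permutation-free accuracy of the fit is what the tests measure: on
  seeded compositions with genuinely sparse densities the recovered rows land
  within 0.05 radians of the generating rows on average. On tissue whose
  mixtures are *not* sparse (e.g. a stroma whose pixels all share one H:E
  ratio) the sparsest basis is legitimately a mixed direction; that is a
  property of the model, not an estimator failure.
* The reference target image is a free choice (the method does not define
  one); every entry point therefore takes the target explicitly.

# Ground-truth derivation

Both routes need an (object, contour) pair per tile.

* Gland mask: `label > 0`.
* Contour mask: boundary pixels (instance pixels 4-adjacent to a different
  label, background, or the frame) dilated to a configurable thickness,
  default 2 px at the 480 px training shape. Touching instances contribute
  both their boundaries, so adjacent glands are separable. The band is a
  morphological surrogate for a polyline contour; since supervision is a
  binary raster anyway, only the band geometry matters.
* Stroma mask: white pixels are removed by thresholding the ITU-R 601 luma at
  220 (the method gives no value; 220 separates rendered lumina/background
  from eosin-stained stroma comfortably), and the remainder is intersected
  with the inverted gland annotation. Precedence gland > white > stroma makes
  the three classes an exact partition — an invariant asserted per pixel in
  the tests.

Conventions fixed once and used everywhere: 4-connectivity for boundaries,
8-connectivity for components, row-major 0-based rasters.

# The dual-decoder Dense-U-Net

The encoder is the Dense-169 feature extractor: a 7×7 stride-2 stem with a
3×3 stride-2 max-pool (the stem is not spelled out by the architecture name's
users; the standard DenseNet stem is assumed), then four dense blocks of
[6, 12, 32, 32] layers at growth 32, bottleneck 1×1 convolutions at 4× growth,
pre-activation BN-ReLU ordering, and transition layers (1×1 conv at 0.5
compression, average-pool stride 2). Within a block each layer receives the
concatenation of everything before it — a test ablates the concatenation and
checks the parameter count moves, so a silently non-dense encoder cannot pass.

Two independent decoders (no shared weights) undo the five downsamplings:
each stage is bilinear ×2 upsampling, a 3×3 reverse-transition convolution,
concatenation of the equal-resolution encoder output (block 3, block 2,
block 1, stem; the final stage has no skip), and a BN-ReLU-3×3 convolution.
Decoder widths default to [256, 128, 64, 32, 16] coarse-to-fine; the exact
widths are not published, so they are a declared design decision. Each
decoder ends in a 1×1 convolution and a sigmoid, giving an object map and a
contour map in `[0, 1]` at input resolution.

There is no deep-learning framework in the package's dependency stack, so the
network runs on an in-package engine: a static graph with hand-written
backward passes, convolution as im2col + GEMM in compiled code, and Adam.
Finite-difference tests pin the gradients of every op type. He-normal
initialization is the default everywhere; loading externally trained encoder
weights is a hook (`load_encoder_weights()`), not a requirement, and no
weights ship with the package.

# Training

The loss is `alpha * BCE(object) + (1 - alpha) * BCE(contour) + lambda *
||w||^2` with `alpha = 0.5`, `lambda = 1e-4`, BCE clamped at 1e-7, and
`||w||^2` covering convolution kernels only (normalization parameters are not
decayed — the usual convention, unstated in the recipe). Adam runs at
learning rate 1e-3 with momentum decay rates (0.90, 0.99), batch size 4. An
epoch is a fixed count of mini-batches sampled *with replacement* (the
steps-based epoch is taken literally). The learning rate halves after 5
validation epochs without improvement, and the returned checkpoint is the one
with minimum validation loss; the recorded validation loss is the
alpha-weighted BCE without the (slowly varying) weight-decay term.

Augmentation composes flips, rotation (±30°), perspective jitter (±6 % of the
side), and elastic deformation (amplitude 3 % of the side, smoothing 6 %)
into a single backward coordinate map applied identically to the image
(bilinear, white fill) and both masks (nearest neighbour, so they stay
binary); Gaussian noise (sd 5 gray levels) touches the image only. The
transform identity between image and masks is externally checkable through
`apply_augmentation()`. Images are standardized per channel with mean/sd
computed over the training tiles after resizing, applied after augmentation.

The 80/20 train/validation split is stratified on the tile morphology tag,
mirroring a benign/malignant-balanced split, and is a pure function of the
seed.

# Post-processing

Gland route: both maps are thresholded at 0.5 (the "preset" values are never
published; 0.5 is the neutral choice), the binary contour is dilated twice
with the 3×3 cross, the gland mask is multiplied by the complement so touching
glands separate, components are labelled (8-connected), and each label grows
back — restricted to the thresholded gland mask, nearest-seed on collisions,
run to convergence — to recover the boundary pixels the contour removed.
Growth to convergence rather than a fixed dilation count matters because the
removed band is the contour's own thickness plus the dilation depth; the
restriction to the thresholded mask keeps re-dilation from inflating objects
beyond their predicted support. The contour's job is to partition objects,
not delete them: a component the dilated contour swallowed whole keeps a
single label.

Stroma route: the thresholded stroma map is inverted; white pixels (luma
above 220 on the tile) are removed from the candidates so empty background
does not become gland; then the same fusion runs with the stroma-contour map.
Lumina enclosed by epithelium return during hole filling.

Cleaning removes components below `min_area` (default 200 px at 480×480,
scaled with tile area — 14 px at 128×128) and fills enclosed holes;
it is idempotent.

The CRF runs last. It is mean-field inference over a fully connected
two-label CRF with a Gaussian appearance kernel (spatial sd 20 px, color sd
13 levels, weight 10) and a smoothness kernel (sd 3 px, weight 3), five
iterations, kernels truncated at 2.5 spatial sigma (an exact
permutohedral-lattice filter is out of scope; at these sigmas truncation is
negligible). The unary is the network's own gland probability (for the
stroma route, the inverted stroma probability with white suppressed and
recovered lumina filled) — refining the *predictions* rather than an
already-binarized remnant keeps the network's confidence available, which
matters precisely where the binary mask is least reliable. The refined map
is re-binarized at 0.5 and instance labels carry over from the pre-CRF mask
by nearest-seed assignment, followed by a final clean.

# Evaluation

Dice `2|G∩S| / (|G|+|S|)` on whole-tile binary masks, and the Hausdorff
distance between mask boundaries — both the symmetric form (the default) and
the directed form are available, and reports record which was used, always at
native pixel resolution. Hausdorff is computed by looking up an exact
Euclidean distance transform of each boundary; a test pins it to the
all-pairs brute force within 1e-9. When prediction and truth are both empty
the Dice is reported as 1 with an `empty` flag and the Hausdorff as `NA`.

# The synthetic-tissue generator

`generate_tissue()` places non-overlapping deformed ellipses (radial
perturbation by 3–5 cosine harmonics; a benign-like flag keeps amplitudes at
0.08 with a 3 px separation margin, a malignant-like flag allows 0.22 with a
1 px margin), each a hematoxylin-dense epithelial ring around a white lumen
occupying 20 % of the gland's area; stroma is eosin-dense with band-pass,
mildly anisotropic texture; one corner holds a white background blob. RGB is
rendered through the same two-stain OD model the stain module assumes, plus
Gaussian noise (sd 3). Crowded tiles anneal the sampled radius downward
before declaring a placement error. Everything is a pure function of the
seed.

Desk-scale experiments use 128 px tiles with 4 glands of radius 14–28 px —
small enough that the full pipeline (200 training tiles, the reduced
[2, 2, 2, 2]/growth-8 network, 5 epochs of 10 mini-batches) runs in a few
minutes on one CPU, and large enough that every stage is exercised: ring
geometry, touching-gland separation, lumen recovery, white-background
suppression.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: nuclei and subcellular texture, stain variability
beyond the linear two-stain model, scanner artifacts, out-of-focus regions,
and the annotation noise of human experts. The published full-scale results
on real colon and breast datasets require those datasets and GPU-scale
training of the full encoder; the package reproduces the method, and its
synthetic results are a correctness surrogate, not a clinical benchmark.

# Numerical choices and degenerate inputs

* BCE clamp 1e-7; batch-norm epsilon 1e-5, momentum 0.1.
* Dictionary learning: 40 alternations, 12 coding sweeps; collinear bases are
  rejected (`invalid basis`) before per-pixel solves.
* Empty masks: Dice of two empty masks is 1 (flagged); Hausdorff of an empty
  mask is an error; an all-background tile raises `insufficient tissue`
  rather than returning a junk basis.
* Component labelling is BFS in column-major scan order, so labels are
  deterministic; label ties during re-dilation resolve to the smaller label.
* All randomness fans out from one global seed via `derive_seed(seed, key)`,
  keeping every derived seed a valid 32-bit integer.

# Known limitations

* The CRF is O(pixels × window²); at 480 px with the default 20 px sigma a
  tile takes tens of seconds on one CPU.
* Training on the full [6, 12, 32, 32] configuration is possible but not
  practical without GPU hardware; the engine is single-threaded apart from
  BLAS.
* BMP input is not supported (no decoder in the dependency stack); PNG and
  TIFF are.
* Instance masks are written as 16-bit TIFF; 8-bit PNG is available when
  labels fit.
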
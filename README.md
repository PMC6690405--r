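# glandseg

Gland instance segmentation for H&E histopathology tiles, built around a
cross-organ idea: glands look different in every organ, but the stroma
between them does not. The package therefore implements two parallel routes
that share one network and one training recipe —

* **gland route**: segment the glands directly, with a contour decoder to
  separate touching glands;
* **stroma route**: segment the stroma, then recover the glands by inverting
  the stroma under a three-way tissue model (gland / white / stroma).

The full chain is included: structure-preserving stain normalization by
sparse non-negative stain separation in optical-density space
(`OD ≈ C·M`, 2×3 unit-norm basis `M`, non-negative densities `C`);
derivation of the four supervision masks from instance annotations; a
dual-decoder Dense-U-Net (Dense-169 encoder — blocks [6, 12, 32, 32],
growth 32 — with two independent upsampling decoders) trained with
`L = α·BCE(object) + (1−α)·BCE(contour) + λ‖w‖²` (α = 0.5, λ = 1e−4, Adam,
lr 1e−3); contour-fusion / stroma-inversion post-processing with dense-CRF
refinement; and evaluation by Dice coefficient `2|G∩S|/(|G|+|S|)` and
(symmetric or directed) boundary Hausdorff distance.

A seeded synthetic-tissue generator renders H&E-like tiles — epithelial
rings around white lumina, textured stroma, white background — through the
same two-stain color model, so every stage is testable on one CPU without
external data. The network runs on an in-package compute engine
(im2col + GEMM convolutions in compiled code, hand-written backward passes,
Adam); no deep-learning framework is required.

## Worked example

Desk scale (reduced [2, 2, 2, 2]/growth-8 network, 128 px synthetic tiles),
a few minutes on one CPU:

```r
library(glandseg)

cfg <- default_config(seed = 1)     # 200 training tiles, 20 held out
run <- run_pipeline(cfg, approach = "stroma", out_dir = "run_stroma")
run$eval
#> gland segmentation evaluation (20 images)
#>   mean Dice:      1.0000
#>   mean Hausdorff: 0.10 px (symmetric, native resolution)
```

The run directory contains the resolved `config.yaml`, a log, the training
history CSV, the model checkpoint, per-tile predicted instance masks
(16-bit TIFF) and the per-image evaluation report. Mean Dice is the volume
overlap between predicted and true gland masks on the held-out tiles
(1 = perfect); mean Hausdorff is the worst-case boundary deviation in
pixels (0 = boundaries coincide). The gland route on the same seed reaches
mean Dice 0.9993 / Hausdorff 0.64 px, and the two routes' final masks agree
with mutual Dice 0.9994 — the desk-scale analogue of the observation that
both routes segment same-organ tissue comparably well. (Synthetic tiles are
color-separable by construction, so near-perfect scores say the chain is
correct, not that real tissue is this easy; see the vignette.)

Individual stages are ordinary functions:

```r
tile <- generate_tissue(synth_params(tile_size = 128, n_glands = 4,
                                     gland_radius_range = c(14, 28), seed = 7))
tgt   <- stain_target(tile$image)                    # stain reference
norm  <- normalize_image(tile$image, tgt$basis, tgt$scale)
pair  <- derive_targets(norm, tile$mask, "stroma")   # supervision masks
model <- train_model(manifest, "stroma")             # manifest of (image, annotation)
maps  <- predict_maps(model, norm)                   # two probability maps
inst  <- segment_glands(maps, norm, "stroma")        # labelled instances
dice_coefficient(tile$mask > 0, inst > 0)
```

A thin command-line interface wrapping these functions ships in
`inst/cli/glandseg` (commands: `normalize`, `derive-masks`, `synth`,
`train`, `predict`, `postprocess`, `evaluate`, `run`, `build-info`).

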
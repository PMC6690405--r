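# From probability maps to labelled gland instances.
#
# Gland route: threshold both maps, dilate the binarized contour twice
# (3x3 cross), multiply the gland mask by the complement of the dilated
# contour so touching glands separate, label components, then grow each
# labelled object back by the same number of dilations (restricted to the
# thresholded gland mask, nearest-seed on collisions) to recover the
# boundary pixels the contour removed.
#
# Stroma route: threshold the stroma map and invert it; the inverted mask
# indicates gland candidates and is processed the same way with the
# stroma-contour map. White pixels (lumina outside glands, empty
# background) are removed from the inverted mask before labelling, per the
# three-tissue model; lumina inside glands come back during hole filling.
#
# Cleaning drops small components and fills holes; the final optional CRF
# sharpens the binary mask against the image and is re-binarized at 0.5.

#' Post-processing configuration
#'
#' @param t_object,t_contour probability thresholds in (0, 1) (default 0.5).
#' @param dilation_iters contour dilation iterations with the 3x3 cross
#'   (default 2, the "two concurrent dilations").
#' @param min_area minimum component area in pixels (default 200 at
#'   480x480; scale with tile area).
#' @param crf_iters mean-field iterations (default 5).
#' @param crf_appearance appearance kernel: `weight`, spatial `sxy` (px),
#'   color `srgb` (gray levels).
#' @param crf_smoothness smoothness kernel: `weight`, spatial `sxy` (px).
#' @param white_threshold white gray level used by the stroma route.
#' @param use_crf run CRF refinement in [segment_glands()].
#' @return a `postprocess_config` list.
#' @export
postprocess_config <- function(t_object = 0.5, t_contour = 0.5,
                               dilation_iters = 2, min_area = 200,
                               crf_iters = 5,
                               crf_appearance = list(weight = 10, sxy = 20,
                                                     srgb = 13),
                               crf_smoothness = list(weight = 3, sxy = 3),
                               white_threshold = 220, use_crf = TRUE) {
  if (t_object <= 0 || t_object >= 1 || t_contour <= 0 || t_contour >= 1)
    stopf("thresholds must be in (0, 1)")
  if (min_area < 0 || dilation_iters < 0)
    stopf("min_area and dilation_iters must be >= 0")
  structure(list(t_object = t_object, t_contour = t_contour,
                 dilation_iters = as.integer(dilation_iters),
                 min_area = as.integer(min_area),
                 crf_iters = as.integer(crf_iters),
                 crf_appearance = crf_appearance,
                 crf_smoothness = crf_smoothness,
                 white_threshold = white_threshold, use_crf = isTRUE(use_crf)),
            class = "postprocess_config")
}

# Core fusion: separate a binary object mask with a (dilated) contour mask,
# label 8-connected, and grow labels back into the object mask. The contour
# partitions objects, it must not delete them: a connected component of the
# object mask that the dilated contour swallowed whole (so it received no
# label) is restored as a single instance.
fuse_object_contour <- function(obj_bin, contour_prob, cfg) {
  cb <- contour_prob >= cfg$t_contour
  cd <- dilate_cross(cb, cfg$dilation_iters)
  sep <- obj_bin & !cd
  lab <- cc_label8(sep)
  if (cfg$dilation_iters > 0) {
    # Re-dilate the labelled objects to recover the boundary pixels the
    # dilated contour removed. The removed band is the contour's own
    # thickness plus the dilation depth, so growth runs to convergence
    # within the thresholded object mask (nearest-seed on collisions);
    # restricting it to the object mask keeps the re-dilation from
    # inflating objects beyond their predicted support.
    lab <- propagate_labels(lab, obj_bin, max(dim(obj_bin)))
  }
  comp <- cc_label8(obj_bin)
  if (max(comp) > 0) {
    seeded <- unique(comp[lab > 0])
    lost <- setdiff(seq_len(max(comp)), seeded)
    for (k in lost) {
      lab[comp == k] <- max(lab) + 1L
    }
  }
  lab
}

#' Fuse gland and contour probability maps into instances
#'
#' @param maps a `probability_maps` from the gland-approach network.
#' @param cfg a [postprocess_config()].
#' @return integer instance mask.
#' @export
fuse_gland_contour <- function(maps, cfg = postprocess_config()) {
  gb <- maps$object_prob >= cfg$t_object
  fuse_object_contour(gb, maps$contour_prob, cfg)
}

#' Recover gland instances from a stroma probability map
#'
#' Inverts the thresholded stroma mask; the inverted mask indicates gland
#' candidates, processed like the gland route with the stroma-contour map.
#' When `tile` is supplied, white pixels (gray above
#' `cfg$white_threshold`) are removed from the candidates first, so empty
#' background and stray lumina do not become glands; lumina enclosed by
#' epithelium are restored by hole filling in [clean_mask()].
#'
#' @param maps a `probability_maps` from the stroma-approach network
#'   (`object_prob` is the stroma probability).
#' @param cfg a [postprocess_config()].
#' @param tile optional `(H, W, 3)` RGB array for white suppression.
#' @return integer instance mask.
#' @export
gland_from_stroma <- function(maps, cfg = postprocess_config(), tile = NULL) {
  sb <- maps$object_prob >= cfg$t_object
  cand <- !sb
  if (!is.null(tile)) {
    check_same_shape(tile, maps$object_prob, "tile and maps")
    cand <- cand & !(as_gray(tile) > cfg$white_threshold)
  }
  fuse_object_contour(cand, maps$contour_prob, cfg)
}

#' Clean an instance mask
#'
#' Removes components smaller than `min_area`, fills enclosed background
#' holes inside the remaining components, and relabels contiguously from 1.
#' Idempotent.
#'
#' @param inst integer instance mask.
#' @param cfg a [postprocess_config()].
#' @return integer instance mask.
#' @export
clean_mask <- function(inst, cfg = postprocess_config()) {
  if (max(inst) == 0) return(matrix(0L, nrow(inst), ncol(inst)))
  areas <- tabulate(inst[inst > 0], nbins = max(inst))
  keep <- which(areas >= cfg$min_area)
  out <- matrix(0L, nrow(inst), ncol(inst))
  for (j in seq_along(keep)) out[inst == keep[j]] <- j
  if (length(keep) == 0) return(out)
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(out)))
  matrix(as.integer(filled), nrow(inst), ncol(inst))
}

#' Dense-CRF refinement of a probability map
#'
#' Mean-field inference over a fully connected pairwise CRF with a Gaussian
#' appearance kernel (nearby pixels of similar color prefer the same label)
#' and a Gaussian smoothness kernel, unaries taken as the negative log of
#' `{prob, 1 - prob}`. Kernels are truncated at 2.5 spatial sigma.
#'
#' @param tile `(H, W, 3)` RGB array in `[0, 255]`.
#' @param prob foreground probability matrix of the same spatial shape.
#' @param cfg a [postprocess_config()].
#' @return refined probability matrix in `[0, 1]`.
#' @export
crf_refine <- function(tile, prob, cfg = postprocess_config()) {
  check_same_shape(tile, prob, "tile and probability map")
  a <- cfg$crf_appearance; s <- cfg$crf_smoothness
  crf_mean_field(array(as.numeric(tile), dim = dim(tile)), prob,
                 cfg$crf_iters, a$weight, a$sxy, a$srgb, s$weight, s$sxy)
}

# Relabel a binary mask from seed labels: pixels keep the label of the
# nearest seed instance; seedless components get fresh labels.
relabel_from_seeds <- function(bin, seed_lab) {
  seeds <- seed_lab
  seeds[!bin] <- 0L
  lab <- propagate_labels(seeds, bin, iters = max(dim(bin)))
  rest <- bin & lab == 0L
  if (any(rest)) {
    extra <- cc_label8(rest)
    lab[rest] <- extra[rest] + max(lab)
  }
  lab
}

#' Full post-processing chain for one tile
#'
#' Instance fusion for the chosen route, small-component removal and hole
#' filling, then (optionally) CRF refinement run last: the unary comes from
#' the network's gland probability (for the stroma route, the inverted
#' stroma probability with white pixels suppressed), is sharpened against
#' the image, re-binarized at 0.5, and instance labels are carried over
#' from the pre-CRF mask by nearest-seed assignment before a final clean.
#'
#' @param maps a `probability_maps`.
#' @param tile `(H, W, 3)` RGB array (the network input, unnormalized).
#' @param approach `"gland"` or `"stroma"`.
#' @param cfg a [postprocess_config()].
#' @return integer instance mask.
#' @export
segment_glands <- function(maps, tile, approach = c("gland", "stroma"),
                           cfg = postprocess_config()) {
  approach <- match.arg(approach)
  inst <- if (approach == "gland") fuse_gland_contour(maps, cfg)
          else gland_from_stroma(maps, cfg, tile = tile)
  inst <- clean_mask(inst, cfg)
  if (cfg$use_crf && max(inst) > 0) {
    p <- if (approach == "gland") maps$object_prob else 1 - maps$object_prob
    if (approach == "stroma")
      p[as_gray(tile) > cfg$white_threshold & inst == 0] <- 0.02
    # fill lumina already recovered by hole filling so the CRF does not
    # carve the white gland interiors back out
    p[inst > 0] <- pmax(p[inst > 0], 0.95)
    ref <- crf_refine(tile, p, cfg)
    bin <- ref >= 0.5
    inst <- clean_mask(relabel_from_seeds(bin, inst), cfg)
  }
  inst
}
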
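# Supervision-mask derivation from instance annotations.
#
# Both segmentation routes train a dual-decoder network, so every tile needs
# an (object, contour) target pair: gland mask + gland-contour mask for the
# direct route, stroma mask + stroma-contour mask for the inversion route.
# The stroma mask comes from a three-way tissue model (gland / white / stroma)
# since stroma is not simply the complement of the glands: lumina and empty
# background are white, neither gland nor stroma.
#
# Conventions, used everywhere: 4-connectivity defines boundaries (a boundary
# pixel touches a different label, background, or the image frame across an
# edge); 8-connectivity defines connected components; rasters are row-major
# matrices, 0-based pixel centers.

#' Binarize an instance mask
#'
#' @param inst integer matrix; 0 = background, k > 0 = gland instance k.
#' @return integer 0/1 matrix.
#' @export
binarize_gland_mask <- function(inst) {
  m <- matrix(0L, nrow(inst), ncol(inst))
  m[inst > 0] <- 1L
  m
}

#' Extract a contour mask from an instance mask
#'
#' A pixel is marked iff it lies within `thickness` (4-connected dilation
#' steps) of an instance boundary, where a boundary pixel is an instance
#' pixel 4-adjacent to a different label, to background, or to the image
#' frame. Contour pixels of touching instances are both marked, so adjacent
#' glands are separated by their joint contour.
#'
#' @param inst integer instance mask.
#' @param thickness band thickness in pixels (>= 1); 1 marks exactly the
#'   boundary pixels.
#' @return integer 0/1 contour mask.
#' @export
extract_contour_mask <- function(inst, thickness = 2) {
  if (thickness < 1) stopf("invalid parameter: thickness must be >= 1")
  H <- nrow(inst); W <- ncol(inst)
  up <- rbind(inst[-1, , drop = FALSE], 0L)
  dn <- rbind(0L, inst[-H, , drop = FALSE])
  lf <- cbind(inst[, -1, drop = FALSE], 0L)
  rt <- cbind(0L, inst[, -W, drop = FALSE])
  b <- inst > 0 & (inst != up | inst != dn | inst != lf | inst != rt)
  band <- dilate_cross(b, thickness - 1)
  m <- matrix(0L, H, W)
  m[band] <- 1L
  m
}

#' Three-way tissue partition: gland, white, stroma
#'
#' Thresholds the grayscale tile to find white pixels (lumina, empty
#' background), takes the gland pixels from the annotation, and assigns
#' everything else to stroma. The partition is forced disjoint with
#' precedence gland > white > stroma, so annotated gland interiors keep
#' their gland label even where they are white (lumina).
#'
#' @param tile `(H, W, 3)` RGB array in `[0, 255]`.
#' @param inst integer instance mask of the same spatial shape.
#' @param white_threshold gray level above which a pixel is white
#'   (ITU-R 601 luma; default 220).
#' @return a `tissue_partition`: list of logical matrices `gland`, `stroma`,
#'   `white` that are pairwise disjoint and cover every pixel.
#' @export
derive_stroma_mask <- function(tile, inst, white_threshold = 220) {
  if (white_threshold <= 0 || white_threshold >= 255)
    stopf("invalid parameter: white_threshold must be in (0, 255)")
  check_same_shape(tile, inst, "tile and instance mask")
  gray <- as_gray(tile)
  gland <- inst > 0
  white <- (gray > white_threshold) & !gland
  stroma <- !gland & !white
  structure(list(gland = gland, stroma = stroma, white = white),
            class = "tissue_partition")
}

#' Supervision targets for the gland route
#'
#' @param inst integer instance mask.
#' @param thickness contour band thickness in pixels.
#' @return a `target_pair`: list with `object_mask`, `contour_mask`
#'   (integer 0/1 matrices) and `approach = "gland"`.
#' @export
gland_targets <- function(inst, thickness = 2) {
  structure(list(object_mask = binarize_gland_mask(inst),
                 contour_mask = extract_contour_mask(inst, thickness),
                 approach = "gland"),
            class = "target_pair")
}

#' Supervision targets for the stroma route
#'
#' The object mask is the partition's stroma; the contour mask is the
#' boundary band of the stroma region, extracted the same way as gland
#' contours.
#'
#' @param partition a `tissue_partition` from [derive_stroma_mask()].
#' @param thickness contour band thickness in pixels.
#' @return a `target_pair` with `approach = "stroma"`.
#' @export
stroma_targets <- function(partition, thickness = 2) {
  stopifnot(inherits(partition, "tissue_partition"))
  s <- partition$stroma
  obj <- matrix(0L, nrow(s), ncol(s)); obj[s] <- 1L
  structure(list(object_mask = obj,
                 contour_mask = extract_contour_mask(obj, thickness),
                 approach = "stroma"),
            class = "target_pair")
}

#' Derive the target pair for either route
#'
#' @param tile `(H, W, 3)` RGB array (needed for the stroma route).
#' @param inst integer instance mask.
#' @param approach `"gland"` or `"stroma"`.
#' @param thickness contour band thickness.
#' @param white_threshold white gray level for the stroma route.
#' @return a `target_pair`.
#' @export
derive_targets <- function(tile, inst, approach = c("gland", "stroma"),
                           thickness = 2, white_threshold = 220) {
  approach <- match.arg(approach)
  if (approach == "gland") {
    gland_targets(inst, thickness)
  } else {
    stroma_targets(derive_stroma_mask(tile, inst, white_threshold), thickness)
  }
}
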
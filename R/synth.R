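# Seeded synthetic H&E tissue generator.
#
# Emulates the geometry the segmentation pipeline cares about: ring-shaped
# hematoxylin-dense glandular epithelium around white lumina, eosin-dense
# textured stroma filling the space between glands, and at least one white
# background region. Tiles are rendered through the same two-stain OD color
# model the stain module assumes (OD = densities %*% basis), so the
# generator doubles as the oracle for stain separation, mask derivation and
# the end-to-end pipeline. It does not attempt photorealism: no nuclei, no
# scanner artifacts, no out-of-model color variation.

#' Synthetic tissue parameters
#'
#' @param tile_size tile side in pixels (default 480, the training shape).
#' @param n_glands number of glands to place (>= 0).
#' @param gland_radius_range length-2 range of base gland radii, pixels.
#' @param lumen_fraction fraction of each gland's area taken by its white
#'   lumen, in `[0, 1)`.
#' @param epithelium_density hematoxylin density of the epithelial ring.
#' @param stroma_density eosin density of the stroma.
#' @param noise_sd additive Gaussian intensity noise, gray levels.
#' @param stain_basis rendering `stain_basis`.
#' @param morphology `"benign"` (regular, separated rings) or
#'   `"malignant"` (irregular, crowded shapes).
#' @param seed integer seed; generation is fully reproducible per seed.
#' @return a `synth_params` list.
#' @export
synth_params <- function(tile_size = 480, n_glands = 8,
                         gland_radius_range = c(40, 90),
                         lumen_fraction = 0.2,
                         epithelium_density = 1.0, stroma_density = 0.45,
                         noise_sd = 3, stain_basis = default_stain_basis(),
                         morphology = c("benign", "malignant"), seed = 1) {
  morphology <- match.arg(morphology)
  if (n_glands < 0) stopf("n_glands must be >= 0")
  if (any(gland_radius_range < 4)) stopf("gland radii must be >= 4 px")
  if (lumen_fraction < 0 || lumen_fraction >= 1)
    stopf("lumen_fraction must be in [0, 1)")
  if (epithelium_density < 0 || stroma_density < 0)
    stopf("stain densities must be >= 0")
  structure(list(tile_size = tile_size, n_glands = n_glands,
                 gland_radius_range = gland_radius_range,
                 lumen_fraction = lumen_fraction,
                 epithelium_density = epithelium_density,
                 stroma_density = stroma_density, noise_sd = noise_sd,
                 stain_basis = stain_basis, morphology = morphology,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# Smooth (band-pass) noise field used for stroma texture; mildly
# anisotropic via different smoothing scales along the two axes.
texture_field <- function(H, W, sigma_lo, sigma_hi) {
  z <- matrix(stats::rnorm(H * W), H, W)
  flip <- stats::runif(1) < 0.5   # random orientation of the anisotropy
  k1 <- gauss_kernel_1d(sigma_lo)
  k2 <- gauss_kernel_1d(sigma_hi)
  if (flip) { tmp <- k1; k1 <- k2; k2 <- tmp }
  z <- sep_smooth(z, k1, k2)
  z <- z - sep_smooth(z, gauss_kernel_1d(3 * sigma_hi), gauss_kernel_1d(3 * sigma_hi))
  z / max(stats::sd(z), 1e-8)
}

gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-0.5 * ((-r):r)^2 / sigma^2)
  k / sum(k)
}

# Separable row/column smoothing with reflective padding.
sep_smooth <- function(z, krow, kcol) {
  smooth1 <- function(m, k, along_rows) {
    r <- (length(k) - 1L) / 2L
    n <- if (along_rows) nrow(m) else ncol(m)
    idx <- pmin(pmax(outer(seq_len(n), (-r):r, `+`), 1L), n)
    if (along_rows) {
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
      out
    } else {
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_along(k)) out <- out + k[j] * m[, idx[, j], drop = FALSE]
      out
    }
  }
  smooth1(smooth1(z, krow, TRUE), kcol, FALSE)
}

# Rasterize one deformed-ellipse gland; returns logical masks for the whole
# gland and its lumen within the tile frame.
rasterize_gland <- function(H, W, cy, cx, r0, aspect, theta0, harm, lumen_scale) {
  rmax <- r0 * (1 + sum(abs(harm$amp))) * max(aspect, 1 / aspect) + 2
  y0 <- max(1, floor(cy - rmax)); y1 <- min(H, ceiling(cy + rmax))
  x0 <- max(1, floor(cx - rmax)); x1 <- min(W, ceiling(cx + rmax))
  if (y1 < y0 || x1 < x0) return(NULL)
  yy <- outer(y0:y1 - cy, rep(1, x1 - x0 + 1))
  xx <- outer(rep(1, y1 - y0 + 1), x0:x1 - cx)
  # rotate and stretch into the ellipse frame
  u <- cos(theta0) * xx + sin(theta0) * yy
  v <- (-sin(theta0) * xx + cos(theta0) * yy) / aspect
  rad <- sqrt(u^2 + v^2)
  ang <- atan2(v, u)
  rb <- r0 * (1 + Reduce(`+`, Map(function(a, m, p) a * cos(m * ang + p),
                                  harm$amp, harm$m, harm$phase)))
  rb <- pmax(rb, 0.3 * r0)
  inside <- rad <= rb
  lumen <- rad <= lumen_scale * rb
  list(y = y0:y1, x = x0:x1, inside = inside, lumen = lumen)
}

#' Generate one synthetic H&E tile with ground truth
#'
#' Places non-overlapping deformed-ellipse glands (hematoxylin-dense
#' epithelial ring around a white lumen), fills the remaining tissue with
#' textured eosin-dense stroma, reserves at least one white background
#' region, and renders RGB through `OD = densities %*% stain_basis` plus
#' Gaussian noise.
#'
#' @param params a [synth_params()] object.
#' @return list with `image` (`(H, W, 3)` array in `[0, 255]`), `mask`
#'   (integer instance matrix labelling glands 1..n), `partition` (the
#'   generator's own `tissue_partition`: gland / stroma / white), and
#'   `params`.
#' @export
generate_tissue <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  H <- W <- p$tile_size
  with_seed(p$seed, {
    mask <- matrix(0L, H, W)
    lumen <- matrix(FALSE, H, W)
    # white background region hugging a randomly chosen corner
    corner <- sample(4, 1)
    wy <- if (corner %in% c(1, 2)) 1 else H
    wx <- if (corner %in% c(1, 3)) 1 else W
    wr <- stats::runif(1, 0.18, 0.28) * p$tile_size
    yy <- outer(seq_len(H) - wy, rep(1, W))
    xx <- outer(rep(1, H), seq_len(W) - wx)
    white_bg <- (yy / (1.4 * wr))^2 + (xx / wr)^2 <= 1
    irregular <- p$morphology == "malignant"
    margin_px <- if (irregular) 1L else 3L
    amp_hi <- if (irregular) 0.22 else 0.08
    # occupied = already-placed glands dilated by the separation margin
    occupied <- white_bg
    if (p$n_glands > 0) {
      for (i in seq_len(p$n_glands)) {
        ok <- FALSE
        for (try in seq_len(600)) {
          # progressively favour smaller glands when the tile gets crowded
          shrink <- max(0.4, 1 - 0.1 * (try %/% 60))
          r0 <- stats::runif(1, p$gland_radius_range[1],
                             max(p$gland_radius_range[1],
                                 p$gland_radius_range[2] * shrink))
          cy <- stats::runif(1, 1 + 0.7 * r0, H - 0.7 * r0)
          cx <- stats::runif(1, 1 + 0.7 * r0, W - 0.7 * r0)
          nh <- sample(3:5, 1)
          harm <- list(m = sample(2:6, nh), amp = stats::runif(nh, 0, amp_hi),
                       phase = stats::runif(nh, 0, 2 * pi))
          g <- rasterize_gland(H, W, cy, cx, r0,
                               aspect = stats::runif(1, 0.6, 1),
                               theta0 = stats::runif(1, 0, pi), harm = harm,
                               lumen_scale = sqrt(p$lumen_fraction))
          if (is.null(g) || !any(g$inside)) next
          if (any(g$inside & occupied[g$y, g$x])) next
          sub <- mask[g$y, g$x]
          sub[g$inside] <- i
          mask[g$y, g$x] <- sub
          lsub <- lumen[g$y, g$x]; lsub[g$lumen] <- TRUE
          lumen[g$y, g$x] <- lsub
          occupied <- occupied | dilate_cross(mask > 0, margin_px)
          ok <- TRUE
          break
        }
        if (!ok)
          stopf("placement error: could not place gland %d of %d without overlap",
                i, p$n_glands)
      }
    }
    gland <- mask > 0
    white <- white_bg & !gland
    stroma <- !gland & !white
    ring <- gland & !lumen
    # stain density channels
    Ch <- matrix(0.02, H, W)
    Ce <- matrix(0.02, H, W)
    ring_mod <- 1 + 0.15 * sep_smooth(matrix(stats::rnorm(H * W), H, W),
                                      gauss_kernel_1d(2), gauss_kernel_1d(2))
    Ch[ring] <- p$epithelium_density * pmax(ring_mod[ring], 0.5)
    Ce[ring] <- 0.25 * p$epithelium_density
    tex <- texture_field(H, W, sigma_lo = 1.2, sigma_hi = 4)
    Ce[stroma] <- pmax(p$stroma_density * (1 + 0.35 * tex[stroma]),
                       0.3 * p$stroma_density)
    Ch[stroma] <- 0.12
    M <- unclass(p$stain_basis)
    od <- array(cbind(as.numeric(Ch), as.numeric(Ce)) %*% M, dim = c(H, W, 3))
    img <- 255 * 10^(-od)
    if (p$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, p$noise_sd), dim = dim(img))
    img <- round(pmin(pmax(img, 0), 255))
    list(image = img, mask = mask,
         partition = structure(list(gland = gland, stroma = stroma, white = white),
                               class = "tissue_partition"),
         params = p)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_tiles` (image, mask) pairs with per-tile seeds `seed + i` and a
#' manifest CSV listing paths, gland counts and morphology tags.
#'
#' @param params a [synth_params()] object (its `seed` is the base seed).
#' @param n_tiles number of tiles (>= 1).
#' @param out_dir output directory (created if needed).
#' @param morphology_mix fraction of tiles generated with the malignant-like
#'   morphology flag (default 0.5, balancing the two classes).
#' @return the manifest `data.frame` (columns `image`, `annotation`,
#'   `n_glands`, `morphology`), invisibly; also written as
#'   `manifest.csv` in `out_dir`.
#' @export
generate_dataset <- function(params, n_tiles, out_dir, morphology_mix = 0.5) {
  stopifnot(inherits(params, "synth_params"), n_tiles >= 1)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("I/O error: cannot create %s", out_dir)
  rows <- vector("list", n_tiles)
  for (i in seq_len(n_tiles)) {
    p_i <- params
    p_i$seed <- params$seed + i
    p_i$morphology <- if ((i %% round(1 / max(morphology_mix, 1e-9))) == 0)
      "malignant" else "benign"
    tile <- generate_tissue(p_i)
    img_path <- file.path(out_dir, sprintf("tile_%04d.png", i))
    msk_path <- file.path(out_dir, sprintf("tile_%04d_mask.tif", i))
    write_image(tile$image, img_path)
    write_mask(tile$mask, msk_path)
    rows[[i]] <- data.frame(image = img_path, annotation = msk_path,
                            n_glands = max(tile$mask), morphology = p_i$morphology,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
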
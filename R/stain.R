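# Structure-preserving stain normalization by sparse non-negative stain
# separation in optical-density space.
#
# An H&E tile is modelled in optical density as OD ~ C %*% M where M is a
# 2 x 3 non-negative stain color basis (hematoxylin row first, eosin row
# second, each of unit Euclidean norm) and C holds per-pixel non-negative
# stain densities. Normalization recombines a source tile's densities with
# the basis (and density scale) of a reference target tile, recoloring the
# image while leaving its structure untouched.

#' Convert an RGB tile to optical density
#'
#' `od = -log10((v + eps) / background)`, channelwise. Stain contributions
#' are approximately additive in OD space, which is what makes the linear
#' two-stain model workable.
#'
#' @param tile `(H, W, 3)` array in `[0, background_intensity]`.
#' @param background_intensity transmitted-light white level (default 255).
#' @param eps small positive clamp so zero pixels stay finite (default 1).
#' @return `(H, W, 3)` array of optical densities (>= 0).
#' @export
rgb_to_od <- function(tile, background_intensity = 255, eps = 1) {
  if (background_intensity <= 0)
    stopf("invalid parameter: background_intensity must be > 0")
  od <- -log10((tile + eps) / (background_intensity + eps))
  pmax(od, 0)
}

#' Convert optical density back to RGB
#'
#' Inverse of [rgb_to_od()] up to rounding.
#'
#' @param od `(H, W, 3)` array of optical densities.
#' @inheritParams rgb_to_od
#' @return `(H, W, 3)` array in `[0, background_intensity]`.
#' @export
od_to_rgb <- function(od, background_intensity = 255, eps = 1) {
  v <- (background_intensity + eps) * 10^(-od) - eps
  pmin(pmax(v, 0), background_intensity)
}

#' Construct a stain color basis
#'
#' @param m 2 x 3 non-negative matrix; rows are renormalized to unit norm
#'   and ordered hematoxylin-first (larger blue-channel OD component).
#' @param source_id identifier of the image the basis came from.
#' @return a `stain_basis` (2 x 3 matrix with attributes).
#' @export
stain_basis <- function(m, source_id = NA_character_) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2, 3))) stopf("stain basis must be 2 x 3")
  if (any(m < 0)) stopf("stain basis entries must be >= 0")
  n <- sqrt(rowSums(m^2))
  if (any(n < 1e-12)) stopf("degenerate stain basis row")
  m <- m / n
  if (m[2, 3] > m[1, 3]) m <- m[2:1, , drop = FALSE]  # hematoxylin-first
  rownames(m) <- c("hematoxylin", "eosin")
  colnames(m) <- c("R", "G", "B")
  structure(m, class = c("stain_basis", "matrix"), source_id = source_id)
}

#' Reference H&E stain basis
#'
#' The classical hematoxylin/eosin OD color vectors, unit-normalized; used
#' as the default rendering basis of the synthetic-tissue generator and as
#' a sane fallback target.
#'
#' @return a `stain_basis`.
#' @export
default_stain_basis <- function() {
  stain_basis(rbind(c(0.651, 0.701, 0.290),
                    c(0.072, 0.990, 0.105)),
              source_id = "reference")
}

# Sparse non-negative coding of OD pixels against a fixed 2-row basis.
# X: n x 3 OD pixels; M: 2 x 3 basis. Exact active-set solution of the
# per-pixel problem min ||x - c %*% M||^2 + lambda * sum(c), c >= 0:
# with two variables the solution is either the interior stationary point
# or lies on one of the axes, so all three candidates can be evaluated in
# closed form.
sparse_code <- function(X, M, lambda = 0) {
  G <- M %*% t(M)                    # 2 x 2 Gram
  if (abs(det(G)) < 1e-10) stopf("invalid basis: stain vectors are collinear")
  B <- X %*% t(M) - lambda / 2       # n x 2 (shifted by the L1 subgradient)
  dt <- G[1, 1] * G[2, 2] - G[1, 2]^2
  # interior solution of the 2x2 normal equations
  i1 <- (G[2, 2] * B[, 1] - G[1, 2] * B[, 2]) / dt
  i2 <- (G[1, 1] * B[, 2] - G[1, 2] * B[, 1]) / dt
  # axis solutions
  a1 <- pmax(B[, 1] / G[1, 1], 0)
  a2 <- pmax(B[, 2] / G[2, 2], 0)
  use_int <- i1 >= 0 & i2 >= 0
  # objective (up to the constant ||x||^2): 0.5 c'Gc - B'c evaluated cheaply
  obj <- function(c1, c2)
    0.5 * (G[1, 1] * c1^2 + 2 * G[1, 2] * c1 * c2 + G[2, 2] * c2^2) -
      (B[, 1] * c1 + B[, 2] * c2)
  pick2 <- obj(a1, 0) <= obj(0, a2)
  c1 <- ifelse(use_int, i1, ifelse(pick2, a1, 0))
  c2 <- ifelse(use_int, i2, ifelse(pick2, 0, a2))
  cbind(c1, c2)
}

#' Estimate the stain color basis of a tile
#'
#' Unsupervised decomposition of the tissue-pixel OD cloud into two sparse,
#' non-negative stain density components: seeded dictionary learning with
#' two atoms, alternating sparse non-negative coding of densities with
#' multiplicative non-negative updates of the basis. Near-white pixels
#' (OD norm below `tissue_threshold`) are excluded from the fit.
#'
#' @param od `(H, W, 3)` OD array (from [rgb_to_od()]).
#' @param sparsity_weight L1 penalty on densities (default 0.1).
#' @param seed integer seed (pixel subsampling); same seed, same basis.
#' @param tissue_threshold minimum OD norm for a pixel to count as tissue.
#' @param max_pixels subsample cap for the fit.
#' @param max_iter alternating iterations.
#' @param min_tissue minimum number of tissue pixels required.
#' @param source_id identifier recorded on the basis.
#' @return a `stain_basis`.
#' @export
estimate_stain_basis <- function(od, sparsity_weight = 0.1, seed = 1,
                                 tissue_threshold = 0.15, max_pixels = 3000,
                                 max_iter = 40, min_tissue = 100,
                                 source_id = NA_character_) {
  X <- matrix(od, ncol = 3)
  keep <- sqrt(rowSums(X^2)) >= tissue_threshold
  if (sum(keep) < min_tissue)
    stopf("insufficient tissue: %d pixels above OD %.2f (need >= %d)",
          sum(keep), tissue_threshold, min_tissue)
  X <- X[keep, , drop = FALSE]
  with_seed(seed, {
    if (nrow(X) > max_pixels)
      X <- X[sample.int(nrow(X), max_pixels), , drop = FALSE]
    # Init: principal plane of the OD cloud, extreme-angle directions
    # (Macenko-style), projected to the non-negative orthant.
    sv <- svd(X, nu = 0, nv = 2)
    P <- X %*% sv$v
    if (mean(P[, 1]) < 0) { sv$v[, 1] <- -sv$v[, 1]; P[, 1] <- -P[, 1] }
    ang <- atan2(P[, 2], P[, 1])
    qa <- stats::quantile(ang, c(0.01, 0.99), names = FALSE)
    M <- rbind(cos(qa[1]) * sv$v[, 1] + sin(qa[1]) * sv$v[, 2],
               cos(qa[2]) * sv$v[, 1] + sin(qa[2]) * sv$v[, 2])
    M <- pmax(M, 1e-4)
    M <- M / sqrt(rowSums(M^2))
    # A one-stain image collapses both atoms onto one direction; nudge the
    # second row off the first (deterministically) so coding stays defined.
    decollinear <- function(M) {
      if (abs(det(M %*% t(M))) >= 1e-6) return(M)
      ortho <- M[2, ] - sum(M[2, ] * M[1, ]) * M[1, ]
      if (sqrt(sum(ortho^2)) < 1e-6) {
        ref <- if (abs(M[1, 2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
        ortho <- ref - sum(ref * M[1, ]) * M[1, ]
      }
      ortho <- ortho / sqrt(sum(ortho^2))
      M[2, ] <- pmax(0.98 * M[1, ] + 0.2 * ortho, 1e-6)
      M[2, ] <- M[2, ] / sqrt(sum(M[2, ]^2))
      M
    }
    M <- decollinear(M)
    for (it in seq_len(max_iter)) {
      C <- sparse_code(X, M, lambda = sparsity_weight)
      # multiplicative non-negative update of the basis
      num <- t(C) %*% X
      den <- (t(C) %*% C) %*% M
      upd <- num / pmax(den, 1e-12)
      upd[!is.finite(upd)] <- 1
      M <- M * upd
      M <- pmax(M, 1e-12)
      M <- M / sqrt(rowSums(M^2))
      M <- decollinear(M)
    }
    # Polish: the multiplicative updates carry a shrinkage bias toward the
    # data mean, so refit each atom as the leading singular direction of
    # the pixels it dominates (k-lines refinement; deterministic).
    for (it in seq_len(5)) {
      C <- sparse_code(X, M, lambda = 0)
      for (k in 1:2) {
        dom <- C[, k] > 2 * C[, 3 - k] & C[, k] > 0.1
        if (sum(dom) > 30) {
          v <- svd(X[dom, , drop = FALSE], nu = 0, nv = 1)$v[, 1]
          if (sum(v) < 0) v <- -v
          M[k, ] <- pmax(v, 1e-6)
          M[k, ] <- M[k, ] / sqrt(sum(M[k, ]^2))
        }
      }
      M <- decollinear(M)
    }
  })
  stain_basis(M, source_id = source_id)
}

#' Per-pixel stain densities for a fixed basis
#'
#' Non-negative (optionally sparsity-regularized) least-squares solution of
#' `od ~ densities %*% basis`, pixelwise.
#'
#' @param od `(H, W, 3)` OD array.
#' @param basis a `stain_basis`.
#' @param sparsity_weight L1 penalty (default 0: plain NNLS).
#' @return `(H, W, 2)` array of non-negative densities
#'   (hematoxylin, eosin).
#' @export
compute_densities <- function(od, basis, sparsity_weight = 0) {
  d <- dim(od)
  C <- sparse_code(matrix(od, ncol = 3), unclass(basis), lambda = sparsity_weight)
  array(C, dim = c(d[1], d[2], 2))
}

#' Robust per-stain density scale of a tile
#'
#' The 99th percentile of each stain's density over the tile; used to align
#' stain intensity between source and target during normalization.
#'
#' @param densities `(H, W, 2)` density array.
#' @return length-2 numeric vector.
#' @export
stain_density_scale <- function(densities) {
  apply(matrix(densities, ncol = 2), 2, stats::quantile, probs = 0.99, names = FALSE)
}

#' Fit the stain reference of a target tile
#'
#' Convenience wrapper returning the target's basis and robust density
#' scale, the two quantities [normalize_image()] needs.
#'
#' @param tile `(H, W, 3)` RGB array in `[0, 255]`.
#' @param seed integer seed.
#' @param ... passed to [estimate_stain_basis()].
#' @return list with elements `basis` and `scale`.
#' @export
stain_target <- function(tile, seed = 1, ...) {
  od <- rgb_to_od(tile)
  basis <- estimate_stain_basis(od, seed = seed, ...)
  dens <- compute_densities(od, basis)
  list(basis = basis, scale = stain_density_scale(dens))
}

#' Normalize a tile to a target stain appearance
#'
#' Decomposes the source tile into its own densities and basis, rescales
#' each stain's density so its 99th percentile matches
#' `target_density_scale`, and recombines with the target basis. Only colors
#' change; the spatial structure (and any annotation raster) is untouched.
#'
#' @param source `(H, W, 3)` RGB array in `[0, 255]`.
#' @param target_basis a `stain_basis` estimated from the reference tile.
#' @param target_density_scale length-2 density scale of the reference tile
#'   (from [stain_density_scale()]); `NULL` keeps the source scale.
#' @param seed integer seed for the source basis fit.
#' @param ... passed to [estimate_stain_basis()].
#' @return normalized `(H, W, 3)` RGB array in `[0, 255]`.
#' @export
normalize_image <- function(source, target_basis, target_density_scale = NULL,
                            seed = 1, ...) {
  od <- rgb_to_od(source)
  src_basis <- estimate_stain_basis(od, seed = seed, ...)
  dens <- compute_densities(od, src_basis)
  if (!is.null(target_density_scale)) {
    src_scale <- stain_density_scale(dens)
    sc <- target_density_scale / pmax(src_scale, 1e-8)
    dens[, , 1] <- dens[, , 1] * sc[1]
    dens[, , 2] <- dens[, , 2] * sc[2]
  }
  d <- dim(source)
  od_new <- array(matrix(dens, ncol = 2) %*% unclass(target_basis),
                  dim = c(d[1], d[2], 3))
  round(od_to_rgb(od_new))
}
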
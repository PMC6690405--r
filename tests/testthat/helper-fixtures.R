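# Shared fixtures, built in code and cached per test run.

# A small synthetic tile with ground truth, reused across modules.
fixture_tile <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_tissue(synth_params(
        tile_size = 128, n_glands = 4, gland_radius_range = c(14, 28),
        seed = 7))
    cache
  }
})

tiny_cfg <- function(size = 64)
  model_config(block_layers = c(1, 1, 1, 1), growth_rate = 4,
               input_size = size, decoder_channels = c(8, 8, 8, 8, 4),
               init_channels = 8)

# Brute-force metric oracles (independent of the package implementations).
dice_brute <- function(g, s) {
  gi <- which(g != 0); si <- which(s != 0)
  if (length(gi) + length(si) == 0) return(1)
  2 * length(intersect(gi, si)) / (length(gi) + length(si))
}

boundary_brute <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!m[i, j]) next
    nb <- c(if (i > 1) m[i - 1, j] else FALSE,
            if (i < H) m[i + 1, j] else FALSE,
            if (j > 1) m[i, j - 1] else FALSE,
            if (j < W) m[i, j + 1] else FALSE)
    edge <- i == 1 || i == H || j == 1 || j == W
    out[i, j] <- edge || !all(nb)
  }
  out
}

hausdorff_brute <- function(g, s, mode = "symmetric") {
  bg <- which(boundary_brute(g != 0), arr.ind = TRUE)
  bs <- which(boundary_brute(s != 0), arr.ind = TRUE)
  dmat <- function(a, b) {
    outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
      sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2))
  }
  d_sg <- max(apply(dmat(bs, bg), 1, min))  # sup over S of inf over G
  if (mode == "directed") return(d_sg)
  d_gs <- max(apply(dmat(bg, bs), 1, min))
  max(d_sg, d_gs)
}

# Two blobs bridged by high probability, with a contour line across the
# bridge; contour fusion must cut the bridge into two instances.
two_blob_maps <- function() {
  obj <- matrix(0, 20, 20)
  obj[6:15, 3:9] <- 0.9    # left blob
  obj[6:15, 12:18] <- 0.9  # right blob
  obj[9:12, 10:11] <- 0.9  # bridge
  cnt <- matrix(0, 20, 20)
  cnt[6:15, 10:11] <- 0.9  # contour across the bridge
  structure(list(object_prob = obj, contour_prob = cnt),
            class = "probability_maps")
}

# Random binary masks guaranteed nonempty.
random_mask <- function(H, W, p = 0.3) {
  repeat {
    m <- matrix(stats::runif(H * W) < p, H, W)
    if (sum(m) > 0) return(m)
  }
}
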
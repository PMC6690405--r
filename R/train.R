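# Joint training of the dual-decoder network.
#
# The loss is alpha * BCE(object) + (1 - alpha) * BCE(contour) +
# lambda * ||w||^2, optimized with Adam. Images and both target masks are
# augmented simultaneously on the fly (flips, rotation, elastic and
# perspective warps share one coordinate map; Gaussian noise touches the
# image only), then standardized with per-channel mean/sd computed over the
# training images. An epoch is a fixed number of mini-batches sampled with
# replacement; the learning rate halves when the validation loss fails to
# improve for `plateau_patience` epochs, and the checkpoint with minimum
# validation loss is returned.

BCE_CLAMP <- 1e-7

#' Loss configuration
#'
#' @param alpha weight of the object term in `[0, 1]` (default 0.5,
#'   the cross-validated value).
#' @param weight_decay L2 coefficient lambda on convolution kernels
#'   (default 1e-4).
#' @return a `loss_config` list.
#' @export
loss_config <- function(alpha = 0.5, weight_decay = 1e-4) {
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  if (weight_decay < 0) stopf("weight_decay must be >= 0")
  structure(list(alpha = alpha, weight_decay = weight_decay),
            class = "loss_config")
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 1e-3 and momentum decay rates (0.90, 0.99), batch size 4, 40 epochs of
#' 200 mini-batches, learning rate halved after 5 non-improving validation
#' epochs, 80/20 train/validation split.
#'
#' @param lr initial learning rate.
#' @param betas Adam first/second momentum decay rates.
#' @param batch_size mini-batch size.
#' @param epochs number of epochs.
#' @param steps_per_epoch mini-batches per epoch (sampled with replacement).
#' @param plateau_patience epochs without validation improvement before the
#'   learning rate is multiplied by `lr_factor`.
#' @param lr_factor learning-rate reduction factor.
#' @param val_fraction validation fraction of the dataset.
#' @param seed integer seed controlling split, initialization, sampling and
#'   augmentation.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, betas = c(0.90, 0.99), batch_size = 4,
                         epochs = 40, steps_per_epoch = 200,
                         plateau_patience = 5, lr_factor = 0.5,
                         val_fraction = 0.2, seed = 1) {
  structure(list(lr = lr, betas = betas, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 plateau_patience = as.integer(plateau_patience),
                 lr_factor = lr_factor, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

bce_mean <- function(p, t) {
  p <- pmin(pmax(as.numeric(p), BCE_CLAMP), 1 - BCE_CLAMP)
  t <- as.numeric(t)
  stopifnot(length(p) == length(t))
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

#' Combined segmentation loss
#'
#' `alpha * BCE(object) + (1 - alpha) * BCE(contour) + lambda * weights_norm`
#' where BCE is the mean pixelwise binary cross-entropy of the sigmoid
#' outputs against the binary targets.
#'
#' @param pred a `probability_maps` (or list with `object_prob`,
#'   `contour_prob`).
#' @param target a `target_pair` (or list with `object_mask`,
#'   `contour_mask`).
#' @param weights_norm the network's `||w||^2` (default 0).
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
combined_loss <- function(pred, target, weights_norm = 0, cfg = loss_config()) {
  if (weights_norm < 0) stopf("weights_norm must be >= 0")
  check_same_shape(pred$object_prob, target$object_mask, "prediction and target")
  cfg$alpha * bce_mean(pred$object_prob, target$object_mask) +
    (1 - cfg$alpha) * bce_mean(pred$contour_prob, target$contour_mask) +
    cfg$weight_decay * weights_norm
}

# --- plateau learning-rate scheduler -------------------------------------

#' Reduce-on-plateau scheduler state
#'
#' @param lr initial learning rate.
#' @param patience non-improving epochs tolerated before reduction.
#' @param factor multiplicative reduction factor.
#' @return a `plateau_state` list.
#' @export
plateau_state <- function(lr, patience = 5, factor = 0.5) {
  structure(list(lr = lr, patience = as.integer(patience), factor = factor,
                 best = Inf, wait = 0L, n_reductions = 0L),
            class = "plateau_state")
}

#' Advance the plateau scheduler by one validation epoch
#'
#' The learning rate is multiplied by `factor` when `patience` consecutive
#' epochs fail to improve on the best validation loss seen so far.
#'
#' @param state a [plateau_state()].
#' @param val_loss this epoch's validation loss.
#' @return updated `plateau_state` (fields `lr`, `best`, `wait`,
#'   `n_reductions`).
#' @export
plateau_update <- function(state, val_loss) {
  if (val_loss < state$best - 1e-12) {
    state$best <- val_loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- state$lr * state$factor
      state$n_reductions <- state$n_reductions + 1L
      state$wait <- 0L
    }
  }
  state
}

# --- augmentation ---------------------------------------------------------

# Homography mapping the four 0-based points src (4x2, row col) onto dst.
solve_homography <- function(src, dst) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 2]; y <- src[i, 1]; u <- dst[i, 2]; v <- dst[i, 1]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

# Draw a random augmentation description. Each component fires with
# probability 1/2; `transforms` overrides individual components for
# deterministic use (absent components are off).
draw_augmentation <- function(H, W, noise_sd = 5, transforms = NULL) {
  if (!is.null(transforms)) {
    d <- list(hflip = isTRUE(transforms$hflip), vflip = isTRUE(transforms$vflip),
              angle = transforms$angle, perspective = transforms$perspective,
              elastic = transforms$elastic,
              noise = if (is.null(transforms$noise)) 0 else transforms$noise)
    return(d)
  }
  list(
    hflip = stats::runif(1) < 0.5,
    vflip = stats::runif(1) < 0.5,
    angle = if (stats::runif(1) < 0.5) stats::runif(1, -30, 30) else NULL,
    perspective = if (stats::runif(1) < 0.5)
      matrix(stats::runif(8, -0.06, 0.06) * max(H, W), 4, 2) else NULL,
    elastic = if (stats::runif(1) < 0.5)
      list(alpha = 0.03 * max(H, W), sigma = 0.06 * max(H, W),
           fr = matrix(stats::runif(H * W, -1, 1), H, W),
           fc = matrix(stats::runif(H * W, -1, 1), H, W)) else NULL,
    noise = if (stats::runif(1) < 0.5) noise_sd else 0)
}

# Compose the backward coordinate map of a drawn augmentation.
# Returns NULL when the draw is purely the identity (so callers can skip
# resampling entirely).
augmentation_map <- function(draw, H, W) {
  if (!draw$hflip && !draw$vflip && is.null(draw$angle) &&
      is.null(draw$perspective) && is.null(draw$elastic)) return(NULL)
  mr <- matrix(rep(0:(H - 1), W), H, W)
  mc <- matrix(rep(0:(W - 1), each = H), H, W)
  # inverses applied in reverse order of the forward composition
  if (!is.null(draw$elastic)) {
    e <- draw$elastic
    k <- gauss_kernel_1d(e$sigma)
    dr <- sep_smooth(e$fr, k, k); dr <- dr / max(abs(dr)) * e$alpha
    dc <- sep_smooth(e$fc, k, k); dc <- dc / max(abs(dc)) * e$alpha
    mr <- mr + dr; mc <- mc + dc
  }
  if (!is.null(draw$perspective)) {
    corners <- matrix(c(0, 0, 0, W - 1, H - 1, 0, H - 1, W - 1), 4, 2, byrow = TRUE)
    Hm <- solve_homography(corners, corners + draw$perspective)
    w <- Hm[3, 1] * mc + Hm[3, 2] * mr + Hm[3, 3]
    u <- (Hm[1, 1] * mc + Hm[1, 2] * mr + Hm[1, 3]) / w
    v <- (Hm[2, 1] * mc + Hm[2, 2] * mr + Hm[2, 3]) / w
    mc <- u; mr <- v
  }
  if (!is.null(draw$angle)) {
    th <- -draw$angle * pi / 180
    cy <- (H - 1) / 2; cx <- (W - 1) / 2
    r0 <- mr - cy; c0 <- mc - cx
    mr <- cy + sin(th) * c0 + cos(th) * r0
    mc <- cx + cos(th) * c0 - sin(th) * r0
  }
  if (draw$vflip) mr <- (H - 1) - mr
  if (draw$hflip) mc <- (W - 1) - mc
  list(mr = mr, mc = mc)
}

#' Apply a drawn augmentation's spatial transform to a raster
#'
#' Exposed so that the identity of the spatial transform across image and
#' masks can be verified externally; [augment_pair()] uses exactly this for
#' both.
#'
#' @param draw an augmentation description (the `draw` attribute of an
#'   [augment_pair()] result).
#' @param raster `(H, W)` matrix or `(H, W, C)` array.
#' @param interp `"bilinear"` (images) or `"nearest"` (masks).
#' @param fill out-of-frame fill value.
#' @return transformed raster of the same shape.
#' @export
apply_augmentation <- function(draw, raster, interp = c("bilinear", "nearest"),
                               fill = 0) {
  interp <- match.arg(interp)
  d <- dim(raster)
  m <- augmentation_map(draw, d[1], d[2])
  if (is.null(m)) return(raster)
  out <- warp_image(array(raster, dim = c(d[1], d[2], if (length(d) > 2) d[3] else 1)),
                    m$mr, m$mc, if (interp == "bilinear") 1L else 0L, fill)
  if (length(d) == 2) dim(out) <- d else dim(out) <- d
  out
}

#' Augment an image and its target pair simultaneously
#'
#' Randomly composes horizontal/vertical flips, rotation, perspective and
#' elastic warps into one coordinate map applied identically to the image
#' (bilinear, white fill) and both masks (nearest neighbour, so they stay
#' binary); Gaussian noise is added to the image only.
#'
#' @param tile `(H, W, 3)` RGB array in `[0, 255]`.
#' @param target a `target_pair`.
#' @param seed optional integer seed; `NULL` draws from the current RNG.
#' @param noise_sd Gaussian noise standard deviation in gray levels.
#' @param transforms optional override list (`hflip`, `vflip`, `angle`,
#'   `perspective`, `elastic`, `noise`); components not listed are off.
#'   An empty list forces the identity.
#' @return list(`tile`, `target`) with attribute `draw` recording the
#'   sampled transform.
#' @export
augment_pair <- function(tile, target, seed = NULL, noise_sd = 5,
                         transforms = NULL) {
  check_same_shape(tile, target$object_mask, "tile and target")
  H <- dim(tile)[1]; W <- dim(tile)[2]
  run <- function() {
    draw <- draw_augmentation(H, W, noise_sd, transforms)
    img <- apply_augmentation(draw, tile, "bilinear", fill = 255)
    as_int <- function(m) matrix(as.integer(round(m)), nrow(m), ncol(m))
    obj <- as_int(apply_augmentation(draw, target$object_mask, "nearest", fill = 0))
    cnt <- as_int(apply_augmentation(draw, target$contour_mask, "nearest", fill = 0))
    if (draw$noise > 0) {
      img <- img + array(stats::rnorm(length(img), 0, draw$noise), dim = dim(img))
      img <- pmin(pmax(img, 0), 255)
    }
    structure(list(tile = img,
                   target = structure(list(object_mask = obj, contour_mask = cnt,
                                           approach = target$approach),
                                      class = "target_pair")),
              draw = draw)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# --- normalization statistics --------------------------------------------

#' Per-channel normalization statistics of a training set
#'
#' Pixel-wise mean and (population) standard deviation per channel across
#' all training tiles; applied as `(v - mean) / sd` after augmentation.
#'
#' @param tiles list of `(H, W, 3)` arrays.
#' @return a `norm_stats` list with `mean` and `sd` (length-3 vectors).
#' @export
compute_normalization_stats <- function(tiles) {
  if (length(tiles) < 1) stopf("data error: need at least one tile")
  acc_n <- 0; acc_s <- numeric(3); acc_s2 <- numeric(3)
  for (t in tiles) {
    m <- matrix(t, ncol = 3)
    acc_n <- acc_n + nrow(m)
    acc_s <- acc_s + colSums(m)
    acc_s2 <- acc_s2 + colSums(m^2)
  }
  mu <- acc_s / acc_n
  sd <- sqrt(pmax(acc_s2 / acc_n - mu^2, 0))
  if (any(sd <= 0))
    stopf("degenerate stats: channel(s) %s have zero variance (means: %s)",
          paste(which(sd <= 0), collapse = ","),
          paste(signif(mu, 6), collapse = ", "))
  structure(list(mean = mu, sd = sd), class = "norm_stats")
}

apply_norm_stats <- function(tile, stats) {
  for (c in 1:3) tile[, , c] <- (tile[, , c] - stats$mean[c]) / stats$sd[c]
  tile
}

# --- training loop --------------------------------------------------------

load_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest,
                                                          stringsAsFactors = FALSE)
  if (!is.data.frame(manifest) || nrow(manifest) == 0)
    stopf("data error: empty or invalid manifest")
  if (!all(c("image", "annotation") %in% names(manifest)))
    stopf("data error: manifest needs 'image' and 'annotation' columns")
  miss <- c(manifest$image, manifest$annotation)
  miss <- miss[!file.exists(miss)]
  if (length(miss)) stopf("data error: missing files: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  manifest
}

# Stratified 80/20 split on the morphology tag (when present), mirroring a
# benign/malignant-balanced split.
split_train_val <- function(manifest, val_fraction, seed) {
  strata <- if ("morphology" %in% names(manifest)) manifest$morphology
            else rep("all", nrow(manifest))
  val <- logical(nrow(manifest))
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      n_val <- max(1L, round(val_fraction * length(idx)))
      val[sample(idx, n_val)] <- TRUE
    }
  })
  list(train = which(!val), val = which(val))
}

#' Train a dual-decoder Dense-U-Net
#'
#' Loads the manifest's (image, instance-annotation) pairs, resizes them to
#' the configured input size (bilinear for images, nearest for masks),
#' derives the route's target pair per tile, splits train/validation 80/20
#' stratified on the morphology tag, and runs seeded mini-batch training
#' with on-the-fly augmentation. Returns the checkpoint with minimum
#' validation loss.
#'
#' @param manifest data.frame (or CSV path) with columns `image`,
#'   `annotation` and optionally `morphology`.
#' @param approach `"gland"` or `"stroma"`.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param loss_cfg a [loss_config()].
#' @param contour_thickness contour band thickness in pixels.
#' @param white_threshold white gray level for the stroma route.
#' @param noise_sd augmentation noise level, gray levels.
#' @param verbose print per-epoch progress.
#' @return a `glandseg_model`: list with the trained `net`, `norm_stats`,
#'   `history` (epoch, train_loss, val_loss, lr), `best_epoch`, `approach`
#'   and the three configs.
#' @export
train_model <- function(manifest, approach = c("gland", "stroma"),
                        model_cfg = tiny_model_config(),
                        train_cfg = train_config(),
                        loss_cfg = loss_config(),
                        contour_thickness = 2, white_threshold = 220,
                        noise_sd = 5, verbose = FALSE) {
  approach <- match.arg(approach)
  manifest <- load_manifest(manifest)
  size <- model_cfg$input_size
  tiles <- lapply(manifest$image, function(p) resize_raster(read_image(p), size))
  insts <- lapply(manifest$annotation, function(p) {
    m <- resize_raster(read_mask(p) * 1.0, size, "nearest")
    matrix(as.integer(m), size, size)
  })
  targets <- Map(function(t, i) derive_targets(t, i, approach,
                                               thickness = contour_thickness,
                                               white_threshold = white_threshold),
                 tiles, insts)
  sp <- split_train_val(manifest, train_cfg$val_fraction,
                        derive_seed(train_cfg$seed, "split"))
  stats <- compute_normalization_stats(tiles[sp$train])
  net <- with_seed(derive_seed(train_cfg$seed, "init"),
                   build_dense_unet(model_cfg))
  adam_init(net)
  sched <- plateau_state(train_cfg$lr, train_cfg$plateau_patience,
                         train_cfg$lr_factor)
  alpha <- loss_cfg$alpha
  history <- vector("list", train_cfg$epochs)
  best_val <- Inf; best_params <- NULL; best_epoch <- NA_integer_

  val_loss_fn <- function() {
    tot <- 0
    for (i in sp$val) {
      x <- apply_norm_stats(tiles[[i]], stats)
      dim(x) <- c(size, size, 3, 1)
      out <- forward_net(net, x, training = FALSE)$outputs
      tot <- tot + alpha * bce_mean(out[[1]], targets[[i]]$object_mask) +
        (1 - alpha) * bce_mean(out[[2]], targets[[i]]$contour_mask)
    }
    tot / length(sp$val)
  }

  for (epoch in seq_len(train_cfg$epochs)) {
    epoch_loss <- 0
    with_seed(derive_seed(train_cfg$seed, paste0("epoch", epoch)), {
      for (step in seq_len(train_cfg$steps_per_epoch)) {
        idx <- sample(sp$train, train_cfg$batch_size, replace = TRUE)
        bs <- length(idx)
        x <- array(0, dim = c(size, size, 3, bs))
        tobj <- array(0, dim = c(size, size, 1, bs))
        tcnt <- array(0, dim = c(size, size, 1, bs))
        for (j in seq_len(bs)) {
          aug <- augment_pair(tiles[[idx[j]]], targets[[idx[j]]],
                              noise_sd = noise_sd)
          x[, , , j] <- apply_norm_stats(aug$tile, stats)
          tobj[, , 1, j] <- aug$target$object_mask
          tcnt[, , 1, j] <- aug$target$contour_mask
        }
        fw <- forward_net(net, x, training = TRUE)
        pobj <- fw$outputs[[1]]; pcnt <- fw$outputs[[2]]
        loss <- alpha * bce_mean(pobj, tobj) + (1 - alpha) * bce_mean(pcnt, tcnt)
        if (!is.finite(loss))
          stopf("divergence error: non-finite loss at epoch %d", epoch)
        epoch_loss <- epoch_loss + loss
        npix <- length(pobj)
        seeds <- stats::setNames(
          list(alpha * (pobj - tobj) / npix, (1 - alpha) * (pcnt - tcnt) / npix),
          as.character(net$head_pre))
        backward_net(net, fw$caches, seeds)
        adam_step(net, sched$lr, train_cfg$betas, loss_cfg$weight_decay)
      }
    })
    vl <- val_loss_fn()
    if (vl < best_val - 1e-12) {
      best_val <- vl
      best_params <- net$params
      best_epoch <- epoch
    }
    history[[epoch]] <- data.frame(
      epoch = epoch,
      train_loss = epoch_loss / train_cfg$steps_per_epoch +
        loss_cfg$weight_decay * weights_l2(net),
      val_loss = vl, lr = sched$lr)
    sched <- plateau_update(sched, vl)
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f lr %.2e", epoch,
                      history[[epoch]]$train_loss, vl, history[[epoch]]$lr))
  }
  if (!is.null(best_params)) net$params <- best_params
  structure(list(net = net, norm_stats = stats,
                 history = do.call(rbind, history), best_epoch = best_epoch,
                 best_val = best_val, approach = approach,
                 model_cfg = model_cfg, train_cfg = train_cfg,
                 loss_cfg = loss_cfg),
            class = "glandseg_model")
}

#' @export
print.glandseg_model <- function(x, ...) {
  cat(sprintf("glandseg %s-approach model (best epoch %d, val loss %.4f)\n",
              x$approach, x$best_epoch, x$best_val))
  print(x$net)
  invisible(x)
}

#' Save / load a trained model
#'
#' Checkpoints are RDS files holding the graph description, parameters,
#' normalization statistics and configs with a format version header.
#'
#' @param model a `glandseg_model`.
#' @param path destination `.rds` path.
#' @return `path` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  net <- model$net
  payload <- list(format = "glandseg-checkpoint-1",
                  nodes = net$nodes, params = net$params,
                  out_ids = net$out_ids, head_pre = net$head_pre,
                  config = net$config, encoder_channels = net$encoder_channels,
                  norm_stats = model$norm_stats, history = model$history,
                  best_epoch = model$best_epoch, best_val = model$best_val,
                  approach = model$approach, model_cfg = model$model_cfg,
                  train_cfg = model$train_cfg, loss_cfg = model$loss_cfg)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- readRDS(path)
  if (!identical(p$format, "glandseg-checkpoint-1"))
    stopf("not a glandseg checkpoint: %s", path)
  g <- new_graph()
  g$nodes <- p$nodes; g$params <- p$params
  g$out_ids <- p$out_ids; g$head_pre <- p$head_pre
  g$config <- p$config; g$encoder_channels <- p$encoder_channels
  g$ncons <- count_consumers(g)
  class(g) <- c("dense_unet", "environment")
  structure(list(net = g, norm_stats = p$norm_stats, history = p$history,
                 best_epoch = p$best_epoch, best_val = p$best_val,
                 approach = p$approach, model_cfg = p$model_cfg,
                 train_cfg = p$train_cfg, loss_cfg = p$loss_cfg),
            class = "glandseg_model")
}
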
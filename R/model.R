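# Dual-decoder Dense-U-Net.
#
# Encoder: DenseNet-style stem (7x7 stride-2 conv + 3x3 stride-2 max-pool)
# followed by four dense blocks with transition layers (BN-ReLU-1x1 conv
# with 0.5 compression, then average-pooling stride 2). Within a dense
# block every layer receives the concatenation of all previous outputs and
# adds `growth_rate` channels (pre-activation BN-ReLU ordering, bottleneck
# 1x1 at 4x growth). The default [6, 12, 32, 32] block layout with growth
# 32 is the Dense-169 feature extractor.
#
# Two independent decoders (no shared weights) mirror the five
# downsamplings: each stage is a reverse-transition layer (bilinear x2
# upsampling + 3x3 conv), concatenation of the equal-resolution encoder
# output, and a BN-ReLU-3x3 conv; each decoder ends in a 1-channel sigmoid
# head. One head predicts the object (gland or stroma) probability map,
# the other the contour probability map.

#' Dense-U-Net configuration
#'
#' @param block_layers layer counts of the four dense blocks
#'   (default `c(6, 12, 32, 32)`, the Dense-169 layout).
#' @param growth_rate channels added per dense layer (default 32).
#' @param input_size training tile side in pixels; must be divisible by 32.
#' @param decoder_channels widths of the five decoder stages, coarse to
#'   fine (default `c(256, 128, 64, 32, 16)`).
#' @param init_channels stem output channels (default `2 * growth_rate`).
#' @param bottleneck use 1x1 bottleneck layers inside dense blocks.
#' @param compression transition-layer channel compression (default 0.5).
#' @param pretrained_encoder optional path to an encoder weight list to
#'   load via [load_encoder_weights()]; `NULL` keeps He initialization.
#' @return a `model_config` list.
#' @export
model_config <- function(block_layers = c(6, 12, 32, 32), growth_rate = 32,
                         input_size = 480,
                         decoder_channels = c(256, 128, 64, 32, 16),
                         init_channels = 2 * growth_rate, bottleneck = TRUE,
                         compression = 0.5, pretrained_encoder = NULL) {
  if (length(block_layers) != 4) stopf("config error: need 4 dense blocks")
  if (input_size %% 32 != 0)
    stopf("config error: input_size must be divisible by 32")
  if (length(decoder_channels) != 5)
    stopf("config error: need 5 decoder stage widths")
  structure(list(block_layers = as.integer(block_layers),
                 growth_rate = as.integer(growth_rate),
                 input_size = as.integer(input_size),
                 decoder_channels = as.integer(decoder_channels),
                 init_channels = as.integer(init_channels),
                 bottleneck = isTRUE(bottleneck), compression = compression,
                 pretrained_encoder = pretrained_encoder),
            class = "model_config")
}

#' Desk-scale Dense-U-Net configuration
#'
#' A reduced configuration (`[2, 2, 2, 2]` blocks, growth 8, 128 px tiles)
#' for CPU-scale experiments and tests.
#'
#' @param input_size tile side (default 128).
#' @return a `model_config`.
#' @export
tiny_model_config <- function(input_size = 128) {
  model_config(block_layers = c(2, 2, 2, 2), growth_rate = 8,
               input_size = input_size,
               decoder_channels = c(64, 32, 16, 16, 8), init_channels = 16)
}

# One dense layer: pre-activation (BN-ReLU-conv); with bottleneck a 1x1 at
# 4 * growth precedes the 3x3. Returns the id of the k-channel output.
add_dense_layer <- function(g, x, cin, k, bottleneck) {
  cur <- x; c_cur <- cin
  if (bottleneck) {
    b1 <- add_node(g, "bn", cur, params = init_bn_params(c_cur))
    r1 <- add_node(g, "relu", b1)
    cur <- add_node(g, "conv", r1, args = list(stride = 1L, pad = 0L),
                    params = init_conv_params(1, 1, c_cur, 4 * k))
    c_cur <- 4 * k
  }
  b2 <- add_node(g, "bn", cur, params = init_bn_params(c_cur))
  r2 <- add_node(g, "relu", b2)
  add_node(g, "conv", r2, args = list(stride = 1L, pad = 1L),
           params = init_conv_params(3, 3, c_cur, k))
}

#' Build the dual-decoder Dense-U-Net
#'
#' Constructs the network graph with He-normal initialization (seed the RNG
#' before calling for reproducible weights). `dense = FALSE` replaces dense
#' concatenation with plain chaining (each layer sees only its predecessor);
#' it exists to demonstrate that dense connectivity changes the parameter
#' count, and is not used by the pipeline.
#'
#' @param config a [model_config()].
#' @param dense keep dense connectivity (default TRUE).
#' @return a `dense_unet` graph environment; notable fields:
#'   `encoder_channels` (per-block input/output channel counts),
#'   `out_ids` (object and contour sigmoid heads), `config`.
#' @export
build_dense_unet <- function(config = model_config(), dense = TRUE) {
  stopifnot(inherits(config, "model_config"))
  k <- config$growth_rate
  g <- new_graph()
  inp <- add_node(g, "input")
  # stem: 7x7/2 conv + BN-ReLU + 3x3/2 max-pool (total /4)
  c0 <- config$init_channels
  sc <- add_node(g, "conv", inp, args = list(stride = 2L, pad = 3L),
                 params = init_conv_params(7, 7, 3, c0))
  sb <- add_node(g, "bn", sc, params = init_bn_params(c0))
  stem_act <- add_node(g, "relu", sb)                       # /2 skip
  cur <- add_node(g, "maxpool", stem_act)                   # /4
  c_cur <- c0
  skips <- integer(3); skip_c <- integer(3)
  enc_channels <- data.frame(block = 1:4, c_in = NA_integer_, c_out = NA_integer_)
  for (b in 1:4) {
    enc_channels$c_in[b] <- c_cur
    for (l in seq_len(config$block_layers[b])) {
      y <- add_dense_layer(g, cur, c_cur, k, config$bottleneck)
      if (dense) {
        cur <- add_node(g, "concat", c(cur, y))
        c_cur <- c_cur + k
      } else {
        cur <- y
        c_cur <- k
      }
    }
    if (dense) enc_channels$c_out[b] <- c_cur else enc_channels$c_out[b] <- c_cur
    if (b < 4) {
      skips[4 - b] <- cur; skip_c[4 - b] <- c_cur   # skips[1]=block3, [2]=block2, [3]=block1
      tb <- add_node(g, "bn", cur, params = init_bn_params(c_cur))
      tr <- add_node(g, "relu", tb)
      ct <- max(1L, as.integer(floor(c_cur * config$compression)))
      tc <- add_node(g, "conv", tr, args = list(stride = 1L, pad = 0L),
                     params = init_conv_params(1, 1, c_cur, ct))
      cur <- add_node(g, "avgpool", tc)
      c_cur <- ct
    }
  }
  fb <- add_node(g, "bn", cur, params = init_bn_params(c_cur))
  enc_top <- add_node(g, "relu", fb)                        # /32
  c_top <- c_cur
  skip_ids <- c(skips, stem_act, NA)                        # stages 1..5
  skip_cc <- c(skip_c, c0, 0L)
  dec_w <- config$decoder_channels
  heads <- integer(2); head_pre <- integer(2)
  for (ddx in 1:2) {
    cur <- enc_top; c_cur <- c_top
    for (s in 1:5) {
      up <- add_node(g, "up2", cur)
      rt <- add_node(g, "conv", up, args = list(stride = 1L, pad = 1L),
                     params = init_conv_params(3, 3, c_cur, dec_w[s]))
      c_cur <- dec_w[s]
      if (!is.na(skip_ids[s])) {
        cur <- add_node(g, "concat", c(rt, skip_ids[s]))
        c_cur <- c_cur + skip_cc[s]
      } else cur <- rt
      cb <- add_node(g, "bn", cur, params = init_bn_params(c_cur))
      cr <- add_node(g, "relu", cb)
      cur <- add_node(g, "conv", cr, args = list(stride = 1L, pad = 1L),
                      params = init_conv_params(3, 3, c_cur, dec_w[s]))
      c_cur <- dec_w[s]
      hb <- add_node(g, "bn", cur, params = init_bn_params(c_cur))
      cur <- add_node(g, "relu", hb)
    }
    head_pre[ddx] <- add_node(g, "conv", cur, args = list(stride = 1L, pad = 0L),
                              params = init_conv_params(1, 1, c_cur, 1))
    heads[ddx] <- add_node(g, "sigmoid", head_pre[ddx])
  }
  g$out_ids <- heads
  g$head_pre <- head_pre
  g$ncons <- count_consumers(g)
  g$config <- config
  g$encoder_channels <- enc_channels
  class(g) <- c("dense_unet", "environment")
  if (!is.null(config$pretrained_encoder))
    load_encoder_weights(g, config$pretrained_encoder)
  g
}

#' Number of trainable parameters
#'
#' @param net a `dense_unet` or `glandseg_model`.
#' @return integer parameter count.
#' @export
n_params <- function(net) {
  if (inherits(net, "glandseg_model")) net <- net$net
  n_params_graph(net)
}

#' Layer table of a network
#'
#' @param net a `dense_unet` or `glandseg_model`.
#' @return data.frame with one row per graph node (id, op, inputs, params).
#' @export
layer_table <- function(net) {
  if (inherits(net, "glandseg_model")) net <- net$net
  do.call(rbind, lapply(net$nodes, function(nd) {
    p <- net$params[[nd$id]]
    np <- if (is.null(p)) 0L else
      sum(vapply(p[intersect(names(p), TRAINABLE)], length, integer(1)))
    data.frame(id = nd$id, op = nd$op,
               inputs = paste(nd$inputs, collapse = ","), n_params = np)
  }))
}

#' @export
print.dense_unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Dense-U-Net: blocks [%s], growth %d, input %dx%d\n",
              paste(cfg$block_layers, collapse = ", "), cfg$growth_rate,
              cfg$input_size, cfg$input_size))
  cat(sprintf("  nodes: %d, trainable parameters: %s\n",
              length(x$nodes), format(n_params_graph(x), big.mark = ",")))
  cat("  encoder dense-block channels (in -> out):\n")
  for (b in 1:4)
    cat(sprintf("    block %d: %d -> %d\n", b, x$encoder_channels$c_in[b],
                x$encoder_channels$c_out[b]))
  invisible(x)
}

#' Load encoder weights from a checkpoint list
#'
#' Optional hook for initializing the encoder from externally trained
#' DenseNet weights stored as the list produced by [save_model()] (the
#' decoder keeps its He initialization). No pretrained weights ship with
#' the package.
#'
#' @param net a `dense_unet`.
#' @param path RDS file containing a `params` list of matching shapes.
#' @return the network, invisibly.
#' @export
load_encoder_weights <- function(net, path) {
  ckpt <- readRDS(path)
  src <- if (!is.null(ckpt$params)) ckpt$params else ckpt
  for (id in seq_along(src)) {
    if (is.null(src[[id]]) || id > length(net$params)) next
    tgt <- net$params[[id]]
    if (is.null(tgt)) next
    same <- all(vapply(names(tgt), function(nm)
      !is.null(src[[id]][[nm]]) &&
        identical(dim(src[[id]][[nm]]), dim(tgt[[nm]])) &&
        length(src[[id]][[nm]]) == length(tgt[[nm]]), logical(1)))
    if (same) net$params[[id]] <- src[[id]]
  }
  invisible(net)
}

#' Predict probability maps for a tile
#'
#' Runs the network in inference mode (batch-norm uses running statistics,
#' so repeated calls are identical). The tile side must be divisible by 32;
#' the network is fully convolutional, so sizes other than the training
#' `input_size` are accepted.
#'
#' @param model a trained `glandseg_model` (normalization statistics are
#'   applied automatically) or a raw `dense_unet` (tile used as-is).
#' @param tile `(H, W, 3)` RGB array in `[0, 255]`.
#' @return a `probability_maps` list: `object_prob` and `contour_prob`
#'   matrices of the tile's spatial shape, values in `[0, 1]`.
#' @export
predict_maps <- function(model, tile) {
  net <- model; stats <- NULL
  if (inherits(model, "glandseg_model")) {
    net <- model$net
    stats <- model$norm_stats
  }
  d <- dim(tile)
  if (length(d) != 3 || d[3] != 3) stopf("shape error: tile must be (H, W, 3)")
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    stopf("shape error: tile sides must be divisible by 32 (got %dx%d)", d[1], d[2])
  x <- tile
  if (!is.null(stats))
    for (c in 1:3) x[, , c] <- (x[, , c] - stats$mean[c]) / stats$sd[c]
  dim(x) <- c(d[1], d[2], 3, 1)
  out <- forward_net(net, x, training = FALSE)$outputs
  structure(list(object_prob = matrix(out[[1]], d[1], d[2]),
                 contour_prob = matrix(out[[2]], d[1], d[2])),
            class = "probability_maps")
}
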
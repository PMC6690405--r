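# Minimal static-graph neural-network engine.
#
# The package trains its segmentation network with an in-package engine:
# a directed acyclic graph of typed nodes (conv, batch-norm, relu, pooling,
# bilinear upsampling, concat, sigmoid) with hand-written forward and
# backward passes. Convolutions run as im2col + GEMM in compiled code
# (src/ops.cpp); everything channel-wise stays vectorized R. Activations
# are column-major arrays of shape (H, W, C, N).
#
# This is deliberately not a general autodiff system: the graph is built
# once by the architecture constructor and the per-op backward rules are
# exact for that graph.

new_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$params <- list()
  g$grads <- list()
  g
}

add_node <- function(g, op, inputs = integer(0), args = list(), params = NULL) {
  id <- length(g$nodes) + 1L
  g$nodes[[id]] <- list(id = id, op = op, inputs = as.integer(inputs), args = args)
  g$params[[id]] <- params
  id
}

init_conv_params <- function(kh, kw, cin, cout) {
  # He-normal initialization for ReLU networks
  list(w = array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
                 dim = c(kh, kw, cin, cout)),
       b = rep(0, cout))
}

init_bn_params <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c), rm = rep(0, c), rv = rep(1, c))
}

# --- channel-wise helpers -------------------------------------------------

chan_expand <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])

chan_sum <- function(x) {
  d <- dim(x)
  cs <- colSums(matrix(x, d[1] * d[2], d[3] * d[4]))
  rowSums(matrix(cs, d[3], d[4]))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# --- per-op forward -------------------------------------------------------

op_forward <- function(node, ins, p, training) {
  switch(node$op,
    input = list(y = ins[[1]], cache = NULL),
    conv = {
      x <- ins[[1]]
      y <- nn_conv2d_fwd(x, p$w, p$b, node$args$stride, node$args$pad)
      list(y = y, cache = if (training) x)
    },
    bn = {
      x <- ins[[1]]; d <- dim(x)
      if (training) {
        m <- d[1] * d[2] * d[4]
        xm <- matrix(x, d[1] * d[2], d[3] * d[4])
        mu_cn <- colMeans(xm)
        e2_cn <- colMeans(xm^2)
        mu <- rowMeans(matrix(mu_cn, d[3], d[4]))
        vr <- pmax(rowMeans(matrix(e2_cn, d[3], d[4])) - mu^2, 0)
        invstd <- 1 / sqrt(vr + BN_EPS)
        xhat <- (x - chan_expand(mu, d)) * chan_expand(invstd, d)
        y <- xhat * chan_expand(p$gamma, d) + chan_expand(p$beta, d)
        p$rm <- (1 - BN_MOMENTUM) * p$rm + BN_MOMENTUM * mu
        p$rv <- (1 - BN_MOMENTUM) * p$rv + BN_MOMENTUM * vr
        list(y = y, cache = list(xhat = xhat, invstd = invstd), params = p)
      } else {
        scale <- p$gamma / sqrt(p$rv + BN_EPS)
        shift <- p$beta - scale * p$rm
        list(y = x * chan_expand(scale, d) + chan_expand(shift, d), cache = NULL)
      }
    },
    relu = {
      y <- pmax(ins[[1]], 0)
      list(y = y, cache = if (training) y)
    },
    maxpool = {
      r <- nn_maxpool3s2_fwd(ins[[1]])
      d <- dim(ins[[1]])
      list(y = r$y, cache = if (training) list(idx = r$idx, H = d[1], W = d[2]))
    },
    avgpool = {
      d <- dim(ins[[1]])
      list(y = nn_avgpool2_fwd(ins[[1]]),
           cache = if (training) list(H = d[1], W = d[2]))
    },
    up2 = {
      d <- dim(ins[[1]])
      list(y = nn_upsample2_fwd(ins[[1]]),
           cache = if (training) list(H = d[1], W = d[2]))
    },
    concat = {
      dims <- lapply(ins, dim)
      cc <- vapply(dims, `[`, numeric(1), 3)
      d1 <- dims[[1]]
      out <- array(0, dim = c(d1[1], d1[2], sum(cc), d1[4]))
      off <- 0L
      for (j in seq_along(ins)) {
        out[, , off + seq_len(cc[j]), ] <- ins[[j]]
        off <- off + cc[j]
      }
      list(y = out, cache = if (training) cc)
    },
    sigmoid = {
      y <- 1 / (1 + exp(-ins[[1]]))
      list(y = y, cache = if (training) y)
    },
    stop("unknown op: ", node$op))
}

# --- per-op backward ------------------------------------------------------

op_backward <- function(node, dy, cache, p) {
  switch(node$op,
    input = list(dins = list(NULL)),
    conv = {
      r <- nn_conv2d_bwd(cache, p$w, dy, node$args$stride, node$args$pad)
      list(dins = list(r$dx), dparams = list(w = r$dw, b = r$db))
    },
    bn = {
      d <- dim(dy)
      m <- d[1] * d[2] * d[4]
      s1 <- chan_sum(dy)
      s2 <- chan_sum(dy * cache$xhat)
      dx <- chan_expand(p$gamma * cache$invstd, d) *
        (dy - chan_expand(s1 / m, d) - cache$xhat * chan_expand(s2 / m, d))
      list(dins = list(dx), dparams = list(gamma = s2, beta = s1))
    },
    relu = list(dins = list(dy * (cache > 0))),
    maxpool = list(dins = list(nn_maxpool3s2_bwd(dy, cache$idx, cache$H, cache$W))),
    avgpool = list(dins = list(nn_avgpool2_bwd(dy, cache$H, cache$W))),
    up2 = list(dins = list(nn_upsample2_bwd(dy, cache$H, cache$W))),
    concat = {
      off <- 0L
      dins <- lapply(cache, function(cc) {
        g <- dy[, , off + seq_len(cc), , drop = FALSE]
        off <<- off + cc
        g
      })
      list(dins = dins)
    },
    sigmoid = list(dins = list(dy * cache * (1 - cache))),
    stop("unknown op: ", node$op))
}

# --- engine ---------------------------------------------------------------

count_consumers <- function(g) {
  rc <- integer(length(g$nodes))
  for (node in g$nodes)
    for (i in node$inputs) rc[i] <- rc[i] + 1L
  rc
}

# Forward pass. Returns the values of g$out_ids and (in training mode) the
# per-node caches needed for backward. Intermediate activations are freed
# as soon as their last consumer has run.
forward_net <- function(g, x, training = FALSE) {
  n <- length(g$nodes)
  vals <- vector("list", n)
  caches <- if (training) vector("list", n)
  rc <- g$ncons
  keep <- g$out_ids
  for (id in seq_len(n)) {
    node <- g$nodes[[id]]
    ins <- if (node$op == "input") list(x) else lapply(node$inputs, function(i) vals[[i]])
    r <- op_forward(node, ins, g$params[[id]], training)
    vals[[id]] <- r$y
    if (training) caches[[id]] <- r$cache
    if (!is.null(r$params)) g$params[[id]] <- r$params
    for (i in node$inputs) {
      rc[i] <- rc[i] - 1L
      if (rc[i] == 0L && !(i %in% keep)) vals[i] <- list(NULL)
    }
  }
  list(outputs = vals[g$out_ids], caches = caches)
}

# Backward pass from seeded gradients (a named-by-id list of arrays, usually
# injected at the pre-sigmoid heads). Accumulates parameter gradients into
# g$grads.
backward_net <- function(g, caches, seeds) {
  n <- length(g$nodes)
  gr <- vector("list", n)
  for (sid in names(seeds)) gr[[as.integer(sid)]] <- seeds[[sid]]
  g$grads <- vector("list", n)
  for (id in rev(seq_len(n))) {
    if (is.null(gr[[id]])) next
    node <- g$nodes[[id]]
    r <- op_backward(node, gr[[id]], caches[[id]], g$params[[id]])
    if (!is.null(r$dparams)) g$grads[[id]] <- r$dparams
    for (j in seq_along(node$inputs)) {
      i <- node$inputs[j]
      di <- r$dins[[j]]
      if (is.null(di)) next
      gr[[i]] <- if (is.null(gr[[i]])) di else gr[[i]] + di
    }
    gr[id] <- list(NULL)
  }
  invisible(g)
}

# --- Adam -----------------------------------------------------------------

TRAINABLE <- c("w", "b", "gamma", "beta")

adam_init <- function(g) {
  st <- list(t = 0, m = vector("list", length(g$nodes)),
             v = vector("list", length(g$nodes)))
  for (id in seq_along(g$params)) {
    p <- g$params[[id]]
    if (is.null(p)) next
    nm <- intersect(names(p), TRAINABLE)
    st$m[[id]] <- lapply(p[nm], function(a) array(0, dim = if (is.null(dim(a))) length(a) else dim(a)))
    st$v[[id]] <- st$m[[id]]
  }
  g$opt <- st
  invisible(g)
}

# One Adam update. L2 weight decay (the lambda ||w||^2 loss term) applies to
# convolution kernels only, entering through the gradient as 2*lambda*w.
adam_step <- function(g, lr, betas = c(0.9, 0.99), weight_decay = 0, eps = 1e-8) {
  st <- g$opt
  st$t <- st$t + 1
  bc1 <- 1 - betas[1]^st$t
  bc2 <- 1 - betas[2]^st$t
  for (id in seq_along(g$grads)) {
    gri <- g$grads[[id]]
    if (is.null(gri)) next
    is_conv <- g$nodes[[id]]$op == "conv"
    for (nm in names(gri)) {
      gval <- gri[[nm]]
      if (is_conv && nm == "w" && weight_decay > 0)
        gval <- gval + 2 * weight_decay * g$params[[id]][[nm]]
      m <- betas[1] * st$m[[id]][[nm]] + (1 - betas[1]) * gval
      v <- betas[2] * st$v[[id]][[nm]] + (1 - betas[2]) * gval^2
      st$m[[id]][[nm]] <- m
      st$v[[id]][[nm]] <- v
      g$params[[id]][[nm]] <- g$params[[id]][[nm]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  g$opt <- st
  invisible(g)
}

# Sum of squared convolution-kernel weights (the ||w||^2 of the loss).
weights_l2 <- function(g) {
  s <- 0
  for (id in seq_along(g$params)) {
    if (!is.null(g$params[[id]]) && g$nodes[[id]]$op == "conv")
      s <- s + sum(g$params[[id]]$w^2)
  }
  s
}

n_params_graph <- function(g) {
  s <- 0L
  for (p in g$params) {
    if (is.null(p)) next
    for (nm in intersect(names(p), TRAINABLE)) s <- s + length(p[[nm]])
  }
  s
}
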
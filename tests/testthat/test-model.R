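# Dense-U-Net architecture and inference contracts.

test_that("encoder channel counts follow the dense growth rule", {
  # channel arithmetic c_out = c_in + n_layers * growth, checked on the
  # reduced configuration that the desk-scale experiments use
  set.seed(1)
  net <- build_dense_unet(tiny_model_config())
  cfg <- net$config
  c_in <- cfg$init_channels
  for (b in 1:4) {
    expect_equal(net$encoder_channels$c_in[b], c_in)
    c_out <- c_in + cfg$block_layers[b] * cfg$growth_rate
    expect_equal(net$encoder_channels$c_out[b], c_out)
    c_in <- floor(c_out * cfg$compression)
  }
  # exactly two sigmoid output heads
  expect_length(net$out_ids, 2)
  expect_true(all(vapply(net$nodes[net$out_ids], function(n) n$op,
                         character(1)) == "sigmoid"))
})

test_that("forward pass honours the spatial contract on a tiny config", {
  set.seed(2)
  net <- build_dense_unet(model_config(block_layers = c(2, 2, 2, 2),
                                       growth_rate = 8, input_size = 64,
                                       decoder_channels = c(16, 16, 8, 8, 8),
                                       init_channels = 16))
  tile <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  maps <- predict_maps(net, tile)
  expect_equal(dim(maps$object_prob), c(64, 64))
  expect_equal(dim(maps$contour_prob), c(64, 64))
  expect_true(all(is.finite(maps$object_prob)))
  expect_true(all(maps$object_prob >= 0 & maps$object_prob <= 1))
  expect_true(all(maps$contour_prob >= 0 & maps$contour_prob <= 1))
  # inference determinism
  expect_identical(predict_maps(net, tile), predict_maps(net, tile))
  # shape guards
  expect_error(predict_maps(net, array(0, c(60, 60, 3))), "shape error")
  expect_error(model_config(input_size = 100), "config error")
})

test_that("sigmoid outputs stay in range over random inputs", {
  set.seed(3)
  net <- build_dense_unet(tiny_cfg(64))
  for (i in 1:10) {
    m <- predict_maps(net, array(rnorm(64 * 64 * 3, 128, 60), c(64, 64, 3)))
    expect_true(all(m$object_prob >= 0 & m$object_prob <= 1))
    expect_true(all(m$contour_prob >= 0 & m$contour_prob <= 1))
  }
})

test_that("transition layers halve resolution and the decoder restores it", {
  set.seed(4)
  net <- build_dense_unet(tiny_cfg(64))
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  # record every node's spatial dims by re-running the graph manually
  vals <- vector("list", length(net$nodes))
  for (id in seq_along(net$nodes)) {
    node <- net$nodes[[id]]
    ins <- if (node$op == "input") list(x) else lapply(node$inputs, function(i) vals[[i]])
    vals[[id]] <- glandseg:::op_forward(node, ins, net$params[[id]], FALSE)$y
  }
  hs <- vapply(vals, function(v) dim(v)[1], numeric(1))
  pool_ids <- which(vapply(net$nodes, function(n) n$op %in% c("avgpool", "maxpool"),
                           logical(1)))
  for (id in pool_ids)
    expect_equal(hs[id], hs[net$nodes[[id]]$inputs[1]] / 2)
  up_ids <- which(vapply(net$nodes, function(n) n$op == "up2", logical(1)))
  for (id in up_ids)
    expect_equal(hs[id], 2 * hs[net$nodes[[id]]$inputs[1]])
  # encoder path for 64 px input: 32 (stem) -> 16 -> 8 -> 4 -> 2
  expect_equal(sort(unique(hs)), c(2, 4, 8, 16, 32, 64))
  expect_equal(hs[net$out_ids], c(64, 64))
})

test_that("dense connectivity changes the parameter count", {
  set.seed(5)
  dense <- build_dense_unet(tiny_cfg(64), dense = TRUE)
  chained <- build_dense_unet(tiny_cfg(64), dense = FALSE)
  expect_false(n_params(dense) == n_params(chained))
})

test_that("analytic gradients match finite differences through the graph", {
  set.seed(42)
  net <- build_dense_unet(tiny_cfg(64))
  x <- array(rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  tobj <- array(rbinom(64 * 64 * 2, 1, 0.3), c(64, 64, 1, 2))
  tcnt <- array(rbinom(64 * 64 * 2, 1, 0.1), c(64, 64, 1, 2))
  loss <- function() {
    fw <- glandseg:::forward_net(net, x, training = TRUE)
    p1 <- pmin(pmax(fw$outputs[[1]], 1e-7), 1 - 1e-7)
    p2 <- pmin(pmax(fw$outputs[[2]], 1e-7), 1 - 1e-7)
    list(fw = fw,
         value = 0.5 * -mean(tobj * log(p1) + (1 - tobj) * log(1 - p1)) +
                 0.5 * -mean(tcnt * log(p2) + (1 - tcnt) * log(1 - p2)))
  }
  r <- loss()
  npix <- length(r$fw$outputs[[1]])
  seeds <- stats::setNames(list(0.5 * (r$fw$outputs[[1]] - tobj) / npix,
                                0.5 * (r$fw$outputs[[2]] - tcnt) / npix),
                           as.character(net$head_pre))
  glandseg:::backward_net(net, r$fw$caches, seeds)
  set.seed(9)
  ids <- which(!vapply(net$grads, is.null, logical(1)))
  worst <- 0
  for (id in sample(ids, 5)) {
    nm <- sample(names(net$grads[[id]]), 1)
    k <- sample(length(net$params[[id]][[nm]]), 1)
    eps <- 1e-5
    orig <- net$params[[id]][[nm]][k]
    net$params[[id]][[nm]][k] <- orig + eps; lp <- loss()$value
    net$params[[id]][[nm]][k] <- orig - eps; lm <- loss()$value
    net$params[[id]][[nm]][k] <- orig
    g_num <- (lp - lm) / (2 * eps)
    g_an <- net$grads[[id]][[nm]][k]
    worst <- max(worst, abs(g_num - g_an) / max(abs(g_num), abs(g_an), 1e-6))
  }
  expect_lt(worst, 1e-3)
})

test_that("checkpoints round-trip through save and load", {
  set.seed(6)
  net <- build_dense_unet(tiny_cfg(64))
  model <- structure(list(net = net, norm_stats = list(mean = c(100, 120, 140),
                                                       sd = c(30, 30, 30)),
                          history = data.frame(epoch = 1, train_loss = 1,
                                               val_loss = 1, lr = 1e-3),
                          best_epoch = 1L, best_val = 1,
                          approach = "gland", model_cfg = net$config,
                          train_cfg = train_config(), loss_cfg = loss_config()),
                     class = "glandseg_model")
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  tile <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  expect_identical(predict_maps(back, tile), predict_maps(model, tile))
})
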
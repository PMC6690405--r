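# Loss, augmentation, normalization statistics, scheduler, training loop.

test_that("combined loss matches closed forms", {
  tgt <- structure(list(object_mask = matrix(rbinom(64, 1, 0.4), 8, 8),
                        contour_mask = matrix(rbinom(64, 1, 0.2), 8, 8),
                        approach = "gland"), class = "target_pair")
  # uniform 0.5 predictions give ln 2 against any binary target
  half <- list(object_prob = matrix(0.5, 8, 8), contour_prob = matrix(0.5, 8, 8))
  expect_equal(combined_loss(half, tgt, 0, loss_config(0.5, 0)), log(2),
               tolerance = 1e-9)
  # perfect prediction, lambda = 0 -> loss ~ 0 (clamped)
  perfect <- list(object_prob = tgt$object_mask, contour_prob = tgt$contour_mask)
  expect_lt(combined_loss(perfect, tgt, 0, loss_config(0.5, 0)), 1e-6)
  # alpha = 1 removes the contour term entirely
  bad_contour <- list(object_prob = tgt$object_mask,
                      contour_prob = 1 - tgt$contour_mask)
  expect_lt(combined_loss(bad_contour, tgt, 0, loss_config(1, 0)), 1e-6)
  # the regularization term enters as lambda * ||w||^2
  expect_equal(combined_loss(half, tgt, weights_norm = 10,
                             loss_config(0.5, 1e-4)),
               log(2) + 1e-3, tolerance = 1e-9)
})

test_that("plateau scheduler halves the rate after exactly patience epochs", {
  st <- plateau_state(1e-3, patience = 5, factor = 0.5)
  st <- plateau_update(st, 1.0)          # first epoch improves on Inf
  for (i in 1:4) {
    st <- plateau_update(st, 1.0)        # non-improving 1..4
    expect_equal(st$lr, 1e-3)
  }
  st <- plateau_update(st, 1.0)          # 5th non-improving epoch
  expect_equal(st$lr, 5e-4)
  expect_equal(st$n_reductions, 1L)
  # improvement resets the counter
  st <- plateau_update(st, 0.5)
  st <- plateau_update(st, 0.9)
  expect_equal(st$lr, 5e-4)
})

test_that("augmentation identity, involution and mask binarity hold", {
  t1 <- fixture_tile()
  tgt <- gland_targets(t1$mask)
  # forced identity leaves the pair untouched
  id <- augment_pair(t1$image, tgt, transforms = list())
  expect_identical(id$tile, t1$image)
  expect_identical(id$target$object_mask, tgt$object_mask)
  # horizontal flip applied twice is the identity
  f1 <- augment_pair(t1$image, tgt, transforms = list(hflip = TRUE))
  f2 <- augment_pair(f1$tile, f1$target, transforms = list(hflip = TRUE))
  expect_equal(f2$tile, t1$image, tolerance = 1e-10)
  expect_identical(f2$target$object_mask, tgt$object_mask)
  expect_false(identical(f1$target$object_mask, tgt$object_mask))
  # random draws keep masks binary and are seed-deterministic
  a <- augment_pair(t1$image, tgt, seed = 12)
  b <- augment_pair(t1$image, tgt, seed = 12)
  expect_identical(a, b)
  expect_true(all(a$target$object_mask %in% 0:1))
  expect_true(all(a$target$contour_mask %in% 0:1))
})

test_that("image and masks share one spatial transform", {
  t1 <- fixture_tile()
  tgt <- gland_targets(t1$mask)
  for (s in c(3, 17, 44)) {
    aug <- augment_pair(t1$image, tgt, seed = s)
    draw <- attr(aug, "draw")
    # warp the raw mask through the recorded transform: must equal the
    # mask the augmentation produced (Dice exactly 1)
    painted <- apply_augmentation(draw, tgt$object_mask, "nearest", fill = 0)
    expect_equal(as.numeric(dice_coefficient(painted, aug$target$object_mask)), 1)
  }
})

test_that("normalization statistics are population moments with guards", {
  t0 <- array(0, c(4, 4, 3)); t200 <- array(200, c(4, 4, 3))
  st <- compute_normalization_stats(list(t0, t200))
  expect_equal(st$mean, rep(100, 3))
  expect_equal(st$sd, rep(100, 3))  # population sd
  expect_error(compute_normalization_stats(list(array(100, c(4, 4, 3)))),
               "degenerate")
  # standardizing the set gives mean ~ 0, sd ~ 1
  z <- lapply(list(t0, t200), glandseg:::apply_norm_stats, stats = st)
  st2 <- tryCatch(compute_normalization_stats(z), error = function(e) NULL)
  expect_equal(mean(vapply(z, mean, numeric(1))), 0, tolerance = 1e-12)
  expect_equal(st2$sd, rep(1, 3), tolerance = 1e-12)
})

test_that("train/validation split is deterministic and stratified", {
  man <- data.frame(image = sprintf("i%02d.png", 1:20),
                    annotation = sprintf("a%02d.tif", 1:20),
                    morphology = rep(c("benign", "malignant"), 10))
  s1 <- glandseg:::split_train_val(man, 0.2, 99)
  s2 <- glandseg:::split_train_val(man, 0.2, 99)
  expect_identical(s1, s2)
  expect_length(s1$val, 4)
  expect_equal(sum(man$morphology[s1$val] == "benign"), 2)
  s3 <- glandseg:::split_train_val(man, 0.2, 100)
  expect_false(identical(s1$val, s3$val))
})

test_that("a short seeded run learns and keeps honest books", {
  dir <- withr::local_tempdir()
  p <- synth_params(tile_size = 64, n_glands = 2, gland_radius_range = c(8, 13),
                    seed = 50)
  man <- generate_dataset(p, 12, dir)
  cfg <- train_config(epochs = 2, steps_per_epoch = 8, batch_size = 4, seed = 3)
  m <- train_model(man, "gland", model_cfg = tiny_cfg(64), train_cfg = cfg)
  expect_s3_class(m, "glandseg_model")
  expect_equal(nrow(m$history), 2)
  expect_lt(m$history$val_loss[2], m$history$val_loss[1])
  expect_true(all(is.finite(m$history$train_loss)))
  # optimizer progress on a single batch: loss after 20 steps is lower
  set.seed(77)
  net <- build_dense_unet(tiny_cfg(64))
  adam_ <- glandseg:::adam_init(net)
  t1 <- generate_tissue(synth_params(tile_size = 64, n_glands = 2,
                                     gland_radius_range = c(8, 13), seed = 51))
  tgt <- gland_targets(t1$mask)
  x <- array((t1$image - 128) / 60, c(64, 64, 3, 1))
  tobj <- array(tgt$object_mask, c(64, 64, 1, 1))
  tcnt <- array(tgt$contour_mask, c(64, 64, 1, 1))
  losses <- numeric(21)
  for (i in 1:21) {
    fw <- glandseg:::forward_net(net, x, training = TRUE)
    losses[i] <- 0.5 * glandseg:::bce_mean(fw$outputs[[1]], tobj) +
      0.5 * glandseg:::bce_mean(fw$outputs[[2]], tcnt)
    seeds <- stats::setNames(
      list(0.5 * (fw$outputs[[1]] - tobj) / (64 * 64),
           0.5 * (fw$outputs[[2]] - tcnt) / (64 * 64)),
      as.character(net$head_pre))
    glandseg:::backward_net(net, fw$caches, seeds)
    glandseg:::adam_step(net, 1e-3, c(0.9, 0.99), 0)
  }
  expect_lt(losses[21], losses[1])
})
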
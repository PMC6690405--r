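# Supervision-mask derivation.

test_that("binarization counts pixels and ignores label identity", {
  inst <- matrix(0L, 20, 20)
  inst[2:5, 2:11] <- 1L   # 40 px
  inst[8:11, 2:11] <- 2L  # 40 px
  inst[14:17, 2:11] <- 3L # 40 px
  b <- binarize_gland_mask(inst)
  expect_equal(sum(b), 120)
  expect_true(all(b %in% 0:1))
  relab <- inst
  relab[inst == 1L] <- 7L; relab[inst == 3L] <- 1L
  expect_identical(binarize_gland_mask(relab), b)
  expect_equal(sum(binarize_gland_mask(matrix(0L, 4, 4))), 0)
})

test_that("contour of a 5x5 square at thickness 1 is its 16-pixel ring", {
  inst <- matrix(0L, 11, 11)
  inst[4:8, 4:8] <- 1L
  cm <- extract_contour_mask(inst, thickness = 1)
  # brute force: instance pixels 4-adjacent to a different value
  expected <- matrix(0L, 11, 11)
  for (i in 4:8) for (j in 4:8)
    if (i %in% c(4, 8) || j %in% c(4, 8)) expected[i, j] <- 1L
  expect_identical(cm, expected)
  expect_equal(sum(cm), 16)
  expect_equal(sum(extract_contour_mask(matrix(0L, 5, 5), 1)), 0)
})

test_that("contours separate touching instances and ignore relabeling", {
  inst <- matrix(0L, 12, 12)
  inst[3:10, 3:6] <- 1L
  inst[3:10, 7:10] <- 2L  # shares an edge with instance 1
  cm <- extract_contour_mask(inst, thickness = 1)
  # both sides of the shared edge are contour
  expect_true(all(cm[3:10, 6] == 1L))
  expect_true(all(cm[3:10, 7] == 1L))
  remaining <- binarize_gland_mask(inst) == 1L & cm == 0L
  comp <- glandseg:::cc_label8(remaining)
  expect_gte(max(comp), 2)
  swap <- inst; swap[inst == 1L] <- 2L; swap[inst == 2L] <- 1L
  expect_identical(extract_contour_mask(swap, thickness = 2),
                   extract_contour_mask(inst, thickness = 2))
})

test_that("tissue partition is exact and follows gland > white > stroma", {
  # 4x4 toy: 2x2 gland block, 2x2 white block (gray 250), rest gray 100
  tile <- array(100, c(4, 4, 3))
  tile[1:2, 3:4, ] <- 250
  inst <- matrix(0L, 4, 4); inst[1:2, 1:2] <- 1L
  part <- derive_stroma_mask(tile, inst, white_threshold = 220)
  expect_equal(sum(part$stroma), 8)
  expect_equal(sum(part$white), 4)
  expect_equal(sum(part$gland), 4)
  # all-white tile, no glands
  pw <- derive_stroma_mask(array(255, c(3, 3, 3)), matrix(0L, 3, 3))
  expect_equal(sum(pw$white), 9)
  expect_equal(sum(pw$stroma), 0)
  # fully annotated tile has no stroma regardless of intensities
  pg <- derive_stroma_mask(array(255, c(3, 3, 3)), matrix(1L, 3, 3))
  expect_equal(sum(pg$gland), 9)
  expect_equal(sum(pg$stroma) + sum(pg$white), 0)
  expect_error(derive_stroma_mask(array(0, c(3, 3, 3)), matrix(0L, 4, 4)),
               "shape mismatch")
  expect_error(derive_stroma_mask(array(0, c(3, 3, 3)), matrix(0L, 3, 3),
                                  white_threshold = 300), "invalid parameter")
})

test_that("partition property holds on generated tissue", {
  t1 <- fixture_tile()
  part <- derive_stroma_mask(t1$image, t1$mask)
  total <- part$gland + part$stroma + part$white
  expect_true(all(total == 1))  # pairwise disjoint and covering
})

test_that("stroma targets take the partition's stroma and band its boundary", {
  t1 <- fixture_tile()
  part <- derive_stroma_mask(t1$image, t1$mask)
  tp <- stroma_targets(part, thickness = 2)
  expect_equal(tp$approach, "stroma")
  expect_identical(tp$object_mask == 1L, part$stroma)
  # contour band contains the stroma boundary and stays within its dilation
  b <- glandseg:::inner_boundary(part$stroma)
  expect_true(all(tp$contour_mask[b] == 1L))
  band <- glandseg:::dilate_cross(b, 1)
  expect_true(all(band[tp$contour_mask == 1L]))
  # full-frame stroma: contour only at the frame border
  full <- structure(list(gland = matrix(FALSE, 8, 8),
                         stroma = matrix(TRUE, 8, 8),
                         white = matrix(FALSE, 8, 8)),
                    class = "tissue_partition")
  tf <- stroma_targets(full, thickness = 1)
  inner <- tf$contour_mask[2:7, 2:7]
  expect_equal(sum(inner), 0)
  expect_true(all(tf$contour_mask[1, ] == 1L))
  # empty stroma gives empty masks
  empty <- structure(list(gland = matrix(TRUE, 4, 4),
                          stroma = matrix(FALSE, 4, 4),
                          white = matrix(FALSE, 4, 4)),
                     class = "tissue_partition")
  te <- stroma_targets(empty)
  expect_equal(sum(te$object_mask) + sum(te$contour_mask), 0)
})
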
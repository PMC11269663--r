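test_that("tile plans give the expected 50%-overlap grids", {
  p <- plan_tiles(c(1024, 1024), 512)
  expect_equal(nrow(p$origins), 9)
  expect_equal(p$n_tiles_axis, c(3, 3))
  expect_equal(sort(unique(p$boundary_class)),
               c("corner", "edge", "interior"))
  expect_equal(sum(p$boundary_class == "corner"), 4)
  expect_equal(sum(p$boundary_class == "interior"), 1)

  expect_equal(nrow(plan_tiles(c(512, 512), 512)$origins), 1)
  expect_error(plan_tiles(c(512, 512), 511), class = "vs_config_error")
})

accumulate_weights <- function(plan) {
  acc <- matrix(0, plan$padded_dim[1], plan$padded_dim[2])
  for (i in seq_len(nrow(plan$origins))) {
    rr <- plan$origins$row[i] + seq_len(plan$patch_size)
    cc <- plan$origins$col[i] + seq_len(plan$patch_size)
    acc[rr, cc] <- acc[rr, cc] + make_weight_matrix(plan, i)
  }
  acc
}

test_that("blend weights form a partition of unity with smooth ramps", {
  sizes <- withr::with_seed(4, matrix(sample(32:140, 12), ncol = 2))
  for (i in seq_len(nrow(sizes))) {
    plan <- plan_tiles(sizes[i, ], 32)
    acc <- accumulate_weights(plan)
    expect_lt(max(abs(acc - 1)), 1e-6)
  }

  plan <- plan_tiles(c(96, 96), 32)   # 5 x 5 tiles of 32, stride 16
  # every interior pixel is covered by exactly 4 tiles
  cover <- matrix(0, 96, 96)
  for (i in seq_len(nrow(plan$origins))) {
    rr <- plan$origins$row[i] + 1:32; cc <- plan$origins$col[i] + 1:32
    cover[rr, cc] <- cover[rr, cc] + 1
  }
  expect_true(all(cover[17:80, 17:80] == 4))

  # corner tile keeps weight 1 at the canvas corner; ramps stay continuous
  w1 <- make_weight_matrix(plan, 1)
  expect_equal(w1[1, 1], 1)
  interior_idx <- which(plan$boundary_class == "interior")[1]
  wi <- make_weight_matrix(plan, interior_idx)
  expect_lte(max(abs(diff(wi[, 16]))), 2 / 32 + 1e-12)
  # opposing ramps of neighbouring interior tiles are complementary, and
  # the overlap midpoint splits the weight 0.5 / 0.5
  w1d <- virtualstain:::blend_window_1d(32, TRUE, TRUE)
  expect_equal(w1d[1:16] + w1d[17:32], rep(1, 16), tolerance = 1e-12)
  expect_equal(mean(w1d[8:9]), 0.5, tolerance = 1e-12)
})

test_that("stitching ground-truth crops reproduces the image", {
  p <- tissue_pair()
  img <- round(p$stained)
  plan <- plan_tiles(dim(img)[1:2], 64)
  tiles <- lapply(seq_len(nrow(plan$origins)), function(i)
    virtualstain:::crop_tile(img, plan$origins$row[i], plan$origins$col[i], 64))
  out <- stitch(tiles, plan)
  expect_lte(max(abs(out - img)), 1)

  # two constant tiles blend to a monotone ramp with midpoint 150
  plan2 <- plan_tiles(c(32, 48), 32)   # 1 x 2 tiles, overlap 16 wide
  t100 <- array(100, c(32, 32, 3)); t200 <- array(200, c(32, 32, 3))
  out2 <- stitch(list(t100, t200), plan2)
  prof <- out2[16, , 1]
  expect_true(all(diff(prof) >= 0))
  expect_equal(mean(prof[24:25]), 150, tolerance = 1)
  expect_true(all(prof[1:16] == 100) && all(prof[33:48] == 200))

  zero <- stitch(list(t100 * 0, t200 * 0), plan2)
  expect_true(all(zero == 0))
  expect_error(stitch(list(t100), plan2), class = "vs_input_error")
})

test_that("whole-slide translation with an identity stub is the identity", {
  p <- tissue_pair()
  img <- round(p$stained)
  out <- translate_whole_slide(function(tile) tile, img, patch_size = 64)
  expect_equal(dim(out), dim(img))
  expect_lte(max(abs(out - img)), 1)
})

test_that("blending removes seams that naive tiling leaves", {
  res <- shared_trained_fit()
  sets <- shared_training_data()
  slide <- array(0, c(64, 256, 3))       # a 64 x 256 strip "slide"
  for (k in 1:4) slide[, (k - 1) * 64 + 1:64, ] <- sets$eval_u[[k]]

  out <- translate_whole_slide(res$state, slide, patch_size = 64)
  expect_equal(dim(out), dim(slide))

  # naive stride = patch-size tiling of the same generator
  naive <- slide
  for (j in seq(1, 256, 64)) {
    tl <- slide[, j + 0:63, , drop = FALSE]
    naive[, j + 0:63, ] <-
      (generator_forward(res$state$g1, tl / 127.5 - 1) + 1) * 127.5
  }
  gray_b <- virtualstain:::rgb_to_gray(out)
  gray_n <- virtualstain:::rgb_to_gray(naive)
  border_cols <- c(64, 128, 192)         # naive tile borders
  border_grad <- function(g) max(abs(g[, border_cols + 1] - g[, border_cols]))
  grad_b <- abs(gray_b[, -1] - gray_b[, -256])
  p99 <- quantile(grad_b[, -c(border_cols - 1, border_cols, border_cols + 1)],
                  0.99)
  expect_lte(border_grad(gray_b), 1.5 * p99)
  expect_lte(border_grad(gray_b), border_grad(gray_n) + 1e-9)
})
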
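test_that("adaptive foreground segmentation finds tissue", {
  # uniform near-white image: nothing to segment
  blank <- array(250, c(128, 128, 3))
  fg0 <- segment_foreground(blank)
  expect_lt(fg0$foreground_fraction, 0.01)
  expect_identical(dim(fg0$mask), c(128L, 128L))

  # recovered fraction tracks the label map's tissue fraction
  p <- tissue_pair(seed = 31, cytoplasm_fraction = 0.30)
  fg <- segment_foreground(p$stained)
  expect_lt(abs(fg$foreground_fraction - mean(p$label > 0)), 0.05)

  expect_error(segment_foreground(blank, block_size = 50),
               class = "vs_config_error")
})

test_that("patch grids follow the overlap arithmetic", {
  g <- patch_grid(c(1024, 1024), 512, 256)
  expect_equal(nrow(g$origins), 9)
  expect_equal(g$padded_dim, c(1024L, 1024L))
  expect_equal(g$origins$row, rep(c(0L, 256L, 512L), each = 3))

  g1 <- patch_grid(c(512, 512), 512, 256)
  expect_equal(nrow(g1$origins), 1)

  # ragged sizes get padded up to the lattice
  g2 <- patch_grid(c(700, 600), 512, 256)
  expect_true(all(g2$padded_dim >= c(700, 600)))
  expect_equal((g2$padded_dim - 512) %% 256, c(0L, 0L))

  expect_error(patch_grid(c(512, 512), 256, 512), class = "vs_config_error")
})

test_that("patch extraction applies one grid to both images", {
  p <- tissue_pair()
  td <- tempfile()
  recs <- extract_patches(p$unstained, p$stained, td, "tp",
                          patch_size = 128, stride = 64)
  expect_equal(nrow(recs), 9)  # (256-128)/64+1 = 3 per axis
  # single full-size patch equals the image
  recs1 <- extract_patches(p$unstained, p$stained, tempfile(), "tp1",
                           patch_size = 256, stride = 256)
  expect_equal(nrow(recs1), 1)
  expect_equal(read_image(recs1$stained_patch_path[1]), round(p$stained),
               ignore_attr = TRUE)
  # same-origin patches cover identical coordinates
  i <- 5
  pu <- read_image(recs$unstained_patch_path[i])
  ps <- read_image(recs$stained_patch_path[i])
  rr <- recs$row[i] + 1:128; cc <- recs$col[i] + 1:128
  expect_equal(pu, round(p$unstained[rr, cc, ]), ignore_attr = TRUE)
  expect_equal(ps, round(p$stained[rr, cc, ]), ignore_attr = TRUE)
})

test_that("background patches are filtered by foreground fraction", {
  p <- tissue_pair()
  td <- tempfile()
  recs <- extract_patches(p$unstained, p$stained, td, "tp",
                          patch_size = 128, stride = 64)
  mask_true <- p$label > 0

  # oracle: per-patch tissue fraction straight from the label map
  expected <- vapply(seq_len(nrow(recs)), function(i)
    mean(mask_true[recs$row[i] + 1:128, recs$col[i] + 1:128]),
    numeric(1))

  kept <- filter_background_patches(recs, mask_true, 0.05, 128)
  expect_setequal(kept$unstained_patch_path,
                  recs$unstained_patch_path[expected >= 0.05])
  expect_equal(kept$foreground_fraction,
               expected[expected >= 0.05], tolerance = 1e-12)

  # all background -> nothing; all tissue -> everything
  none <- filter_background_patches(recs, mask_true & FALSE, 0.05, 128)
  expect_equal(nrow(none), 0)
  all_kept <- filter_background_patches(recs, mask_true | TRUE, 0.05, 128)
  expect_equal(nrow(all_kept), nrow(recs))

  # idempotent and order-independent
  twice <- filter_background_patches(kept, mask_true, 0.05, 128)
  expect_equal(twice, kept)
  shuf <- recs[rev(seq_len(nrow(recs))), ]
  kept_rev <- filter_background_patches(shuf, mask_true, 0.05, 128)
  expect_setequal(kept_rev$unstained_patch_path, kept$unstained_patch_path)
})

test_that("registration recovers identity and known misalignments", {
  p <- tissue_pair()
  reg0 <- register_pair(p$stained, p$stained)
  expect_lt(max(abs(reg0$transform$matrix - diag(3))), 1e-2)

  h_perturb <- homography_compose(
    homography_similarity(angle_deg = 3, center = c(127.5, 127.5)),
    homography_similarity(tx = 10, ty = -5))
  un_mis <- perturb_geometry(p$unstained, h_perturb, fill = 248)
  h_true <- homography_inverse(h_perturb)
  reg <- register_pair(un_mis, p$stained, seed = 5)
  corners <- rbind(c(0, 0), c(255, 0), c(0, 255), c(255, 255))
  err <- sqrt(rowSums((apply_homography(reg$transform, corners) -
                       apply_homography(h_true, corners))^2))
  expect_lt(mean(err), 2)
  expect_gte(reg$transform$inlier_count, 4)
  # warped output lives in the reference frame
  expect_equal(dim(reg$warped), dim(p$stained))
  expect_lt(mean(abs(reg$warped[60:200, 60:200, ] -
                     p$unstained[60:200, 60:200, ])), 6)
})

test_that("featureless pairs raise a registration failure", {
  flat <- array(250, c(128, 128, 3))
  err <- expect_error(register_pair(flat, flat, pair_id = "blank42"),
                      class = "vs_registration_error")
  expect_match(conditionMessage(err), "blank42")
  expect_error(register_pair(flat[1:64, 1:64, ], flat),
               class = "vs_input_error")
})
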
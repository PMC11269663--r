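test_that("generation is a pure function of spec and seed", {
  spec <- synthetic_tissue_spec(96, 96, seed = 11)
  g1 <- generate_unstained_image(spec)
  g2 <- generate_unstained_image(spec)
  expect_identical(g1, g2)
  st1 <- apply_stain_oracle(g1$image, g1$label_map, stain_oracle())
  st2 <- apply_stain_oracle(g2$image, g2$label_map, stain_oracle())
  expect_identical(st1, st2)
  # the generator must not disturb the caller's RNG
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_unstained_image(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("nucleus density controls nucleus placement", {
  spec0 <- synthetic_tissue_spec(96, 96, nucleus_density = 0, seed = 3)
  g0 <- generate_unstained_image(spec0)
  expect_false(any(g0$label_map == 2L))

  spec <- synthetic_tissue_spec(512, 512, nucleus_density = 5, seed = 5)
  g <- generate_unstained_image(spec)
  lambda <- 5 * 512 * 512 / 1e4
  interval <- qpois(c(0.005, 0.995), lambda)
  n <- nrow(g$nucleus_centers)
  expect_gte(n, interval[1])
  expect_lte(n, interval[2])
  expect_true(any(g$label_map == 2L))
})

test_that("unstained images are faint and grayscale-like", {
  p <- tissue_pair()
  expect_equal(dim(p$unstained), c(256, 256, 3))
  expect_identical(dim(p$label), c(256L, 256L))
  # channels equal up to noise replication; luminance compressed high
  expect_identical(p$unstained[, , 1], p$unstained[, , 2])
  expect_gte(min(p$unstained), 150)
  # tissue darker than background, but faintly
  expect_lt(mean(p$unstained[, , 1][p$label > 0]),
            mean(p$unstained[, , 1][p$label == 0]))
})

test_that("stain oracle recolours class-conditionally", {
  oracle <- stain_oracle()
  # all-background map: exact background colour everywhere
  img <- array(246, c(64, 64, 3))
  lab <- matrix(0L, 64, 64)
  out <- apply_stain_oracle(img, lab, oracle)
  for (ch in 1:3)
    expect_lte(max(abs(out[, , ch] - oracle$background_rgb[ch])), 2)

  # constant-luminance pure-nucleus interior: hue equals nucleus hue
  lab2 <- matrix(2L, 64, 64)
  img2 <- array(230, c(64, 64, 3))
  out2 <- apply_stain_oracle(img2, lab2, oracle)
  px <- out2[32, 32, ]
  expect_equal(px / sqrt(sum(px^2)),
               oracle$nucleus_rgb / sqrt(sum(oracle$nucleus_rgb^2)),
               tolerance = 1e-6)

  # shape mismatch is an input error
  expect_error(apply_stain_oracle(img, matrix(0L, 32, 32), oracle),
               class = "vs_input_error")
  # oracle validation
  expect_error(stain_oracle(background_rgb = c(200, 246, 246)),
               class = "vs_config_error")
})

test_that("geometric perturbation matches the homography definition", {
  p <- tissue_pair()
  img <- p$stained
  expect_equal(perturb_geometry(img, homography_identity()), img,
               tolerance = 1e-12, ignore_attr = TRUE)

  h <- homography_similarity(tx = 10, ty = -5)
  warped <- perturb_geometry(img, h, fill = 0)
  # pixel (y, x) of the input lands at (y - 5, x + 10) in the output
  expect_equal(warped[100 - 5, 100 + 10, ], img[100, 100, ],
               ignore_attr = TRUE)

  # warp by H then H^-1 loses only interpolation
  h2 <- withr::with_seed(1, virtualstain:::random_mild_homography(256, 256))
  round_trip <- perturb_geometry(perturb_geometry(img, h2, fill = 248),
                                 homography_inverse(h2), fill = 248)
  interior <- 40:216
  expect_lt(mean(abs(round_trip[interior, interior, ] -
                     img[interior, interior, ])), 3)

  expect_error(homography(matrix(0, 3, 3)), class = "vs_input_error")
})

test_that("paired datasets are complete, aligned and reproducible", {
  spec <- synthetic_tissue_spec(96, 96, seed = 21)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  m1 <- build_paired_dataset(spec, stain_oracle(), 3, misalign = FALSE,
                             out_dir = d1)
  expect_equal(nrow(m1), 3)
  expect_true(all(file.exists(m1$unstained_path, m1$stained_path,
                              m1$label_path)))
  # identity homography recorded when not misaligned
  hom_cols <- paste0("h", rep(1:3, each = 3), rep(1:3, 3))
  expect_equal(unname(as.matrix(m1[, hom_cols])),
               matrix(rep(as.numeric(t(diag(3))), each = 3), nrow = 3))

  m2 <- build_paired_dataset(spec, stain_oracle(), 3, misalign = FALSE,
                             out_dir = d2)
  expect_equal(unname(tools::md5sum(m2$unstained_path)),
               unname(tools::md5sum(m1$unstained_path)))
  expect_identical(gsub(d1, "", readLines(file.path(d1, "manifest.csv")),
                        fixed = TRUE),
                   gsub(d2, "", readLines(file.path(d2, "manifest.csv")),
                        fixed = TRUE))

  # label maps survive the PNG round trip
  lab <- read_label_map(m1$label_path[1])
  expect_true(all(lab %in% 0:2))

  # misaligned datasets record the aligning homography
  m3 <- build_paired_dataset(spec, stain_oracle(), 1, misalign = TRUE,
                             out_dir = file.path(tempfile(), "c"))
  expect_gt(max(abs(as.numeric(m3[1, hom_cols]) - as.numeric(t(diag(3))))),
            1e-4)
})
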
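rand_images <- function(n, seed, size = 32) {
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    array(runif(size * size * 3, 0, 255), c(size, size, 3))))
}

test_that("the toy extractor is deterministic with the declared dimension", {
  ex <- toy_extractor(d = 16)
  imgs <- rand_images(10, 1)
  f <- extract_features(imgs, ex)
  expect_equal(dim(f), c(10, 16))
  expect_identical(extract_features(imgs, ex), f)
  expect_identical(extract_features(imgs[3], ex)[1, ], f[3, ])
  err <- expect_error(extract_features(imgs, inception_extractor()),
                      class = "vs_config_error")
  expect_match(conditionMessage(err), "toy_extractor")
})

test_that("Frechet distance matches its closed forms", {
  d <- 8
  base <- list(mean = rep(0, d), covariance = diag(d), n = 100,
               extractor_id = "x")
  class(base) <- "feature_distribution"
  expect_equal(frechet_distance(base, base), 0, tolerance = 1e-6)

  shifted <- base; shifted$mean <- c(2, rep(0, d - 1))
  expect_equal(frechet_distance(base, shifted), 4, tolerance = 1e-6)

  # diagonal covariances: sum((sqrt(sa) - sqrt(sb))^2) + ||dmu||^2
  withr::with_seed(3, {
    sa <- runif(d, 0.5, 2); sb <- runif(d, 0.5, 2)
    mua <- rnorm(d); mub <- rnorm(d)
  })
  da <- base; da$mean <- mua; da$covariance <- diag(sa)
  db <- base; db$mean <- mub; db$covariance <- diag(sb)
  closed <- sum((sqrt(sa) - sqrt(sb))^2) + sum((mua - mub)^2)
  expect_equal(frechet_distance(da, db, jitter = 0), closed,
               tolerance = 1e-8)
  expect_equal(frechet_distance(db, da, jitter = 0),
               frechet_distance(da, db, jitter = 0), tolerance = 1e-8)

  dc <- db; dc$extractor_id <- "y"
  expect_error(frechet_distance(da, dc), class = "vs_input_error")
})

test_that("FID falls as one Gaussian's mean approaches the other's", {
  d <- 6
  withr::with_seed(5, {
    a <- matrix(rnorm(400 * d), 400, d)
    b <- matrix(rnorm(400 * d, mean = 2), 400, d)
  })
  da <- feature_distribution(a, "x")
  fids <- vapply(c(0, 0.5, 1), function(t) {
    shifted <- sweep(b, 2, t * (da$mean - colMeans(b)), "+")
    frechet_distance(da, feature_distribution(shifted, "x"))
  }, numeric(1))
  expect_true(all(diff(fids) < 0))
})

test_that("KID matches a double-loop MMD oracle and is null-centred", {
  # explicit O(n^2) oracle at n = 4, d = 3
  withr::with_seed(11, {
    xa <- matrix(rnorm(12), 4, 3)
    xb <- matrix(rnorm(12), 4, 3)
  })
  kf <- function(x, y) (sum(x * y) / 3 + 1)^3
  sxx <- 0; syy <- 0; sxy <- 0
  for (i in 1:4) for (j in 1:4) {
    if (i != j) {
      sxx <- sxx + kf(xa[i, ], xa[j, ])
      syy <- syy + kf(xb[i, ], xb[j, ])
    }
    sxy <- sxy + kf(xa[i, ], xb[j, ])
  }
  oracle <- sxx / 12 + syy / 12 - 2 * sxy / 16
  k <- kid(xa, xb, subset_size = 4, n_subsets = 1, seed = 2)
  expect_equal(k$kid_mean, oracle, tolerance = 1e-10)

  # kernel value at the origin
  expect_equal(virtualstain:::poly_kernel(matrix(0, 1, 3),
                                          matrix(0, 1, 3))[1, 1], 1)

  # unbiasedness: same 16-d Gaussian on both sides
  withr::with_seed(13, {
    ga <- matrix(rnorm(1000 * 16), 1000, 16)
    gb <- matrix(rnorm(1000 * 16), 1000, 16)
  })
  k2 <- kid(ga, gb, subset_size = 100, n_subsets = 10, seed = 3)
  expect_lt(abs(k2$kid_mean), 0.01)
  expect_gte(k2$kid_std, 0)

  expect_error(kid(xa, xb, subset_size = 1), class = "vs_config_error")
  expect_error(kid(xa, xb, subset_size = 10), class = "vs_input_error")
})

test_that("evaluate_sets orders fixture comparisons sensibly", {
  sets <- shared_training_data()
  root <- tempfile()
  dirs <- list(s1 = file.path(root, "s1"), s2 = file.path(root, "s2"),
               u = file.path(root, "u"))
  for (d in dirs) dir.create(d, recursive = TRUE)
  n <- length(sets$eval_s)
  half <- seq_len(n %/% 2)
  for (i in half) {
    write_image(sets$eval_s[[i]], file.path(dirs$s1, sprintf("%02d.png", i)))
    write_image(sets$eval_s[[n %/% 2 + i]],
                file.path(dirs$s2, sprintf("%02d.png", i)))
    write_image(sets$eval_u[[i]], file.path(dirs$u, sprintf("%02d.png", i)))
  }
  ex <- toy_extractor(d = 16)
  same <- evaluate_sets(dirs$s1, dirs$s2, ex, seed = 1)
  cross <- evaluate_sets(dirs$s1, dirs$u, ex, seed = 1)
  # two halves of the stained set are far closer than stained vs unstained
  expect_lt(same$fid, cross$fid)
  expect_lt(same$kid_mean, cross$kid_mean)
  expect_equal(same$extractor_id, ex$id)
  expect_equal(same$n_a, length(half))

  rp <- file.path(root, "report.json")
  evaluate_sets(dirs$s1, dirs$s2, ex, seed = 1, report_path = rp)
  expect_true(file.exists(rp))
  empty <- file.path(root, "empty"); dir.create(empty)
  expect_error(evaluate_sets(dirs$s1, empty, ex), class = "vs_input_error")
})

test_that("the trained translator moves unstained images toward the stain", {
  res <- shared_trained_fit()
  sets <- shared_training_data()
  ex <- toy_extractor(d = 16)
  translated <- translate_images(res$state, sets$eval_u)
  fid_trans <- fid_between(sets$eval_s, translated, ex)
  fid_unst <- fid_between(sets$eval_s, sets$eval_u, ex)
  expect_lt(fid_trans, fid_unst)
})
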
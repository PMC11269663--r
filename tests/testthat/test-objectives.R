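unit <- function(v) v / sqrt(sum(v^2))
rand_unit_rows <- function(n, k) {
  m <- matrix(rnorm(n * k), n, k)
  m / sqrt(rowSums(m^2))
}

# direct-exponentiation oracle for the contrastive cross-entropy
nce_oracle <- function(v, vp, neg, tau) {
  s <- function(a, b) sum(a * b) / sqrt(sum(a^2)) / sqrt(sum(b^2))
  num <- exp(s(v, vp) / tau)
  den <- num
  if (nrow(neg) > 0)
    for (i in seq_len(nrow(neg))) den <- den + exp(s(v, neg[i, ]) / tau)
  -log(num / den)
}

test_that("cosine similarity matches its definition", {
  u <- c(3, 4, 0)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(-1, 0)), -1)
  expect_error(cosine_similarity(c(0, 0), u[1:2]), class = "vs_input_error")
})

test_that("contrastive cross-entropy matches closed forms and the oracle", {
  v <- unit(c(1, 2, 3, 4, 5, 6, 7, 8))
  # no negatives, query equals positive: perfect (N+1)=1 classification
  expect_equal(nce_cross_entropy(nce_batch(v, v, temperature = 1)), 0)
  # one orthogonal negative at tau = 1: -log(e / (e + 1)) = log(1 + e^-1)
  northo <- unit(c(-2, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(nce_cross_entropy(nce_batch(v, v, rbind(northo), 1)),
               log(1 + exp(-1)), tolerance = 1e-9)

  withr::with_seed(101, {
    for (rep in 1:50) {
      q <- rand_unit_rows(1, 8)[1, ]
      p <- rand_unit_rows(1, 8)[1, ]
      neg <- rand_unit_rows(7, 8)
      expect_equal(nce_cross_entropy(nce_batch(q, p, neg, 0.07)),
                   nce_oracle(q, p, neg, 0.07), tolerance = 1e-6)
    }
  })

  # strictly positive whenever there is at least one negative
  expect_gt(nce_cross_entropy(nce_batch(v, v, rbind(v), 0.07)), 0)
  expect_error(nce_batch(v, v, temperature = 0), class = "vs_config_error")
})

test_that("contrastive loss is monotone in the similarities", {
  base <- diag(8)[1, ]
  neg <- rbind(diag(8)[2, ])
  mix <- function(a) unit(a * base + (1 - a) * diag(8)[3, ])
  # raising sim(query, positive) lowers the loss
  l <- vapply(c(0.2, 0.5, 0.9), function(a)
    nce_cross_entropy(nce_batch(base, mix(a), neg, 0.2)), numeric(1))
  expect_true(all(diff(l) < 0))
  # raising sim(query, negative) raises the loss
  l2 <- vapply(c(0.2, 0.5, 0.9), function(a)
    nce_cross_entropy(nce_batch(base, diag(8)[4, ], rbind(mix(a)), 0.2)),
    numeric(1))
  expect_true(all(diff(l2) > 0))
  # stable down to very low temperature
  expect_true(is.finite(nce_cross_entropy(
    nce_batch(base, mix(0.7), neg, 0.01))))
})

make_stack <- function(vectors, locations = NULL) {
  if (is.null(locations))
    locations <- setNames(lapply(vectors, function(v) seq_len(nrow(v))),
                          names(vectors))
  structure(list(layer_ids = names(vectors),
                 locations = locations,
                 vectors = vectors,
                 channel_dims = vapply(vectors, ncol, integer(1))),
            class = "embedding_stack")
}

test_that("PatchNCE equals the per-location loop oracle", {
  withr::with_seed(7, {
    zs <- list("0" = rand_unit_rows(4, 6), "2" = rand_unit_rows(4, 6))
    zh <- list("0" = rand_unit_rows(4, 6), "2" = rand_unit_rows(4, 6))
  })
  inp <- make_stack(zs); out <- make_stack(zh)

  oracle <- mean(vapply(names(zs), function(l) {
    mean(vapply(1:4, function(s)
      nce_oracle(zh[[l]][s, ], zs[[l]][s, ], zs[[l]][-s, , drop = FALSE], 1),
      numeric(1)))
  }, numeric(1)))
  expect_equal(patchnce_loss("A2B", inp, out, temperature = 1), oracle,
               tolerance = 1e-6)

  # identical stacks: same oracle, evaluated on sims of the stack with itself
  oracle_self <- mean(vapply(names(zs), function(l)
    mean(vapply(1:4, function(s)
      nce_oracle(zs[[l]][s, ], zs[[l]][s, ], zs[[l]][-s, , drop = FALSE], 1),
      numeric(1))), numeric(1)))
  expect_equal(patchnce_loss("A2B", inp, inp, temperature = 1), oracle_self,
               tolerance = 1e-6)

  # one layer, one location, no negatives, identical stacks: exactly zero
  one <- make_stack(list("0" = rand_unit_rows(1, 6)))
  expect_equal(patchnce_loss("B2A", one, one), 0)

  # consistent permutation of locations leaves the loss unchanged
  perm <- c(3, 1, 4, 2)
  permute <- function(st) make_stack(lapply(st$vectors, function(v)
    v[perm, , drop = FALSE]), st$locations)
  expect_equal(patchnce_loss("A2B", permute(inp), permute(out), 1),
               patchnce_loss("A2B", inp, out, 1), tolerance = 1e-12)

  # mismatched locations are an input error
  bad <- make_stack(zh, setNames(lapply(zs, function(v) 4 + seq_len(nrow(v))),
                                 names(zs)))
  expect_error(patchnce_loss("A2B", inp, bad), class = "vs_input_error")
})

test_that("adversarial losses match their closed forms", {
  ones <- matrix(1, 2, 2); zeros <- matrix(0, 2, 2); half <- matrix(0.5, 2, 2)
  perfect <- adversarial_losses("A2B", ones, zeros, "log")
  expect_equal(perfect$d_loss, 0, tolerance = 1e-9)
  undecided <- adversarial_losses("A2B", half, half, "log")
  expect_equal(undecided$d_loss, log(2), tolerance = 1e-9)
  expect_equal(undecided$g_loss, log(2), tolerance = 1e-9)
  ls <- adversarial_losses("B2A", ones, zeros, "lsgan")
  expect_equal(ls$d_loss, 0)
  expect_equal(ls$g_loss, 1)
  expect_error(adversarial_losses("A2B", ones, zeros, "wasserstein"),
               class = "vs_config_error")
})

test_that("identity loss is the sum of the two L1 deviations", {
  a <- withr::with_seed(1, array(runif(48 * 48 * 3, -1, 1), c(48, 48, 3)))
  b <- withr::with_seed(2, array(runif(48 * 48 * 3, -1, 1), c(48, 48, 3)))
  expect_equal(identity_loss(function(x) x, function(x) x, a, b), 0)
  expect_equal(identity_loss(function(x) x, function(x) x + 0.1, a, b), 0.1,
               tolerance = 1e-12)
  # joint channel permutation of inputs leaves the loss unchanged for
  # channel-equivariant generators
  pc <- function(x) x[, , c(2, 3, 1)]
  damp <- function(x) 0.5 * x
  expect_equal(identity_loss(damp, damp, pc(a), pc(b)),
               identity_loss(damp, damp, a, b), tolerance = 1e-12)
  expect_error(identity_loss(function(x) x, function(x) x, a, b[1:24, , ]),
               class = "vs_input_error")
})

test_that("the collective objective combines components with the stated weights", {
  comp <- list(gan1 = 0.6, gan2 = 0.4, nce_a = 0.3, nce_b = 0.2, idt = 0.5)
  expect_identical(total_objective(comp, loss_weights(1, 2, 1)), 2.5)
  expect_equal(total_objective(list(gan1 = 0, gan2 = 0, nce_a = 0,
                                    nce_b = 0, idt = 0)), 0)
  # doubling lambda_nce doubles only the NCE contribution
  base <- total_objective(comp, loss_weights(1, 2, 1))
  doubled <- total_objective(comp, loss_weights(1, 4, 1))
  expect_equal(doubled - base, 2 * (comp$nce_a + comp$nce_b))
  expect_error(total_objective(list(gan1 = 0.1, gan2 = NaN, nce_a = 0,
                                    nce_b = 0, idt = 0)),
               class = "vs_numeric_error")
  expect_error(loss_weights(lambda_gan = -1), class = "vs_config_error")
})

test_that("the tape-based PatchNCE agrees with the numeric route", {
  gen <- build_generator(tiny_preset()$generator, seed = 3)
  x <- withr::with_seed(5, array(runif(64 * 64 * 3, -1, 1), c(64, 64, 3)))
  y <- generator_forward(gen, x)
  feats_x <- encoder_features(gen, x)
  feats_y <- encoder_features(gen, y)
  cd <- vapply(feats_x, `[[`, integer(1), "channels")
  ha <- projection_head(cd, 32, 32, seed = 7)
  hb <- projection_head(cd, 32, 32, seed = 8)
  sx <- sample_and_project(feats_x, 32, ha, seed = 11)
  sy <- sample_and_project(feats_y, 32, hb, locations = sx$locations)
  numeric_loss <- patchnce_loss("A2B", sx, sy, temperature = 0.07)

  tp <- virtualstain:::tape_new()
  zh <- lapply(sy$vectors, function(v) virtualstain:::op_const(tp, v))
  zz <- lapply(sx$vectors, function(v) virtualstain:::op_const(tp, v))
  tape_loss <- virtualstain:::nce_node(tp, zh, zz, 0.07)$val
  expect_equal(tape_loss, numeric_loss, tolerance = 1e-10)
})
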
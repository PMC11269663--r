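# Stage 2: the dual-mapping optimisation loop.  Each step updates the two
# discriminators on detached translations, then jointly updates both
# generators and both projection heads against the collective objective.
# All randomness (initialisation, batch order, location sampling) is a
# pure function of the configured seed, so runs are reproducible and a
# restored checkpoint continues bit-exactly.

#' Training configuration
#'
#' @param iterations number of optimisation steps (>= 1).
#' @param batch_size images per domain per step.
#' @param learning_rate Adam learning rate.
#' @param beta1,beta2 Adam moment decays.
#' @param seed master seed fixing initialisation, batch order and location
#'   sampling.
#' @param checkpoint_every checkpoint cadence in iterations.
#' @param image_size expected square patch size in pixels.
#' @param weights a [loss_weights()].
#' @param adversarial `"log"` (cross-entropy, non-saturating generator
#'   update) or `"lsgan"` (least squares).
#' @param model list with `generator`, `discriminator` configs plus
#'   `n_locations`, `embed_dim`, `head_hidden`; defaults to [tiny_preset()].
#' @export
train_config <- function(iterations = 1000L, batch_size = 1L,
                         learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                         seed = 1L, checkpoint_every = 500L,
                         image_size = 64L, weights = loss_weights(),
                         adversarial = c("log", "lsgan"),
                         model = tiny_preset()) {
  adversarial <- match.arg(adversarial)
  if (iterations < 1) vs_config_error("iterations must be >= 1")
  if (batch_size < 1) vs_config_error("batch_size must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 image_size = as.integer(image_size), weights = weights,
                 adversarial = adversarial, model = model),
            class = "train_config")
}

# channel dims of the default encoder taps, keyed like gen_forward_tape taps
tap_channel_dims <- function(gcfg) {
  f <- gcfg$base_channels; nd <- gcfg$n_downsamples
  ids <- c(0L, 1L, 1L + seq_len(nd),
           1L + nd + max(1L, (gcfg$n_resnet_blocks + 1L) %/% 2L))
  ch <- c(3L, f, f * 2L^seq_len(nd), f * 2L^nd)
  setNames(as.integer(ch), as.character(unique(ids)))[as.character(unique(ids))]
}

#' Initialise a training state
#'
#' Builds both generators, both discriminators and both projection heads
#' with seeds derived from the configuration seed.
#'
#' @param config a [train_config()].
#' @return a `train_state` (mutable; parameters are environments).
#' @export
init_train_state <- function(config) {
  m <- config$model
  cd <- tap_channel_dims(m$generator)
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$g1 <- build_generator(m$generator, seed = config$seed + 11L)
  st$g2 <- build_generator(m$generator, seed = config$seed + 12L)
  st$da <- build_discriminator(m$discriminator, seed = config$seed + 13L)
  st$db <- build_discriminator(m$discriminator, seed = config$seed + 14L)
  st$ha <- projection_head(cd, m$embed_dim, m$head_hidden,
                           seed = config$seed + 15L)
  st$hb <- projection_head(cd, m$embed_dim, m$head_hidden,
                           seed = config$seed + 16L)
  st$layer_ids <- as.integer(names(cd))
  st$iter <- 0L
  st$t_g <- 0L; st$t_d <- 0L
  class(st) <- "train_state"
  st
}

as_input_node <- function(tp, img) {
  d <- dim(img)
  op_input(tp, t(matrix(img, d[1] * d[2], 3)), H = d[1], W = d[2])
}

# adversarial loss nodes from logits, matching adversarial_losses()
adv_d_node <- function(tp, logits_real, logits_fake, form) {
  if (form == "log") {
    op_weighted_sum(tp, list(op_softplus_mean(tp, logits_real, -1),
                             op_softplus_mean(tp, logits_fake, 1)),
                    c(0.5, 0.5))
  } else {
    op_weighted_sum(tp, list(op_mean_sq(tp, logits_real, 1),
                             op_mean_sq(tp, logits_fake, 0)),
                    c(0.5, 0.5))
  }
}

adv_g_node <- function(tp, logits_fake, form) {
  if (form == "log") op_softplus_mean(tp, logits_fake, -1)
  else op_mean_sq(tp, logits_fake, 1)
}

nce_node <- function(tp, zhat_nodes, z_nodes, tau) {
  per_layer <- mapply(function(zh, z) op_patch_nce(tp, zh, z, tau),
                      zhat_nodes, z_nodes, SIMPLIFY = FALSE)
  op_weighted_sum(tp, per_layer, rep(1 / length(per_layer),
                                     length(per_layer)))
}

iter_seed <- function(config, iter, stream) {
  (config$seed * 7919L + iter * 13L + stream) %% 2147483587L
}

#' One optimisation step
#'
#' Updates `D_A` and `D_B` on detached translations, then jointly updates
#' `G1`, `G2`, `H_A` and `H_B` against the collective objective.
#'
#' @param state a `train_state` from [init_train_state()] (modified in
#'   place).
#' @param batch list with `a` and `b`: lists of H x W x 3 arrays in
#'   `[-1, 1]` from the unstained (A) and stained (B) domains.
#' @return named numeric loss record: `iter, d_A, d_B, g_adv_1, g_adv_2,
#'   nce_A, nce_B, idt, total`.
#' @export
train_step <- function(state, batch) {
  cfg <- state$config
  form <- cfg$adversarial
  tau <- cfg$weights$temperature
  state$iter <- state$iter + 1L
  if (length(batch$a) != length(batch$b))
    vs_input_error("train_step needs equal counts from both domains")

  d_params <- c(disc_params(state$da), disc_params(state$db))
  g_params <- c(gen_params(state$g1), gen_params(state$g2),
                head_params(state$ha), head_params(state$hb))

  acc <- c(d_A = 0, d_B = 0, g_adv_1 = 0, g_adv_2 = 0,
           nce_A = 0, nce_B = 0, idt = 0, total = 0)
  nb <- length(batch$a)

  # ---- discriminator update -------------------------------------------------
  fakes_b <- lapply(batch$a, function(a) generator_forward(state$g1, a))
  fakes_a <- lapply(batch$b, function(b) generator_forward(state$g2, b))
  param_zero_grads(d_params)
  tp <- tape_new()
  d_nodes <- list()
  for (i in seq_len(nb)) {
    la_r <- disc_forward_tape(tp, state$da, as_input_node(tp, batch$a[[i]]))
    la_f <- disc_forward_tape(tp, state$da, as_input_node(tp, fakes_a[[i]]))
    lb_r <- disc_forward_tape(tp, state$db, as_input_node(tp, batch$b[[i]]))
    lb_f <- disc_forward_tape(tp, state$db, as_input_node(tp, fakes_b[[i]]))
    da_l <- adv_d_node(tp, la_r, la_f, form)
    db_l <- adv_d_node(tp, lb_r, lb_f, form)
    d_nodes[[i]] <- op_weighted_sum(tp, list(da_l, db_l), c(1, 1) / nb)
    acc["d_A"] <- acc["d_A"] + da_l$val / nb
    acc["d_B"] <- acc["d_B"] + db_l$val / nb
  }
  d_total <- op_weighted_sum(tp, d_nodes, rep(1, nb))
  tape_backward(tp, d_total)
  state$t_d <- state$t_d + 1L
  adam_step(d_params, cfg$learning_rate, cfg$beta1, cfg$beta2, t = state$t_d)

  # ---- generator + head update ---------------------------------------------
  param_zero_grads(c(g_params, d_params))
  tp <- tape_new()
  taps <- state$layer_ids
  enc_d <- encoder_depth(state$g1)
  g_nodes <- list()
  for (i in seq_len(nb)) {
    a_nd <- as_input_node(tp, batch$a[[i]])
    b_nd <- as_input_node(tp, batch$b[[i]])
    f1 <- gen_forward_tape(tp, state$g1, a_nd, taps = taps)   # G1(a), G1enc(a)
    f2 <- gen_forward_tape(tp, state$g2, b_nd, taps = taps)   # G2(b), G2enc(b)
    e_fb <- gen_forward_tape(tp, state$g2, f1$out, taps = taps,
                             upto = enc_d)$taps               # G2enc(G1(a))
    e_fa <- gen_forward_tape(tp, state$g1, f2$out, taps = taps,
                             upto = enc_d)$taps               # G1enc(G2(b))

    spa <- sample_project_tape(tp, f1$taps, state$ha, cfg$model$n_locations,
                               seed = iter_seed(cfg, state$iter, 100L + i))
    spa_hat <- sample_project_tape(tp, e_fb, state$hb, cfg$model$n_locations,
                                   locations = spa$locations)
    spb <- sample_project_tape(tp, f2$taps, state$hb, cfg$model$n_locations,
                               seed = iter_seed(cfg, state$iter, 200L + i))
    spb_hat <- sample_project_tape(tp, e_fa, state$ha, cfg$model$n_locations,
                                   locations = spb$locations)
    nce_a <- nce_node(tp, spa_hat$nodes, spa$nodes, tau)
    nce_b <- nce_node(tp, spb_hat$nodes, spb$nodes, tau)

    g1_adv <- adv_g_node(tp, disc_forward_tape(tp, state$db, f1$out), form)
    g2_adv <- adv_g_node(tp, disc_forward_tape(tp, state$da, f2$out), form)

    id_b <- gen_forward_tape(tp, state$g1, b_nd)$out          # G1(b) ~ b
    id_a <- gen_forward_tape(tp, state$g2, a_nd)$out          # G2(a) ~ a
    idt <- op_weighted_sum(tp, list(op_mean_abs_diff(tp, id_a, a_nd),
                                    op_mean_abs_diff(tp, id_b, b_nd)),
                           c(1, 1))

    w <- cfg$weights
    tot <- op_weighted_sum(tp, list(g1_adv, g2_adv, nce_a, nce_b, idt),
                           c(w$lambda_gan, w$lambda_gan, w$lambda_nce,
                             w$lambda_nce, w$lambda_idt))
    g_nodes[[i]] <- tot
    for (k in c("g_adv_1", "g_adv_2", "nce_A", "nce_B", "idt", "total")) {
      v <- switch(k, g_adv_1 = g1_adv$val, g_adv_2 = g2_adv$val,
                  nce_A = nce_a$val, nce_B = nce_b$val, idt = idt$val,
                  total = tot$val)
      acc[k] <- acc[k] + v / nb
    }
  }
  g_total <- op_weighted_sum(tp, g_nodes, rep(1 / nb, nb))
  if (!all(is.finite(acc)))
    vs_numeric_error(paste0("non-finite loss at iteration ", state$iter, ": ",
                            paste(names(acc)[!is.finite(acc)], collapse = ", ")),
                     record = acc)
  tape_backward(tp, g_total)
  state$t_g <- state$t_g + 1L
  adam_step(g_params, cfg$learning_rate, cfg$beta1, cfg$beta2, t = state$t_g)
  param_zero_grads(d_params)  # discriminator grads from the G pass are unused

  c(iter = state$iter, acc)
}

#' Load a directory of patches into model space
#' @param dir directory of PNG patches.
#' @return list of H x W x 3 arrays in `[-1, 1]`.
#' @export
load_patch_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0)
    vs_input_error(paste0("no PNG patches found in ", dir))
  lapply(files, function(f) read_image(f) / 127.5 - 1)
}

#' Train the dual contrastive model
#'
#' Batches are drawn unpaired: the two domains are shuffled independently
#' each epoch, so the optimiser never sees pixel correspondences even when
#' the underlying dataset is paired.
#'
#' @param config a [train_config()].
#' @param unstained_dir,stained_dir directories of training patches.
#' @param out_dir output directory for checkpoints and the loss history.
#' @param quiet suppress progress lines?
#' @return list with `state`, `history` (data frame, one row per
#'   iteration, also written to `loss_history.csv`) and `checkpoint_path`.
#' @export
fit <- function(config, unstained_dir, stained_dir,
                out_dir = tempfile("vstrain"), quiet = TRUE) {
  imgs_a <- load_patch_dir(unstained_dir)
  imgs_b <- load_patch_dir(stained_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- init_train_state(config)
  history <- run_iterations(state, imgs_a, imgs_b, config$iterations,
                            out_dir, quiet)
  hist_df <- as.data.frame(do.call(rbind, history))
  write.csv(hist_df, file.path(out_dir, "loss_history.csv"),
            row.names = FALSE)
  ckpt <- file.path(out_dir, "checkpoint_final.rds")
  save_checkpoint(state, ckpt)
  list(state = state, history = hist_df, checkpoint_path = ckpt)
}

# draw the (a, b) index pair for a given iteration: independent per-domain
# epoch shuffles, derived deterministically from the config seed
batch_indices <- function(config, iter, n_a, n_b, bs) {
  idx <- function(n, stream) {
    k <- (iter - 1L) * bs
    epoch <- k %/% n
    off <- k %% n
    ord <- with_seed(iter_seed(config, epoch, stream), sample.int(n))
    ord[(off + seq_len(bs) - 1L) %% n + 1L]
  }
  list(a = idx(n_a, 301L), b = idx(n_b, 302L))
}

run_iterations <- function(state, imgs_a, imgs_b, n_iter, out_dir,
                           quiet = TRUE) {
  cfg <- state$config
  bs <- cfg$batch_size
  history <- vector("list", n_iter)
  for (k in seq_len(n_iter)) {
    ib <- batch_indices(cfg, state$iter + 1L, length(imgs_a),
                        length(imgs_b), bs)
    rec <- train_step(state, list(a = imgs_a[ib$a], b = imgs_b[ib$b]))
    history[[k]] <- rec
    if (!quiet && state$iter %% 50L == 0L)
      message(sprintf("iter %d  total %.4f", state$iter, rec[["total"]]))
    if (!is.null(out_dir) && cfg$checkpoint_every > 0L &&
        state$iter %% cfg$checkpoint_every == 0L)
      save_checkpoint(state, file.path(out_dir,
                                       sprintf("checkpoint_%06d.rds",
                                               state$iter)))
  }
  history
}

#' Save a training checkpoint
#'
#' Stores all six component weights, the Adam state, the configuration and
#' the iteration counters; [load_checkpoint()] restores it bit-exactly.
#' @param state a `train_state`.
#' @param path output `.rds` path.
#' @export
save_checkpoint <- function(state, path) {
  grab <- function(params) lapply(params, function(p)
    list(val = p$val, m = p$m, v = p$v))
  saveRDS(list(config = state$config, iter = state$iter,
               t_g = state$t_g, t_d = state$t_d,
               g1 = grab(gen_params(state$g1)),
               g2 = grab(gen_params(state$g2)),
               da = grab(disc_params(state$da)),
               db = grab(disc_params(state$db)),
               ha = grab(head_params(state$ha)),
               hb = grab(head_params(state$hb))),
          path)
  invisible(path)
}

#' Restore a training checkpoint
#' @param path path written by [save_checkpoint()].
#' @return a `train_state` identical to the saved one.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) vs_io_error(paste0("checkpoint not found: ", path))
  ck <- readRDS(path)
  state <- init_train_state(ck$config)
  put <- function(params, saved) {
    for (i in seq_along(params)) {
      params[[i]]$val <- saved[[i]]$val
      params[[i]]$m <- saved[[i]]$m
      params[[i]]$v <- saved[[i]]$v
    }
  }
  put(gen_params(state$g1), ck$g1); put(gen_params(state$g2), ck$g2)
  put(disc_params(state$da), ck$da); put(disc_params(state$db), ck$db)
  put(head_params(state$ha), ck$ha); put(head_params(state$hb), ck$hb)
  state$iter <- ck$iter; state$t_g <- ck$t_g; state$t_d <- ck$t_d
  state
}
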
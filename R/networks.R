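# DCLGAN components: two resnet-style generators (encoder + decoder), two
# PatchGAN discriminators and two 2-layer projection heads.  Weights are
# plain R matrices inside parameter environments; all forward passes run
# on the autodiff tape so the same code serves training and inference.

#' Generator architecture configuration
#'
#' A resnet generator: a 7x7 input convolution, `n_downsamples` stride-2
#' convolutions, `n_resnet_blocks` residual blocks, mirrored
#' nearest-neighbour-upsample + convolution stages and a 7x7 output
#' convolution with tanh, so inputs and outputs are 3-channel images of
#' equal size with values in `[-1, 1]`.
#'
#' @param base_channels channels after the first convolution.
#' @param n_downsamples number of stride-2 encoder stages.
#' @param n_resnet_blocks number of residual blocks (>= 1).
#' @param norm_kind `"instance"` or `"batch"`.  Normalisation is computed
#'   per image over spatial positions; with the single-image batches this
#'   package trains on the two choices coincide.
#' @export
generator_config <- function(base_channels = 64, n_downsamples = 2,
                             n_resnet_blocks = 9,
                             norm_kind = c("instance", "batch")) {
  norm_kind <- match.arg(norm_kind)
  if (n_resnet_blocks < 1) vs_config_error("n_resnet_blocks must be >= 1")
  if (n_downsamples < 1) vs_config_error("n_downsamples must be >= 1")
  structure(list(base_channels = as.integer(base_channels),
                 n_downsamples = as.integer(n_downsamples),
                 n_resnet_blocks = as.integer(n_resnet_blocks),
                 norm_kind = norm_kind),
            class = "generator_config")
}

#' Discriminator architecture configuration
#'
#' A PatchGAN classifier: `n_layers` stride-2 4x4 convolutions followed by
#' two stride-1 convolutions down to a one-channel spatial realness map
#' (logits), so realness is judged per receptive-field patch rather than
#' per image.
#'
#' @param base_channels channels after the first convolution.
#' @param n_layers number of stride-2 stages.
#' @export
discriminator_config <- function(base_channels = 64, n_layers = 3) {
  if (n_layers < 1) vs_config_error("n_layers must be >= 1")
  structure(list(base_channels = as.integer(base_channels),
                 n_layers = as.integer(n_layers)),
            class = "discriminator_config")
}

#' Compact presets for CPU-scale experiments
#'
#' `tiny_preset()` bundles a small generator (1 downsample, 2 residual
#' blocks, 8 base channels), a 2-layer discriminator and a 32-dimensional
#' projection head with 64 sampled locations -- the configuration used by
#' the package's own tests and desk-scale experiments on 64 x 64 patches.
#' @export
tiny_preset <- function() {
  list(generator = generator_config(base_channels = 8, n_downsamples = 1,
                                    n_resnet_blocks = 2),
       discriminator = discriminator_config(base_channels = 8, n_layers = 2),
       n_locations = 64L, embed_dim = 32L, head_hidden = 32L)
}

conv_param <- function(cout, cin, k, sd = 0.02) {
  list(w = param_new(matrix(rnorm(cout * cin * k * k, 0, sd), cout, cin * k * k)),
       b = param_new(rep(0, cout)))
}

#' Build a resnet generator
#'
#' @param config a [generator_config()].
#' @param seed seed for weight initialisation (N(0, 0.02)).
#' @return a `generator` object holding layer descriptors and parameters.
#' @export
build_generator <- function(config, seed = 1L) {
  with_seed(seed, {
    f <- config$base_channels
    layers <- list()
    add <- function(l) layers[[length(layers) + 1L]] <<- l
    add(c(list(type = "conv", k = 7L, stride = 1L, pad = 3L,
               pad_mode = "reflect", norm = TRUE, act = "relu",
               cin = 3L, cout = f), conv_param(f, 3L, 7L)))
    ch <- f
    for (i in seq_len(config$n_downsamples)) {
      add(c(list(type = "conv", k = 3L, stride = 2L, pad = 1L,
                 pad_mode = "zero", norm = TRUE, act = "relu",
                 cin = ch, cout = 2L * ch), conv_param(2L * ch, ch, 3L)))
      ch <- 2L * ch
    }
    for (i in seq_len(config$n_resnet_blocks)) {
      add(c(list(type = "resblock", k = 3L, cin = ch, cout = ch),
            list(conv1 = conv_param(ch, ch, 3L), conv2 = conv_param(ch, ch, 3L))))
    }
    for (i in seq_len(config$n_downsamples)) {
      add(c(list(type = "upconv", k = 3L, pad = 1L, pad_mode = "reflect",
                 norm = TRUE, act = "relu", cin = ch, cout = ch %/% 2L),
            conv_param(ch %/% 2L, ch, 3L)))
      ch <- ch %/% 2L
    }
    add(c(list(type = "conv", k = 7L, stride = 1L, pad = 3L,
               pad_mode = "reflect", norm = FALSE, act = "tanh",
               cin = ch, cout = 3L), conv_param(3L, ch, 7L)))
    structure(list(config = config, layers = layers), class = "generator")
  })
}

# encoder depth: layers up to and including the middle residual block
encoder_depth <- function(gen) {
  nd <- gen$config$n_downsamples; nb <- gen$config$n_resnet_blocks
  1L + nd + max(1L, (nb + 1L) %/% 2L)
}

#' Default feature tap layers of a generator encoder
#'
#' Input image, first convolution, every downsample stage and the middle
#' residual block.
#' @param gen a generator.
#' @return integer vector of tap ids (0 = input image).
#' @export
default_layer_ids <- function(gen) {
  nd <- gen$config$n_downsamples
  unique(c(0L, 1L, 1L + seq_len(nd), encoder_depth(gen)))
}

gen_params <- function(gen) {
  out <- list()
  for (l in gen$layers) {
    if (l$type == "resblock") {
      out <- c(out, list(l$conv1$w, l$conv1$b, l$conv2$w, l$conv2$b))
    } else out <- c(out, list(l$w, l$b))
  }
  out
}

run_layer <- function(tp, l, x) {
  if (l$type == "conv") {
    y <- op_conv(tp, x, l$w, l$b, l$k, l$stride, l$pad, l$pad_mode)
    if (isTRUE(l$norm)) y <- op_instance_norm(tp, y)
    switch(l$act, relu = op_relu(tp, y), tanh = op_tanh(tp, y), y)
  } else if (l$type == "upconv") {
    y <- op_upsample2(tp, x)
    y <- op_conv(tp, y, l$w, l$b, l$k, 1L, l$pad, l$pad_mode)
    if (isTRUE(l$norm)) y <- op_instance_norm(tp, y)
    op_relu(tp, y)
  } else if (l$type == "resblock") {
    y <- op_conv(tp, x, l$conv1$w, l$conv1$b, l$k, 1L, 1L, "reflect")
    y <- op_instance_norm(tp, y)
    y <- op_relu(tp, y)
    y <- op_conv(tp, y, l$conv2$w, l$conv2$b, l$k, 1L, 1L, "reflect")
    y <- op_instance_norm(tp, y)
    op_add(tp, x, y)
  } else vs_config_error(paste0("unknown layer type ", l$type))
}

# forward through the generator on an existing tape; returns output node
# and (optionally) tap activation nodes keyed by layer id
gen_forward_tape <- function(tp, gen, x, taps = NULL, upto = NULL) {
  tap_nodes <- list()
  if (!is.null(taps) && 0L %in% taps) tap_nodes[["0"]] <- x
  n_run <- if (is.null(upto)) length(gen$layers) else upto
  for (i in seq_len(n_run)) {
    x <- run_layer(tp, gen$layers[[i]], x)
    if (!is.null(taps) && i %in% taps) tap_nodes[[as.character(i)]] <- x
  }
  list(out = x, taps = tap_nodes)
}

check_model_image <- function(x, n_down) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3 || d[3] != 3L)
    vs_input_error("generator input must be an H x W x 3 array")
  if (d[1] %% (2^n_down) != 0 || d[2] %% (2^n_down) != 0)
    vs_input_error(paste0("spatial size must be divisible by ", 2^n_down))
  invisible(d)
}

#' Run a generator on an image
#'
#' @param gen a generator from [build_generator()].
#' @param image H x W x 3 array with values in `[-1, 1]` whose spatial
#'   size is divisible by `2^n_downsamples`.
#' @return translated H x W x 3 array in `[-1, 1]`.
#' @export
generator_forward <- function(gen, image) {
  d <- check_model_image(image, gen$config$n_downsamples)
  if (min(image) < -1 - 1e-6 || max(image) > 1 + 1e-6)
    vs_input_error("generator input values must lie in [-1, 1]")
  tp <- tape_new()
  x <- op_input(tp, t(matrix(image, d[1] * d[2], 3)), H = d[1], W = d[2])
  out <- gen_forward_tape(tp, gen, x)$out
  array(t(out$val), d)
}

#' Raw encoder feature maps at selected layers
#'
#' @param gen a generator.
#' @param image H x W x 3 array in `[-1, 1]`.
#' @param layer_ids tap ids (0 = the input image itself); defaults to
#'   [default_layer_ids()].
#' @return named list of features, one per tap, each a list with `map`
#'   (C_l x S_l matrix), `H`, `W`, `channels`.
#' @export
encoder_features <- function(gen, image, layer_ids = default_layer_ids(gen)) {
  d <- check_model_image(image, gen$config$n_downsamples)
  if (any(layer_ids < 0L) || any(layer_ids > encoder_depth(gen)))
    vs_config_error(paste0("layer_ids must lie in 0..", encoder_depth(gen)))
  tp <- tape_new()
  x <- op_input(tp, t(matrix(image, d[1] * d[2], 3)), H = d[1], W = d[2])
  res <- gen_forward_tape(tp, gen, x, taps = layer_ids,
                          upto = encoder_depth(gen))
  lapply(res$taps, function(nd)
    list(map = nd$val, H = nd$H, W = nd$W, channels = nrow(nd$val)))
}

#' Build a PatchGAN discriminator
#' @param config a [discriminator_config()].
#' @param seed weight initialisation seed.
#' @export
build_discriminator <- function(config, seed = 1L) {
  with_seed(seed, {
    f <- config$base_channels
    layers <- list()
    add <- function(l) layers[[length(layers) + 1L]] <<- l
    add(c(list(type = "conv", k = 4L, stride = 2L, pad = 1L,
               pad_mode = "zero", norm = FALSE, act = "lrelu",
               cin = 3L, cout = f), conv_param(f, 3L, 4L)))
    ch <- f
    for (i in seq_len(config$n_layers - 1L)) {
      add(c(list(type = "conv", k = 4L, stride = 2L, pad = 1L,
                 pad_mode = "zero", norm = TRUE, act = "lrelu",
                 cin = ch, cout = 2L * ch), conv_param(2L * ch, ch, 4L)))
      ch <- 2L * ch
    }
    add(c(list(type = "conv", k = 4L, stride = 1L, pad = 1L,
               pad_mode = "zero", norm = TRUE, act = "lrelu",
               cin = ch, cout = 2L * ch), conv_param(2L * ch, ch, 4L)))
    ch <- 2L * ch
    add(c(list(type = "conv", k = 4L, stride = 1L, pad = 1L,
               pad_mode = "zero", norm = FALSE, act = "none",
               cin = ch, cout = 1L), conv_param(1L, ch, 4L)))
    structure(list(config = config, layers = layers), class = "discriminator")
  })
}

disc_params <- function(d) gen_params(d)  # same layer descriptor layout

disc_forward_tape <- function(tp, disc, x) {
  for (l in disc$layers) {
    y <- op_conv(tp, x, l$w, l$b, l$k, l$stride, l$pad, l$pad_mode)
    if (isTRUE(l$norm)) y <- op_instance_norm(tp, y)
    x <- switch(l$act, lrelu = op_lrelu(tp, y), none = y)
  }
  x  # 1 x S logits map
}

#' Run a discriminator, returning its spatial logits map
#' @param disc a discriminator.
#' @param image H x W x 3 array in `[-1, 1]`.
#' @return matrix of patch-level realness logits.
#' @export
discriminator_forward <- function(disc, image) {
  d <- dim(image)
  tp <- tape_new()
  x <- op_input(tp, t(matrix(image, d[1] * d[2], 3)), H = d[1], W = d[2])
  out <- disc_forward_tape(tp, disc, x)
  matrix(out$val, out$H, out$W)
}

#' Build a projection head
#'
#' One two-layer perceptron per tapped encoder layer: a linear map to
#' `hidden` units, ReLU, a linear map to `output_dim`, then L2
#' normalisation, so every projected feature is a unit K-vector.
#'
#' @param channel_dims named integer vector: channels of each tapped layer.
#' @param output_dim embedding dimension K.
#' @param hidden hidden width.
#' @param seed initialisation seed.
#' @export
projection_head <- function(channel_dims, output_dim = 256L, hidden = 256L,
                            seed = 1L) {
  with_seed(seed, {
    mlps <- lapply(channel_dims, function(cl) {
      # small non-zero biases so an all-zero feature location (a dead
      # ReLU position) still projects to a normalisable vector
      list(w1 = param_new(matrix(rnorm(hidden * cl, 0, sqrt(2 / cl)),
                                 hidden, cl)),
           b1 = param_new(rnorm(hidden, 0, 0.01)),
           w2 = param_new(matrix(rnorm(output_dim * hidden, 0, sqrt(1 / hidden)),
                                 output_dim, hidden)),
           b2 = param_new(rnorm(output_dim, 0, 0.01)))
    })
    structure(list(mlps = mlps, output_dim = as.integer(output_dim),
                   hidden = as.integer(hidden),
                   channel_dims = channel_dims),
              class = "projection_head")
  })
}

head_params <- function(h) {
  unlist(lapply(h$mlps, function(m) list(m$w1, m$b1, m$w2, m$b2)),
         recursive = FALSE, use.names = FALSE)
}

head_forward_tape <- function(tp, head, layer_key, x) {
  m <- head$mlps[[layer_key]]
  if (is.null(m)) vs_config_error(paste0("projection head has no MLP for layer ",
                                         layer_key))
  y <- op_linear(tp, x, m$w1, m$b1)
  y <- op_relu(tp, y)
  y <- op_linear(tp, y, m$w2, m$b2)
  op_l2norm_rows(tp, y)
}

# sample locations and project tapped features on an existing tape
sample_project_tape <- function(tp, tap_nodes, head, n_locations,
                                locations = NULL, seed = 1L) {
  keys <- names(tap_nodes)
  if (is.null(locations)) {
    locations <- with_seed(seed, lapply(tap_nodes, function(nd) {
      s_av <- ncol(nd$val)
      if (n_locations > s_av)
        vs_config_error(paste0("n_locations (", n_locations,
                               ") exceeds available positions (", s_av, ")"))
      sort(sample.int(s_av, n_locations))
    }))
  }
  vec_nodes <- lapply(keys, function(k) {
    g <- op_gather_t(tp, tap_nodes[[k]], locations[[k]])
    head_forward_tape(tp, head, k, g)
  })
  names(vec_nodes) <- keys
  list(nodes = vec_nodes, locations = locations)
}

#' Sample feature locations and project them to unit embeddings
#'
#' From each tapped feature map, `n_locations` spatial positions are drawn
#' uniformly without replacement (or reused from `locations`, so the
#' paired image's stack uses identical positions) and pushed through the
#' domain's projection head.
#'
#' @param features output of [encoder_features()].
#' @param n_locations positions per layer.
#' @param head a [projection_head()].
#' @param locations optional list of per-layer location indices to reuse.
#' @param seed sampling seed (ignored when `locations` is given).
#' @return an `embedding_stack`: list with `layer_ids`, `locations`,
#'   `vectors` (per layer S x K unit-row matrices) and `channel_dims`.
#' @export
sample_and_project <- function(features, n_locations, head,
                               locations = NULL, seed = 1L) {
  tp <- tape_new()
  tap_nodes <- lapply(features, function(f)
    op_const(tp, f$map, H = f$H, W = f$W))
  sp <- sample_project_tape(tp, tap_nodes, head, n_locations, locations, seed)
  structure(list(layer_ids = names(features),
                 locations = sp$locations,
                 vectors = lapply(sp$nodes, function(nd) nd$val),
                 channel_dims = vapply(features, function(f) f$channels,
                                       integer(1))),
            class = "embedding_stack")
}

# ---- checkpoints ------------------------------------------------------------

params_values <- function(params) lapply(params, function(p) p$val)
params_restore <- function(params, values) {
  for (i in seq_along(params)) params[[i]]$val <- values[[i]]
  invisible(NULL)
}
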
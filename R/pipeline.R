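# End-to-end orchestration: fixtures -> preprocess -> train -> infer ->
# evaluate, each stage re-runnable from its on-disk inputs.  One flat YAML
# config with per-stage sections; unknown keys are rejected; the resolved
# config is echoed into every stage's output directory.

#' Default pipeline configuration
#'
#' @return nested list with sections `fixtures`, `preprocess`, `model`,
#'   `train`, `infer`, `evaluate`, plus global `seed` and `out_root`.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_root = "vstain_out",
    fixtures = list(n_pairs = 6L, height = 256L, width = 256L,
                    nucleus_density = 5, cytoplasm_fraction = 0.35,
                    noise_sd = 3, misalign = FALSE),
    preprocess = list(patch_size = 64L, stride = 32L, min_fraction = 0.05,
                      block_size = 51L, offset = 10, register = NULL,
                      ratio_threshold = 0.75, ransac_tol_px = 3),
    model = list(preset = "tiny"),
    train = list(iterations = 300L, batch_size = 1L, learning_rate = 2e-4,
                 checkpoint_every = 500L, adversarial = "log",
                 lambda_gan = 1, lambda_nce = 2, lambda_idt = 1,
                 temperature = 0.07),
    infer = list(patch_size = NULL),
    evaluate = list(subset_size = 100L, n_subsets = 10L)
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(base))
      vs_config_error(paste0("unknown config key: ", path, k))
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(path, k, "."))
    } else base[[k]] <- user[[k]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param config NULL (defaults), a YAML file path, or a nested list;
#'   unknown keys raise a configuration error.
#' @param overrides nested list applied on top.
#' @param seed,out_root optional global overrides.
#' @export
load_pipeline_config <- function(config = NULL, overrides = list(),
                                 seed = NULL, out_root = NULL) {
  cfg <- default_pipeline_config()
  if (is.character(config)) {
    if (!file.exists(config)) vs_io_error(paste0("config not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (is.list(config)) cfg <- merge_config(cfg, config)
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_root)) cfg$out_root <- out_root
  cfg
}

echo_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(dir, "config_used.yaml"))
}

log_line <- function(stage, ...) {
  message(sprintf("[%s] %s", stage,
                  paste(vapply(list(...), as.character, character(1)),
                        collapse = " ")))
}

need_artifact <- function(path, stage_needed) {
  if (!file.exists(path))
    vs_input_error(paste0("missing upstream artifact ", path,
                          "; run the '", stage_needed, "' stage first"))
  path
}

stage_fixtures <- function(cfg) {
  fx <- cfg$fixtures
  dir <- file.path(cfg$out_root, "fixtures")
  spec <- synthetic_tissue_spec(fx$height, fx$width, fx$nucleus_density,
                                cytoplasm_fraction = fx$cytoplasm_fraction,
                                noise_sd = fx$noise_sd, seed = cfg$seed)
  manifest <- build_paired_dataset(spec, stain_oracle(), fx$n_pairs,
                                   misalign = fx$misalign, out_dir = dir)
  echo_config(cfg, dir)
  log_line("fixtures", nrow(manifest), "pairs written to", dir)
  invisible(manifest)
}

stage_preprocess <- function(cfg) {
  pp <- cfg$preprocess
  fxdir <- file.path(cfg$out_root, "fixtures")
  manifest <- read.csv(need_artifact(file.path(fxdir, "manifest.csv"),
                                     "fixtures"))
  dir <- file.path(cfg$out_root, "patches")
  register <- if (is.null(pp$register)) isTRUE(cfg$fixtures$misalign)
              else isTRUE(pp$register)
  all_recs <- list()
  for (i in seq_len(nrow(manifest))) {
    un <- read_image(manifest$unstained_path[i])
    st <- read_image(manifest$stained_path[i])
    if (register) {
      reg <- register_pair(un, st, pp$ratio_threshold, pp$ransac_tol_px,
                           seed = cfg$seed + i,
                           pair_id = manifest$pair_id[i])
      log_line("preprocess", manifest$pair_id[i], "registered,",
               reg$transform$inlier_count, "inliers")
      un <- reg$warped
    }
    fg <- segment_foreground(st, pp$block_size, pp$offset)
    recs <- extract_patches(un, st, dir, manifest$pair_id[i],
                            pp$patch_size, pp$stride)
    kept <- filter_background_patches(recs, fg$mask, pp$min_fraction,
                                      pp$patch_size)
    drop <- setdiff(recs$unstained_patch_path, kept$unstained_patch_path)
    file.remove(drop, sub("/unstained/", "/stained/", drop, fixed = TRUE))
    log_line("preprocess", manifest$pair_id[i], "kept", nrow(kept), "of",
             nrow(recs), "patches (foreground", round(fg$foreground_fraction, 3),
             ")")
    all_recs[[i]] <- kept
  }
  patches <- do.call(rbind, all_recs)
  write.csv(patches, file.path(dir, "patches.csv"), row.names = FALSE)
  echo_config(cfg, dir)
  invisible(patches)
}

pipeline_train_config <- function(cfg) {
  tr <- cfg$train
  model <- if (identical(cfg$model$preset, "tiny")) tiny_preset()
           else list(generator = generator_config(),
                     discriminator = discriminator_config(),
                     n_locations = 256L, embed_dim = 256L, head_hidden = 256L)
  train_config(iterations = tr$iterations, batch_size = tr$batch_size,
               learning_rate = tr$learning_rate, seed = cfg$seed,
               checkpoint_every = tr$checkpoint_every,
               image_size = cfg$preprocess$patch_size,
               weights = loss_weights(tr$lambda_gan, tr$lambda_nce,
                                      tr$lambda_idt, tr$temperature),
               adversarial = tr$adversarial, model = model)
}

stage_train <- function(cfg) {
  pdir <- file.path(cfg$out_root, "patches")
  need_artifact(file.path(pdir, "patches.csv"), "preprocess")
  dir <- file.path(cfg$out_root, "checkpoints")
  res <- fit(pipeline_train_config(cfg), file.path(pdir, "unstained"),
             file.path(pdir, "stained"), out_dir = dir)
  echo_config(cfg, dir)
  log_line("train", "final total", round(tail(res$history$total, 1), 4),
           "->", res$checkpoint_path)
  invisible(res)
}

stage_infer <- function(cfg) {
  ckpt <- need_artifact(file.path(cfg$out_root, "checkpoints",
                                  "checkpoint_final.rds"), "train")
  fxdir <- file.path(cfg$out_root, "fixtures")
  manifest <- read.csv(need_artifact(file.path(fxdir, "manifest.csv"),
                                     "fixtures"))
  dir <- file.path(cfg$out_root, "stained_virtual")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  state <- load_checkpoint(ckpt)
  ps <- cfg$infer$patch_size
  for (i in seq_len(nrow(manifest))) {
    out <- translate_whole_slide(state, read_image(manifest$unstained_path[i]),
                                 patch_size = ps)
    write_image(out, file.path(dir, paste0(manifest$pair_id[i],
                                           "_virtual.png")))
  }
  echo_config(cfg, dir)
  log_line("infer", nrow(manifest), "slides translated to", dir)
  invisible(dir)
}

stage_evaluate <- function(cfg) {
  sdir <- need_artifact(file.path(cfg$out_root, "patches", "stained"),
                        "preprocess")
  vdir <- need_artifact(file.path(cfg$out_root, "stained_virtual"), "infer")
  dir <- file.path(cfg$out_root, "report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep <- evaluate_sets(sdir, vdir, toy_extractor(),
                       subset_size = cfg$evaluate$subset_size,
                       n_subsets = cfg$evaluate$n_subsets, seed = cfg$seed,
                       report_path = file.path(dir, "report.json"))
  echo_config(cfg, dir)
  log_line("evaluate", "FID", round(rep$fid, 3), "KID", round(rep$kid_mean, 5))
  invisible(rep)
}

#' Run pipeline stages
#'
#' @param subcommand one of `fixtures`, `preprocess`, `train`, `infer`,
#'   `evaluate`, `all`.
#' @param config NULL, a YAML path or a nested list (see
#'   [load_pipeline_config()]).
#' @param overrides nested list of config overrides.
#' @param seed,out_root optional global overrides.
#' @return the final stage's artifact summary, invisibly.
#' @export
run_pipeline <- function(subcommand = c("all", "fixtures", "preprocess",
                                        "train", "infer", "evaluate"),
                         config = NULL, overrides = list(), seed = NULL,
                         out_root = NULL) {
  subcommand <- tryCatch(match.arg(subcommand), error = function(e)
    vs_config_error(paste0("unknown subcommand: ", subcommand[1])))
  cfg <- load_pipeline_config(config, overrides, seed, out_root)
  stages <- if (subcommand == "all")
    c("fixtures", "preprocess", "train", "infer", "evaluate")
  else subcommand
  out <- NULL
  for (s in stages)
    out <- switch(s, fixtures = stage_fixtures(cfg),
                  preprocess = stage_preprocess(cfg),
                  train = stage_train(cfg), infer = stage_infer(cfg),
                  evaluate = stage_evaluate(cfg))
  invisible(out)
}
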
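# Shared synthetic fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# one 256 x 256 tissue pair with its label map
tissue_pair <- function(seed = 7, size = 256, cytoplasm_fraction = 0.45,
                        nucleus_density = 8) {
  memo(sprintf("pair_%d_%d_%g", seed, size, cytoplasm_fraction), {
    spec <- synthetic_tissue_spec(size, size,
                                  nucleus_density = nucleus_density,
                                  cytoplasm_fraction = cytoplasm_fraction,
                                  seed = seed)
    g <- generate_unstained_image(spec)
    list(spec = spec,
         unstained = g$image,
         label = g$label_map,
         centers = g$nucleus_centers,
         stained = apply_stain_oracle(g$image, g$label_map, stain_oracle()))
  })
}

# n paired 64 x 64 patch sets for training / evaluation experiments
patch_sets <- function(seed, n_train = 16, n_eval = 24, size = 64) {
  oracle <- stain_oracle()
  one <- function(s) {
    sp <- synthetic_tissue_spec(size, size, nucleus_density = 8,
                                cytoplasm_fraction = 0.45, seed = s)
    g <- generate_unstained_image(sp)
    list(u = g$image, s = apply_stain_oracle(g$image, g$label_map, oracle))
  }
  train <- lapply(seed * 1000L + seq_len(n_train), one)
  eval <- lapply(seed * 1000L + 500L + seq_len(n_eval), one)
  list(train_u = lapply(train, `[[`, "u"),
       train_s = lapply(train, `[[`, "s"),
       eval_u = lapply(eval, `[[`, "u"),
       eval_s = lapply(eval, `[[`, "s"))
}

write_patch_dirs <- function(sets, root = tempfile("patches")) {
  du <- file.path(root, "unstained"); ds <- file.path(root, "stained")
  dir.create(du, recursive = TRUE); dir.create(ds, recursive = TRUE)
  for (i in seq_along(sets$train_u)) {
    write_image(sets$train_u[[i]], file.path(du, sprintf("%03d.png", i)))
    write_image(sets$train_s[[i]], file.path(ds, sprintf("%03d.png", i)))
  }
  list(unstained = du, stained = ds)
}

translate_images <- function(state, images) {
  lapply(images, function(img)
    pmin(pmax((generator_forward(state$g1, img / 127.5 - 1) + 1) * 127.5,
              0), 255))
}
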
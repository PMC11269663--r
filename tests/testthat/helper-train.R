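# One tiny model trained for 300 iterations on the synthetic stain task,
# shared by the training, stitching and metrics tests (each asserts a
# different property of the same run).

shared_train_seed <- 42L

shared_training_data <- function() {
  memo("shared_sets", patch_sets(shared_train_seed))
}

shared_trained_fit <- function() {
  memo("shared_fit", {
    sets <- shared_training_data()
    dirs <- write_patch_dirs(sets)
    cfg <- train_config(iterations = 300L, seed = shared_train_seed,
                        image_size = 64L, checkpoint_every = 0L)
    fit(cfg, dirs$unstained, dirs$stained, out_dir = tempfile("fit"))
  })
}
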
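# Stage 3: whole-slide inference.  Tiles at 50% overlap, translates each
# tile, and alpha-blends with a separable triangular weight window.  The
# windows form an exact partition of unity at this overlap, so stitching
# un-translated tiles reproduces the source image to rounding.

#' Plan a 50%-overlap tiling of a canvas
#'
#' Stride is `patch_size / 2`; the canvas is reflect-padded at the
#' bottom/right so the lattice covers it exactly.  Each tile is classed as
#' corner, edge or interior by its position in the grid.
#'
#' @param img_dim `c(H, W)` of the image to stitch.
#' @param patch_size even tile width in pixels.
#' @return a `stitch_plan`: a [patch_grid()] plus `n_tiles_axis` and a
#'   per-tile `boundary_class`.
#' @export
plan_tiles <- function(img_dim, patch_size = 512) {
  if (patch_size %% 2 != 0) vs_config_error("patch_size must be even")
  grid <- patch_grid(img_dim, patch_size, patch_size %/% 2L)
  nr <- length(unique(grid$origins$row))
  nc <- length(unique(grid$origins$col))
  on_edge_r <- grid$origins$row %in% c(0L, max(grid$origins$row))
  on_edge_c <- grid$origins$col %in% c(0L, max(grid$origins$col))
  grid$boundary_class <- ifelse(on_edge_r & on_edge_c, "corner",
                                ifelse(on_edge_r | on_edge_c, "edge",
                                       "interior"))
  grid$n_tiles_axis <- c(nr, nc)
  class(grid) <- "stitch_plan"
  grid
}

# 1-D blend window of length p: triangular ramps across overlapped sides,
# constant 1 towards a side lying on the canvas boundary.  Offsets are
# sampled at pixel centres (t + 0.5), which makes opposing ramps sum to
# exactly 1.
blend_window_1d <- function(p, ramp_low, ramp_high) {
  r <- p %/% 2L
  asc <- (seq_len(r) - 0.5) / r
  w_lo <- if (ramp_low) asc else rep(1, r)
  w_hi <- if (ramp_high) rev(asc) else rep(1, r)
  c(w_lo, w_hi)
}

#' Blend weight matrix of one tile
#'
#' The outer product of two 1-D windows: weight ramps linearly to zero
#' across every side shared with a neighbouring tile and stays 1 towards
#' sides on the canvas boundary -- giving corner, edge and interior tiles
#' their distinct profiles while the weights of all tiles covering a pixel
#' sum to exactly 1.
#'
#' @param plan a [plan_tiles()] plan.
#' @param tile_index row index into `plan$origins`.
#' @return `patch_size` x `patch_size` weight matrix.
#' @export
make_weight_matrix <- function(plan, tile_index) {
  if (tile_index < 1 || tile_index > nrow(plan$origins))
    vs_input_error("tile_index outside the plan")
  o <- plan$origins[tile_index, ]
  p <- plan$patch_size
  wr <- blend_window_1d(p, o$row > 0L, o$row < max(plan$origins$row))
  wc <- blend_window_1d(p, o$col > 0L, o$col < max(plan$origins$col))
  outer(wr, wc)
}

#' Blend translated tiles into a whole image
#'
#' Accumulates `weight * tile` in floating point over the padded canvas,
#' crops back to the original size and rounds once to 8-bit.
#'
#' @param tiles list of `patch_size` x `patch_size` x 3 arrays (0..255
#'   scale), one per plan origin, in plan order.
#' @param plan a [plan_tiles()] plan.
#' @return raster array of the planned image size.
#' @export
stitch <- function(tiles, plan) {
  n <- nrow(plan$origins)
  if (length(tiles) != n)
    vs_input_error(paste0("expected ", n, " tiles, got ", length(tiles)))
  p <- plan$patch_size
  canvas <- array(0, c(plan$padded_dim, 3L))
  for (i in seq_len(n)) {
    tl <- tiles[[i]]
    if (is.null(tl) || !all(dim(tl)[1:2] == c(p, p)))
      vs_input_error(paste0("tile ", i, " missing or mis-sized"))
    w <- make_weight_matrix(plan, i)
    rr <- plan$origins$row[i] + seq_len(p)
    cc <- plan$origins$col[i] + seq_len(p)
    for (ch in 1:3)
      canvas[rr, cc, ch] <- canvas[rr, cc, ch] + w * tl[, , ch]
  }
  out <- canvas[seq_len(plan$img_dim[1]), seq_len(plan$img_dim[2]), ,
                drop = FALSE]
  clamp255(round(out))
}

#' Translate a whole slide
#'
#' Plans a 50%-overlap tiling, translates every tile with the trained
#' A-to-B generator and blends the results.  Deterministic given the
#' checkpoint.
#'
#' @param model a checkpoint path, a `train_state`, or a plain function
#'   mapping one 0..255 tile array to another (useful as a stub).
#' @param image raster array `c(H, W, 3)` on the 0..255 scale.
#' @param patch_size tile width; defaults to the checkpoint's training
#'   `image_size`.
#' @return virtually stained raster array, same size as `image`.
#' @export
translate_whole_slide <- function(model, image, patch_size = NULL) {
  tile_fun <-
    if (is.function(model)) {
      model
    } else {
      state <- if (inherits(model, "train_state")) model
               else load_checkpoint(model)
      if (is.null(patch_size)) patch_size <- state$config$image_size
      function(tile)
        clamp255((generator_forward(state$g1, tile / 127.5 - 1) + 1) * 127.5)
    }
  if (is.null(patch_size))
    vs_config_error("patch_size is required when model is a plain function")
  plan <- plan_tiles(dim(image)[1:2], patch_size)
  padded <- reflect_pad_br(image, plan$padded_dim[1] - dim(image)[1],
                           plan$padded_dim[2] - dim(image)[2])
  tiles <- lapply(seq_len(nrow(plan$origins)), function(i) {
    tl <- crop_tile(padded, plan$origins$row[i], plan$origins$col[i],
                    plan$patch_size)
    tryCatch(tile_fun(tl), error = function(e)
      vs_input_error(paste0("tile at (", plan$origins$row[i], ", ",
                            plan$origins$col[i], ") failed: ",
                            conditionMessage(e))))
  })
  stitch(tiles, plan)
}
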
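# Synthetic paired-tissue generator.  Produces unstained/stained image pairs
# with a known per-pixel class map (background / cytoplasm / nucleus), a
# known colour oracle for the "stain", and optionally a known homography
# misaligning the unstained member of the pair.  The stain mapping is local
# (class + texture decide the colour), so a patch-level translator can learn
# it -- the property every downstream training test relies on.

#' Specification of a synthetic tissue image
#'
#' @param height,width canvas size in pixels (each at least 64).
#' @param nucleus_density expected nuclei per 10^4 px^2; nucleus count is
#'   Poisson with mean `nucleus_density * height * width / 1e4`.
#' @param nucleus_radius_range `c(min, max)` nucleus semi-axis in pixels.
#' @param cytoplasm_fraction fraction of the canvas covered by tissue, in
#'   `[0, 1]`.
#' @param noise_sd additive Gaussian intensity noise (0..255 scale).
#' @param seed RNG seed; identical spec + seed gives bit-identical output.
#' @return object of class `synthetic_tissue_spec`.
#' @export
synthetic_tissue_spec <- function(height = 256, width = 256,
                                  nucleus_density = 5,
                                  nucleus_radius_range = c(4, 8),
                                  cytoplasm_fraction = 0.35,
                                  noise_sd = 3, seed = 1L) {
  if (height < 64 || width < 64)
    vs_config_error("synthetic tissue canvas must be at least 64 x 64")
  if (cytoplasm_fraction < 0 || cytoplasm_fraction > 1)
    vs_config_error("cytoplasm_fraction must lie in [0, 1]")
  if (length(nucleus_radius_range) != 2 || any(nucleus_radius_range <= 0) ||
      diff(nucleus_radius_range) < 0)
    vs_config_error("nucleus_radius_range must be increasing and positive")
  if (nucleus_density < 0) vs_config_error("nucleus_density must be >= 0")
  if (noise_sd < 0) vs_config_error("noise_sd must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 nucleus_density = nucleus_density,
                 nucleus_radius_range = nucleus_radius_range,
                 cytoplasm_fraction = cytoplasm_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_tissue_spec")
}

#' Colour oracle defining the ground-truth synthetic stain
#'
#' Target colours for the three pixel classes plus an edge-mixing width.
#' The defaults give a blue-purple nucleus / pink cytoplasm palette on a
#' near-white background, echoing how hematoxylin colours nuclei and eosin
#' colours cytoplasm and most proteins.
#'
#' @param nucleus_rgb,cytoplasm_rgb,background_rgb colour triples in
#'   `[0, 255]`; every `background_rgb` channel must be at least 230.
#' @param blend_softness Gaussian edge-mixing width in pixels.
#' @export
stain_oracle <- function(nucleus_rgb = c(72, 61, 139),
                         cytoplasm_rgb = c(244, 184, 196),
                         background_rgb = c(248, 246, 246),
                         blend_softness = 1.5) {
  for (v in list(nucleus_rgb, cytoplasm_rgb, background_rgb))
    if (length(v) != 3 || any(v < 0) || any(v > 255))
      vs_config_error("oracle colours must be RGB triples in [0, 255]")
  if (any(background_rgb < 230))
    vs_config_error("background_rgb must be near-white (every channel >= 230)")
  if (blend_softness < 0) vs_config_error("blend_softness must be >= 0")
  structure(list(nucleus_rgb = as.numeric(nucleus_rgb),
                 cytoplasm_rgb = as.numeric(cytoplasm_rgb),
                 background_rgb = as.numeric(background_rgb),
                 blend_softness = blend_softness),
            class = "stain_oracle")
}

smooth_field <- function(h, w, sigma) {
  x <- matrix(rnorm(h * w), h, w)
  if (sigma > 0) x <- EBImage::imageData(EBImage::gblur(EBImage::Image(x), sigma))
  x
}

#' Generate a synthetic unstained tissue image
#'
#' Draws cytoplasm blobs from a smoothed-noise field, scatters elliptical
#' nuclei inside them (Poisson count, uniform placement) and renders a
#' low-contrast, grayscale-like RGB image: the latent stained luminance is
#' compressed into the 200..255 band so tissue is only faintly visible on a
#' near-white background, mimicking brightfield contrast of an unstained
#' section.
#'
#' @param spec a [synthetic_tissue_spec()].
#' @return list with `image` (H x W x 3 array, 0..255), `label_map`
#'   (H x W integer matrix; 0 = background, 1 = cytoplasm, 2 = nucleus) and
#'   `nucleus_centers` (n x 2 matrix of `(x, y)` positions actually placed).
#' @export
generate_unstained_image <- function(spec) {
  if (!inherits(spec, "synthetic_tissue_spec"))
    vs_config_error("spec must be a synthetic_tissue_spec")
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    # cytoplasm blobs: threshold a smoothed noise field at the requested area
    blob <- smooth_field(h, w, sigma = min(h, w) / 16)
    label <- matrix(0L, h, w)
    if (spec$cytoplasm_fraction > 0) {
      thr <- stats::quantile(blob, 1 - spec$cytoplasm_fraction)
      label[blob >= thr] <- 1L
    }

    n_nuclei <- stats::rpois(1, spec$nucleus_density * h * w / 1e4)
    tissue_idx <- which(label == 1L)
    centers <- matrix(numeric(0), 0, 2,
                      dimnames = list(NULL, c("x", "y")))
    if (n_nuclei > 0 && length(tissue_idx) > 0) {
      pick <- sample(tissue_idx, n_nuclei, replace = TRUE)
      cy <- (pick - 1L) %% h          # 0-based row
      cx <- (pick - 1L) %/% h         # 0-based col
      rr <- stats::runif(n_nuclei, spec$nucleus_radius_range[1],
                         spec$nucleus_radius_range[2])
      ecc <- stats::runif(n_nuclei, 0.7, 1.3)
      th <- stats::runif(n_nuclei, 0, pi)
      for (i in seq_len(n_nuclei)) {
        a <- rr[i] * ecc[i]; b <- rr[i] / ecc[i]
        r <- ceiling(max(a, b))
        ys <- max(0, cy[i] - r):min(h - 1, cy[i] + r)
        xs <- max(0, cx[i] - r):min(w - 1, cx[i] + r)
        dy <- outer(ys - cy[i], rep(1, length(xs)))
        dx <- outer(rep(1, length(ys)), xs - cx[i])
        u <- cos(th[i]) * dx + sin(th[i]) * dy
        v <- -sin(th[i]) * dx + cos(th[i]) * dy
        inside <- (u / a)^2 + (v / b)^2 <= 1
        sub <- label[ys + 1, xs + 1, drop = FALSE]
        sub[inside] <- 2L
        label[ys + 1, xs + 1] <- sub
      }
      centers <- cbind(x = cx, y = cy)
    }

    # latent stained-luminance proxy in [0, 1]: nuclei darkest, background
    # lightest, plus fine smoothed texture inside tissue
    lum <- matrix(0.97, h, w)
    lum[label == 1L] <- 0.75
    lum[label == 2L] <- 0.45
    tex <- smooth_field(h, w, sigma = 2)
    tex <- tex / max(abs(tex), 1e-8) * 0.08
    lum[label > 0L] <- lum[label > 0L] + tex[label > 0L]
    lum <- pmin(pmax(lum, 0), 1)

    faint <- 200 + 55 * lum
    noise <- matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    img <- clamp255(array(rep(faint + noise, 3), c(h, w, 3)))
    list(image = img, label_map = label, nucleus_centers = centers)
  })
}

#' Apply the ground-truth stain oracle
#'
#' Recolours an image class-conditionally: each pixel takes its class's
#' oracle colour, modulated multiplicatively by the input image's local
#' luminance (so texture survives and hue is preserved), and colours are
#' mixed across class edges with a Gaussian kernel of width
#' `blend_softness`.  Background pixels keep `background_rgb` exactly.
#'
#' @param image raster array `c(H, W, 3)`, 0..255.
#' @param label_map H x W integer matrix of classes 0/1/2.
#' @param oracle a [stain_oracle()].
#' @return stained raster array `c(H, W, 3)`.
#' @export
apply_stain_oracle <- function(image, label_map, oracle) {
  if (!inherits(oracle, "stain_oracle"))
    vs_config_error("oracle must be a stain_oracle")
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || !all(dim(label_map) == d[1:2]))
    vs_input_error("label_map shape must match image")
  h <- d[1]; w <- d[2]

  lum <- rgb_to_gray(image) / 255
  tissue <- label_map > 0L
  mod <- matrix(1, h, w)
  if (any(tissue)) {
    mu <- mean(lum[tissue]); sdv <- stats::sd(lum[tissue])
    if (!is.finite(sdv) || sdv < 1e-8) sdv <- 1
    mod[tissue] <- 1 + 0.25 * tanh((lum[tissue] - mu) / sdv)
  }

  colors <- rbind(oracle$background_rgb, oracle$cytoplasm_rgb,
                  oracle$nucleus_rgb)
  planes <- lapply(1:3, function(cls0) {
    ind <- matrix(as.numeric(label_map == (cls0 - 1L)), h, w)
    if (oracle$blend_softness > 0)
      ind <- EBImage::imageData(EBImage::gblur(EBImage::Image(ind),
                                               oracle$blend_softness))
    ind
  })
  wsum <- Reduce(`+`, planes)
  out <- array(0, c(h, w, 3))
  for (cls in 1:3) {
    wgt <- planes[[cls]] / pmax(wsum, 1e-8)
    m <- if (cls == 1) matrix(1, h, w) else mod   # background unmodulated
    for (ch in 1:3)
      out[, , ch] <- out[, , ch] + wgt * m * colors[cls, ch]
  }
  clamp255(out)
}

#' Warp an image by a known homography (fixture misalignment)
#'
#' Thin wrapper over [warp_image()] used to create the controlled spatial
#' misalignment that registration must undo.
#'
#' @param image raster array.
#' @param transform a [homography()]; must be invertible.
#' @param fill fill colour for out-of-frame pixels.
#' @export
perturb_geometry <- function(image, transform, fill = 255) {
  if (!inherits(transform, "homography"))
    vs_input_error("transform must be a homography")
  warp_image(image, transform, fill = fill)
}

random_mild_homography <- function(h, w, max_rotation_deg = 5,
                                   max_translation_px = 20,
                                   projective_mag = 2e-6) {
  rot <- stats::runif(1, -max_rotation_deg, max_rotation_deg)
  tx <- stats::runif(1, -max_translation_px, max_translation_px)
  ty <- stats::runif(1, -max_translation_px, max_translation_px)
  m <- homography_similarity(rot, tx, ty,
                             center = c((w - 1) / 2, (h - 1) / 2))$matrix
  m[3, 1:2] <- stats::runif(2, -projective_mag, projective_mag)
  homography(m)
}

#' Write a paired synthetic dataset to disk
#'
#' Generates `n_pairs` unstained/stained pairs (plus label maps) as PNG
#' files with a CSV manifest.  When `misalign` is TRUE the unstained image
#' is warped by a random mild homography and the manifest records the
#' *aligning* transform (unstained back onto the stained frame) in columns
#' `h11..h33`; otherwise those columns hold the identity.
#'
#' @param spec a [synthetic_tissue_spec()]; pair `i` uses seed
#'   `spec$seed + i`.
#' @param oracle a [stain_oracle()].
#' @param n_pairs number of pairs to write.
#' @param misalign warp the unstained image by a random mild homography?
#' @param out_dir output directory (created if needed).
#' @param max_rotation_deg,max_translation_px misalignment magnitude.
#' @return the manifest data frame (also written to `manifest.csv`).
#' @export
build_paired_dataset <- function(spec, oracle, n_pairs, misalign = FALSE,
                                 out_dir, max_rotation_deg = 5,
                                 max_translation_px = 20) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    vs_io_error(paste0("output directory not writable: ", out_dir))
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    spec_i <- spec
    spec_i$seed <- spec$seed + i
    gen <- generate_unstained_image(spec_i)
    stained <- apply_stain_oracle(gen$image, gen$label_map, oracle)
    unstained <- gen$image
    h_align <- homography_identity()
    if (misalign) {
      h_perturb <- with_seed(spec_i$seed + 10000L,
        random_mild_homography(spec$height, spec$width,
                               max_rotation_deg, max_translation_px))
      unstained <- perturb_geometry(unstained, h_perturb,
                                    fill = 248)
      h_align <- homography_inverse(h_perturb)
    }
    pid <- sprintf("pair%03d", i)
    up <- file.path(out_dir, paste0(pid, "_unstained.png"))
    sp <- file.path(out_dir, paste0(pid, "_stained.png"))
    lp <- file.path(out_dir, paste0(pid, "_label.png"))
    write_image(unstained, up)
    write_image(stained, sp)
    png::writePNG(gen$label_map / 255, lp)
    hm <- t(h_align$matrix)  # row-major h11, h12, h13, h21, ...
    rows[[i]] <- data.frame(pair_id = pid, unstained_path = up,
                            stained_path = sp, label_path = lp,
                            t(setNames(as.numeric(hm),
                                       paste0("h", rep(1:3, each = 3),
                                              rep(1:3, 3)))))
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a label map written by [build_paired_dataset()]
#' @param path label PNG path.
#' @return H x W integer matrix of classes 0/1/2.
#' @export
read_label_map <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
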
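# Stage 1: foreground segmentation, registration of the unstained image
# onto the stained frame, overlapping patch extraction and blank-patch
# filtering.

# ---- foreground segmentation ------------------------------------------------

box_mean <- function(m, radius) {
  # local mean over a (2r+1)^2 window, border windows clipped (integral image)
  h <- nrow(m); w <- ncol(m)
  s <- rbind(0, apply(m, 2, cumsum)); s <- cbind(0, t(apply(s, 1, cumsum)))
  cnt <- rbind(0, apply(matrix(1, h, w), 2, cumsum))
  cnt <- cbind(0, t(apply(cnt, 1, cumsum)))
  r1 <- pmax(seq_len(h) - radius, 1); r2 <- pmin(seq_len(h) + radius, h)
  c1 <- pmax(seq_len(w) - radius, 1); c2 <- pmin(seq_len(w) + radius, w)
  win <- function(s) s[r2 + 1, c2 + 1, drop = FALSE] - s[r1, c2 + 1, drop = FALSE] -
    s[r2 + 1, c1, drop = FALSE] + s[r1, c1, drop = FALSE]
  win(s) / win(cnt)
}

#' Segment tissue foreground by adaptive thresholding
#'
#' A pixel is foreground when its gray value lies more than `offset` below
#' the mean of its `block_size` x `block_size` neighbourhood (tissue is
#' darker than the illuminated background).  Because the interior of a
#' tissue region wider than the neighbourhood is close to its own local
#' mean, the raw threshold response concentrates on tissue boundaries and
#' texture; the mask is therefore closed morphologically and hole-filled
#' before cleanup by opening and small-component removal.
#'
#' @param image raster array `c(H, W, 3)` on the 0..255 scale.
#' @param block_size odd neighbourhood width in pixels (>= 3).
#' @param offset intensity offset below the local mean.
#' @param opening_diameter disc diameter for the morphological opening.
#' @param min_object_px connected components smaller than this are removed.
#' @return list with `mask` (H x W logical) and `foreground_fraction`.
#' @export
segment_foreground <- function(image, block_size = 101, offset = 10,
                               opening_diameter = 3, min_object_px = 256) {
  if (block_size %% 2 == 0 || block_size < 3)
    vs_config_error("block_size must be odd and >= 3")
  gray <- rgb_to_gray(image)
  # mirror-pad so regions clipped by the canvas border still close into
  # fillable rings, and so the local mean is unbiased at the border
  p <- block_size
  mir <- function(n) {
    i <- c(rev(seq_len(p) + 1L), seq_len(n), n - seq_len(p))
    i[i < 1L] <- 1L; i[i > n] <- n
    i
  }
  gp <- gray[mir(nrow(gray)), mir(ncol(gray))]
  local_mean <- box_mean(gp, (block_size - 1) %/% 2)
  # brightfield backgrounds are bright and flat: pair the local criterion
  # (texture, edges, robust to uneven illumination) with a global one
  # referenced to the illumination level, which recovers broad tissue
  # regions whose interior is no darker than its own neighbourhood
  bg_level <- stats::quantile(gray, 0.90, names = FALSE)
  mask <- (gp < local_mean - offset) | (gp < bg_level - 2 * offset)

  m <- EBImage::Image(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  m <- EBImage::closing(m, EBImage::makeBrush(7, "disc"))
  m <- EBImage::fillHull(m)
  if (opening_diameter >= 2)
    m <- EBImage::opening(m, EBImage::makeBrush(opening_diameter, "disc"))
  core <- EBImage::imageData(m)[p + seq_len(nrow(gray)),
                                p + seq_len(ncol(gray))]
  lab <- EBImage::bwlabel(EBImage::Image(core))
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_object_px])
  mask <- matrix(EBImage::imageData(lab) %in% keep, nrow(gray), ncol(gray))
  list(mask = mask, foreground_fraction = mean(mask))
}

# ---- keypoint detection and matching ---------------------------------------

gblur_mat <- function(m, sigma) {
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma))
}

#' Detect scale-space blob keypoints
#'
#' Difference-of-Gaussian detector in the style of SIFT: a short Gaussian
#' scale pyramid is built, DoG responses are computed, and 3D local extrema
#' (8 spatial neighbours plus the two adjacent scales) are kept, with
#' quadratic sub-pixel refinement in the image plane.  Orientation
#' assignment is omitted: the registration problem this serves involves
#' only mild rotations.
#'
#' @param gray H x W numeric matrix.
#' @param n_keypoints maximum number of keypoints, strongest first.
#' @param sigmas Gaussian scales of the pyramid.
#' @return data frame with columns `x`, `y` (0-based, sub-pixel), `sigma`,
#'   `response`.
#' @export
detect_keypoints <- function(gray, n_keypoints = 600,
                             sigmas = c(1, 1.6, 2.56, 4.1)) {
  h <- nrow(gray); w <- ncol(gray)
  pyr <- lapply(sigmas, function(s) gblur_mat(gray, s))
  dog <- lapply(seq_len(length(pyr) - 1),
                function(i) pyr[[i + 1]] - pyr[[i]])
  border <- 8L
  out <- list()
  for (k in seq_along(dog)) {
    d <- dog[[k]]
    lo <- if (k > 1) dog[[k - 1]] else NULL
    hi <- if (k < length(dog)) dog[[k + 1]] else NULL
    ri <- (border + 1):(h - border); ci <- (border + 1):(w - border)
    ctr <- d[ri, ci]
    is_max <- matrix(TRUE, length(ri), length(ci))
    is_min <- matrix(TRUE, length(ri), length(ci))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- d[ri + dr, ci + dc]
      is_max <- is_max & (ctr > nb); is_min <- is_min & (ctr < nb)
    }
    for (other in list(lo, hi)) {
      if (is.null(other)) next
      for (dr in -1:1) for (dc in -1:1) {
        nb <- other[ri + dr, ci + dc]
        is_max <- is_max & (ctr > nb); is_min <- is_min & (ctr < nb)
      }
    }
    ext <- which(is_max | is_min, arr.ind = TRUE)
    if (nrow(ext) == 0) next
    rr <- ext[, 1] + border; cc <- ext[, 2] + border
    # quadratic sub-pixel refinement per axis
    idx <- cbind(rr, cc)
    f0 <- d[idx]
    fy1 <- d[cbind(rr - 1, cc)]; fy2 <- d[cbind(rr + 1, cc)]
    fx1 <- d[cbind(rr, cc - 1)]; fx2 <- d[cbind(rr, cc + 1)]
    dy <- (fy1 - fy2) / (2 * (fy1 - 2 * f0 + fy2 + 1e-12))
    dx <- (fx1 - fx2) / (2 * (fx1 - 2 * f0 + fx2 + 1e-12))
    dy[!is.finite(dy) | abs(dy) > 0.5] <- 0
    dx[!is.finite(dx) | abs(dx) > 0.5] <- 0
    out[[k]] <- data.frame(x = cc - 1 + dx, y = rr - 1 + dy,
                           sigma = sigmas[k + 1], response = abs(f0))
  }
  kp <- do.call(rbind, out)
  if (is.null(kp) || nrow(kp) == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      sigma = numeric(0), response = numeric(0)))
  kp <- kp[order(-kp$response), , drop = FALSE]
  head(kp, n_keypoints)
}

#' Extract normalized patch descriptors at keypoints
#'
#' Samples a `grid x grid` patch (spacing proportional to the keypoint
#' scale) from the Gaussian-smoothed image around each keypoint and
#' normalizes it to zero mean and unit L2 norm, making the descriptor
#' invariant to affine intensity changes between the unstained and stained
#' modalities.
#'
#' @param gray H x W numeric matrix.
#' @param keypoints data frame from [detect_keypoints()].
#' @param grid descriptor grid width (descriptor length is `grid^2`).
#' @return n x grid^2 matrix of unit-norm descriptors.
#' @export
extract_descriptors <- function(gray, keypoints, grid = 16) {
  h <- nrow(gray); w <- ncol(gray)
  sm <- gblur_mat(gray, 1.6)
  off <- seq(-(grid - 1) / 2, (grid - 1) / 2)
  n <- nrow(keypoints)
  desc <- matrix(0, n, grid * grid)
  for (i in seq_len(n)) {
    sp <- max(1, keypoints$sigma[i] * 0.75)
    xs <- keypoints$x[i] + off * sp
    ys <- keypoints$y[i] + off * sp
    xs <- pmin(pmax(xs, 0), w - 1); ys <- pmin(pmax(ys, 0), h - 1)
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
    # bilinear sample the grid x grid lattice
    v <- outer(1 - fy, 1 - fx) * sm[cbind(rep(y0 + 1, grid), rep(x0 + 1, each = grid))] +
      outer(1 - fy, fx) * sm[cbind(rep(y0 + 1, grid), rep(x1 + 1, each = grid))] +
      outer(fy, 1 - fx) * sm[cbind(rep(y1 + 1, grid), rep(x0 + 1, each = grid))] +
      outer(fy, fx) * sm[cbind(rep(y1 + 1, grid), rep(x1 + 1, each = grid))]
    v <- v - mean(v)
    nrm <- sqrt(sum(v^2))
    if (nrm > 1e-8) desc[i, ] <- as.numeric(v) / nrm
  }
  desc
}

#' Match descriptors with Lowe's ratio test
#'
#' @param desc_a,desc_b unit-norm descriptor matrices.
#' @param ratio_threshold best/second-best distance ratio below which a
#'   match is kept.
#' @return data frame `idx_a`, `idx_b`, `distance`.
#' @export
match_descriptors <- function(desc_a, desc_b, ratio_threshold = 0.75) {
  if (nrow(desc_a) == 0 || nrow(desc_b) < 2)
    return(data.frame(idx_a = integer(0), idx_b = integer(0),
                      distance = numeric(0)))
  sim <- desc_a %*% t(desc_b)              # unit vectors: d^2 = 2 - 2 sim
  best <- max.col(sim)
  s1 <- sim[cbind(seq_len(nrow(sim)), best)]
  sim2 <- sim; sim2[cbind(seq_len(nrow(sim)), best)] <- -Inf
  s2 <- sim2[cbind(seq_len(nrow(sim2)), max.col(sim2))]
  d1 <- sqrt(pmax(2 - 2 * s1, 0)); d2 <- sqrt(pmax(2 - 2 * s2, 0))
  keep <- d1 < ratio_threshold * d2
  data.frame(idx_a = which(keep), idx_b = best[keep], distance = d1[keep])
}

# ---- homography estimation --------------------------------------------------

normalize_points <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- sqrt(2) / max(mean(d), 1e-12)
  t_mat <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
  list(pts = sweep(pts, 2, ctr) * s, t = t_mat)
}

#' Estimate a homography from point correspondences (normalized DLT)
#'
#' @param src,dst n x 2 matrices of `(x, y)` points, n >= 4.
#' @return 3 x 3 homography matrix (not yet normalized to h33 = 1).
#' @keywords internal
estimate_homography_dlt <- function(src, dst) {
  n <- nrow(src)
  ns <- normalize_points(src); nd <- normalize_points(dst)
  s <- ns$pts; d <- nd$pts
  a <- matrix(0, 2 * n, 9)
  a[seq(1, 2 * n, 2), ] <- cbind(-s[, 1], -s[, 2], -1, 0, 0, 0,
                                 d[, 1] * s[, 1], d[, 1] * s[, 2], d[, 1])
  a[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -s[, 1], -s[, 2], -1,
                                 d[, 2] * s[, 1], d[, 2] * s[, 2], d[, 2])
  v <- svd(a, nu = 0, nv = 9)$v
  hmat <- matrix(v[, 9], 3, 3, byrow = TRUE)
  solve(nd$t) %*% hmat %*% ns$t
}

ransac_homography <- function(src, dst, tol_px = 3, n_iter = 2000,
                              seed = 1L) {
  n <- nrow(src)
  best_inl <- logical(n); best_count <- -1L
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      pick <- sample.int(n, 4)
      hmat <- tryCatch(estimate_homography_dlt(src[pick, , drop = FALSE],
                                               dst[pick, , drop = FALSE]),
                       error = function(e) NULL)
      if (is.null(hmat) || abs(det(hmat)) < 1e-12) next
      proj <- cbind(src, 1) %*% t(hmat)
      wz <- proj[, 3]
      if (any(abs(wz) < 1e-12)) next
      err <- sqrt((proj[, 1] / wz - dst[, 1])^2 +
                  (proj[, 2] / wz - dst[, 2])^2)
      inl <- err < tol_px
      if (sum(inl) > best_count) {
        best_count <- sum(inl); best_inl <- inl
      }
    }
  })
  if (best_count < 4)
    vs_registration_error("RANSAC found no homography with >= 4 inliers")
  hmat <- estimate_homography_dlt(src[best_inl, , drop = FALSE],
                                  dst[best_inl, , drop = FALSE])
  list(matrix = hmat, inliers = best_inl)
}

#' Register an unstained image onto its stained reference
#'
#' Detects scale-space keypoints in both images, matches intensity-patch
#' descriptors with the ratio test, estimates the homography by RANSAC +
#' normalized DLT refit over the inliers, and warps the moving image into
#' the reference frame.
#'
#' @param moving raster array (the unstained image).
#' @param reference raster array (the stained image).
#' @param ratio_threshold Lowe ratio threshold for descriptor matching.
#' @param ransac_tol_px RANSAC inlier reprojection tolerance in pixels.
#' @param n_keypoints keypoint budget per image.
#' @param seed seed for RANSAC sampling (the only stochastic step).
#' @param pair_id label used in error messages.
#' @return list with `transform` (a [homography()] mapping moving to
#'   reference coordinates, with `inlier_count` set) and `warped` (the
#'   moving image resampled into the reference frame).
#' @export
register_pair <- function(moving, reference, ratio_threshold = 0.75,
                          ransac_tol_px = 3, n_keypoints = 600,
                          seed = 1L, pair_id = "pair") {
  if (any(dim(moving)[1:2] < 128) || any(dim(reference)[1:2] < 128))
    vs_input_error("registration needs images of at least 128 x 128")
  ga <- rgb_to_gray(moving); gb <- rgb_to_gray(reference)
  kpa <- detect_keypoints(ga, n_keypoints)
  kpb <- detect_keypoints(gb, n_keypoints)
  if (nrow(kpa) < 4 || nrow(kpb) < 4)
    vs_registration_error(paste0("registration failed for ", pair_id,
                                 ": too few keypoints (",
                                 nrow(kpa), " / ", nrow(kpb), ")"))
  da <- extract_descriptors(ga, kpa)
  db <- extract_descriptors(gb, kpb)
  m <- match_descriptors(da, db, ratio_threshold)
  if (nrow(m) < 4)
    vs_registration_error(paste0("registration failed for ", pair_id,
                                 ": only ", nrow(m),
                                 " ratio-test matches (need >= 4)"))
  src <- cbind(kpa$x[m$idx_a], kpa$y[m$idx_a])
  dst <- cbind(kpb$x[m$idx_b], kpb$y[m$idx_b])
  fit <- tryCatch(ransac_homography(src, dst, ransac_tol_px, seed = seed),
                  error = function(e) {
                    vs_registration_error(paste0("registration failed for ",
                                                 pair_id, ": ",
                                                 conditionMessage(e)))
                  })
  h <- homography(fit$matrix, inlier_count = sum(fit$inliers))
  list(transform = h,
       warped = warp_image(moving, h, fill = 255,
                           out_dim = dim(reference)[1:2]))
}

# ---- patch grid -------------------------------------------------------------

#' Plan an overlapping patch grid
#'
#' Origins are 0-based `(row, col)` top-left corners of half-open
#' `[r, r + patch) x [c, c + patch)` tiles, row-major.  The canvas is
#' (virtually) reflect-padded at the bottom/right so the lattice covers
#' every pixel.
#'
#' @param img_dim `c(H, W)`.
#' @param patch_size tile width in pixels.
#' @param stride step between tile origins; must not exceed `patch_size`.
#' @return list with `origins` (data frame `row`, `col`), `patch_size`,
#'   `stride`, `padded_dim`, `img_dim`.
#' @export
patch_grid <- function(img_dim, patch_size = 512, stride = 256) {
  if (stride > patch_size)
    vs_config_error("stride must not exceed patch_size")
  if (stride < 1) vs_config_error("stride must be >= 1")
  n_axis <- function(d) {
    if (d <= patch_size) 1L else as.integer(ceiling((d - patch_size) / stride) + 1)
  }
  nr <- n_axis(img_dim[1]); nc <- n_axis(img_dim[2])
  padded <- c((nr - 1L) * stride + patch_size, (nc - 1L) * stride + patch_size)
  origins <- expand.grid(col = (seq_len(nc) - 1L) * stride,
                         row = (seq_len(nr) - 1L) * stride)[, c("row", "col")]
  origins <- origins[order(origins$row, origins$col), , drop = FALSE]
  rownames(origins) <- NULL
  list(origins = origins, patch_size = as.integer(patch_size),
       stride = as.integer(stride), padded_dim = as.integer(padded),
       img_dim = as.integer(img_dim[1:2]))
}

crop_tile <- function(img, row0, col0, size) {
  if (length(dim(img)) == 3L)
    img[row0 + seq_len(size), col0 + seq_len(size), , drop = FALSE]
  else img[row0 + seq_len(size), col0 + seq_len(size), drop = FALSE]
}

#' Extract overlapping patches from an aligned image pair
#'
#' Applies one shared grid to both images (so patches at the same origin
#' cover identical coordinates), reflect-padding each canvas up to the
#' tiling lattice, and writes the tiles as PNG files named
#' `{pair_id}_r{row}_c{col}.png` under `out_dir/unstained` and
#' `out_dir/stained`.
#'
#' @param unstained,stained raster arrays of identical size.
#' @param out_dir output directory.
#' @param pair_id identifier prefix for tile filenames.
#' @param patch_size,stride grid parameters (defaults 512 / 256, i.e. 50%
#'   overlap between consecutive patches).
#' @return data frame of patch records: `pair_id`, `row`, `col`,
#'   `foreground_fraction` (NA until [filter_background_patches()]),
#'   `unstained_patch_path`, `stained_patch_path`.
#' @export
extract_patches <- function(unstained, stained, out_dir, pair_id = "pair",
                            patch_size = 512, stride = 256) {
  if (!all(dim(unstained) == dim(stained)))
    vs_input_error("unstained and stained images must have identical shape")
  grid <- patch_grid(dim(unstained)[1:2], patch_size, stride)
  pu <- reflect_pad_br(unstained, grid$padded_dim[1] - dim(unstained)[1],
                       grid$padded_dim[2] - dim(unstained)[2])
  ps <- reflect_pad_br(stained, grid$padded_dim[1] - dim(stained)[1],
                       grid$padded_dim[2] - dim(stained)[2])
  du <- file.path(out_dir, "unstained"); ds <- file.path(out_dir, "stained")
  dir.create(du, recursive = TRUE, showWarnings = FALSE)
  dir.create(ds, recursive = TRUE, showWarnings = FALSE)
  recs <- grid$origins
  recs$pair_id <- pair_id
  recs$foreground_fraction <- NA_real_
  recs$unstained_patch_path <- NA_character_
  recs$stained_patch_path <- NA_character_
  for (i in seq_len(nrow(recs))) {
    r0 <- recs$row[i]; c0 <- recs$col[i]
    fn <- sprintf("%s_r%d_c%d.png", pair_id, r0, c0)
    write_image(crop_tile(pu, r0, c0, patch_size), file.path(du, fn))
    write_image(crop_tile(ps, r0, c0, patch_size), file.path(ds, fn))
    recs$unstained_patch_path[i] <- file.path(du, fn)
    recs$stained_patch_path[i] <- file.path(ds, fn)
  }
  recs[, c("pair_id", "row", "col", "foreground_fraction",
           "unstained_patch_path", "stained_patch_path")]
}

#' Drop patches that are mostly background
#'
#' Computes each patch's tissue fraction from the foreground mask (padded
#' the same way the images were) and keeps records whose fraction is at
#' least `min_fraction`.  Idempotent and order-independent.
#'
#' @param records patch record data frame from [extract_patches()].
#' @param mask H x W logical foreground mask for the source image.
#' @param min_fraction minimum foreground fraction to keep (default 0.05).
#' @param patch_size tile width used at extraction.
#' @return the kept records with `foreground_fraction` filled in.
#' @export
filter_background_patches <- function(records, mask, min_fraction = 0.05,
                                      patch_size = 512) {
  if (min_fraction < 0 || min_fraction > 1)
    vs_config_error("min_fraction must lie in [0, 1]")
  if (nrow(records) == 0) return(records)
  need_h <- max(records$row) + patch_size
  need_w <- max(records$col) + patch_size
  pm <- reflect_pad_br(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                       max(0, need_h - nrow(mask)),
                       max(0, need_w - ncol(mask)))
  frac <- vapply(seq_len(nrow(records)), function(i) {
    mean(crop_tile(pm, records$row[i], records$col[i], patch_size))
  }, numeric(1))
  records$foreground_fraction <- frac
  records[frac >= min_fraction, , drop = FALSE]
}
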
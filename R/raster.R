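# Raster images are plain numeric arrays of dim c(H, W, 3) on the 0..255
# scale (doubles; callers round on write).  Pixel coordinates are 0-based
# (x = column, y = row) with pixel centres at integers; homographies act on
# homogeneous (x, y, 1) column vectors.

#' Read an 8-bit RGB image
#'
#' Reads a PNG (or TIFF) file into an H x W x 3 numeric array on the 0..255
#' scale.  Grayscale images are replicated to three channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path file path; format inferred from the extension.
#' @return numeric array `c(H, W, 3)` with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) vs_io_error(paste0("image file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    EBImage::imageData(EBImage::transpose(EBImage::readImage(path)))
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an 8-bit RGB image
#'
#' Rounds to integer levels, clamps to `[0, 255]` and writes a PNG.
#'
#' @param img numeric array `c(H, W, 3)` (or `c(H, W)` for a label map) on
#'   the 0..255 scale.
#' @param path output path.
#' @export
write_image <- function(img, path) {
  x <- pmin(pmax(round(img), 0), 255) / 255
  ok <- tryCatch({ png::writePNG(x, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) vs_io_error(paste0("cannot write image: ", path))
  invisible(path)
}

#' @keywords internal
rgb_to_gray <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

#' Convert a raster image to model space
#'
#' Model tensors are `3 x (H*W)` matrices with values in `[-1, 1]`; the
#' spatial index runs down columns first (column-major of the H x W plane).
#' @keywords internal
as_model_space <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  t(matrix(img, h * w, 3)) / 127.5 - 1
}

#' @keywords internal
from_model_space <- function(x, h, w) {
  img <- array(t(x), c(h, w, nrow(x)))
  clamp255((img + 1) * 127.5)
}

# ---- homographies -----------------------------------------------------------

#' Construct a homography transform
#'
#' A 3 x 3 projective map acting on homogeneous pixel coordinates
#' `(x, y, 1)` (x = column, y = row, 0-based).  The matrix is normalised so
#' the bottom-right entry is 1 and must be invertible.
#'
#' @param matrix 3 x 3 numeric matrix.
#' @param inlier_count optional number of keypoint matches supporting an
#'   estimated transform.
#' @return an object of class `homography`.
#' @export
homography <- function(matrix, inlier_count = NA_integer_) {
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(3L, 3L)) || !all(is.finite(m)))
    vs_input_error("homography needs a finite 3 x 3 matrix")
  if (abs(det(m)) < 1e-12)
    vs_input_error("homography matrix is singular")
  if (abs(m[3, 3]) < 1e-12)
    vs_input_error("homography cannot be normalised (h33 ~ 0)")
  m <- m / m[3, 3]
  structure(list(matrix = m, inlier_count = inlier_count),
            class = "homography")
}

#' @export
print.homography <- function(x, ...) {
  cat("homography (h33 = 1",
      if (!is.na(x$inlier_count)) paste0(", ", x$inlier_count, " inliers"),
      ")\n", sep = "")
  print(round(x$matrix, 6))
  invisible(x)
}

#' Identity homography
#' @export
homography_identity <- function() homography(diag(3))

#' Build a similarity homography from rotation + translation
#'
#' @param angle_deg rotation in degrees, about `center`.
#' @param tx,ty translation in pixels (x = column, y = row).
#' @param center rotation centre `c(x, y)`; defaults to the origin.
#' @param scale isotropic scale factor.
#' @export
homography_similarity <- function(angle_deg = 0, tx = 0, ty = 0,
                                  center = c(0, 0), scale = 1) {
  th <- angle_deg * pi / 180
  r <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(center[1], center[2]) - r %*% c(center[1], center[2])
  m <- rbind(cbind(r, shift + c(tx, ty)), c(0, 0, 1))
  homography(m)
}

#' Compose homographies (apply `b` first, then `a`)
#' @export
homography_compose <- function(a, b) homography(a$matrix %*% b$matrix)

#' Invert a homography
#' @export
homography_inverse <- function(h) homography(solve(h$matrix))

#' Apply a homography to points
#'
#' @param h a [homography()].
#' @param pts n x 2 matrix of `(x, y)` coordinates.
#' @return n x 2 matrix of mapped coordinates.
#' @export
apply_homography <- function(h, pts) {
  pts <- rbind(t(as.matrix(pts)), 1)
  out <- h$matrix %*% pts
  t(out[1:2, , drop = FALSE] / rep(out[3, ], each = 2))
}

#' Warp an image by a homography
#'
#' Each output pixel `p` takes the bilinearly interpolated value of the
#' input at `inverse(h) p`; locations falling outside the input frame are
#' set to `fill`.
#'
#' @param img raster array `c(H, W, C)`.
#' @param h a [homography()] mapping input coordinates to output coordinates.
#' @param fill fill colour (length 1 or C) on the 0..255 scale.
#' @param out_dim output `c(H, W)`; defaults to the input size.
#' @export
warp_image <- function(img, h, fill = 255, out_dim = dim(img)[1:2]) {
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  hinv <- solve(h$matrix)
  cpp_warp_bilinear(img, dim(img)[1], dim(img)[2], dim(img)[3],
                    hinv, as.integer(out_dim[1]), as.integer(out_dim[2]),
                    as.numeric(fill))
}

#' Reflect-pad a raster image at the bottom/right
#' @keywords internal
reflect_pad_br <- function(img, pad_h, pad_w) {
  d <- dim(img)
  if (pad_h == 0 && pad_w == 0) return(img)
  mirror <- function(i, n) {           # 0-based reflect without edge repeat
    if (n == 1L) return(rep(0L, length(i)))
    p <- 2L * n - 2L
    i <- i %% p
    ifelse(i >= n, p - i, i)
  }
  h <- d[1]; w <- d[2]
  ridx <- mirror(seq_len(h + pad_h) - 1L, h) + 1L
  cidx <- mirror(seq_len(w + pad_w) - 1L, w) + 1L
  if (length(d) == 3L) img[ridx, cidx, , drop = FALSE] else img[ridx, cidx, drop = FALSE]
}
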
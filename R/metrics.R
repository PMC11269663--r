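# Quantitative evaluation: Frechet distance between Gaussian fits of
# image features (FID) and polynomial-kernel squared MMD (KID), with a
# pluggable feature extractor.  The production choice for both metrics is
# the 2048-feature pool3 layer of a pretrained Inception-v3 at 299 x 299;
# since those weights cannot be bundled, a deterministic random-projection
# "toy" extractor is provided and is the default for desk-scale work.

#' Feature extractors
#'
#' `toy_extractor()` block-averages an image to a `pool x pool` grid per
#' channel, projects the flattened grid through a fixed seeded Gaussian
#' matrix and squashes with tanh -- a cheap, bit-reproducible stand-in
#' feature map that is sensitive to colour and coarse structure.
#' `inception_extractor()` declares the 2048-feature Inception-v3 pool3
#' configuration (images resized to 299 x 299); calling
#' [extract_features()] with it raises an actionable error unless the
#' caller supplies the network, because pretrained weights are not
#' bundled.
#'
#' @param d feature dimension of the toy extractor.
#' @param pool pooling grid width.
#' @export
toy_extractor <- function(d = 64L, pool = 8L) {
  structure(list(id = sprintf("toy_d%d_p%d", d, pool),
                 d = as.integer(d), pool = as.integer(pool)),
            class = c("toy_extractor", "feature_extractor"))
}

#' @rdname toy_extractor
#' @export
inception_extractor <- function() {
  structure(list(id = "inception_pool3", d = 2048L, resize = 299L),
            class = c("inception_extractor", "feature_extractor"))
}

block_pool <- function(img, pool) {
  h <- dim(img)[1]; w <- dim(img)[2]
  rb <- rep(seq_len(pool), diff(round(seq(0, h, length.out = pool + 1))))
  cb <- rep(seq_len(pool), diff(round(seq(0, w, length.out = pool + 1))))
  cnt <- outer(tabulate(rb, pool), tabulate(cb, pool))
  as.numeric(vapply(1:3, function(ch) {
    s <- t(rowsum(t(rowsum(img[, , ch], rb)), cb))  # row-bins x col-bins
    as.numeric(s / cnt)
  }, numeric(pool * pool)))
}

toy_projection <- function(extractor) {
  # fixed internal seed: the extractor is part of the metric's definition
  # and must not move with analysis seeds
  with_seed(770013L, matrix(rnorm(extractor$d * 3L * extractor$pool^2),
                            extractor$d) / sqrt(3 * extractor$pool^2))
}

#' Extract features from a set of images
#'
#' @param images list of raster arrays (0..255 scale) or a character
#'   vector of PNG paths.
#' @param extractor a [toy_extractor()] or [inception_extractor()].
#' @return n x d feature matrix, one row per image.
#' @export
extract_features <- function(images, extractor = toy_extractor()) {
  if (inherits(extractor, "inception_extractor"))
    vs_config_error(paste0(
      "pretrained Inception-v3 weights are not bundled with this package; ",
      "use toy_extractor() for a deterministic, download-free feature map"))
  if (!inherits(extractor, "toy_extractor"))
    vs_config_error("unknown feature extractor")
  if (is.character(images)) images <- lapply(images, read_image)
  proj <- toy_projection(extractor)
  feats <- t(vapply(images, function(img) {
    v <- block_pool(img, extractor$pool) / 255
    tanh(as.numeric(proj %*% as.numeric(v)))
  }, numeric(extractor$d)))
  feats
}

#' Gaussian fit of a feature matrix
#'
#' @param feats n x d feature matrix, n >= 2.
#' @param extractor_id provenance tag; distances are only defined between
#'   distributions from the same extractor.
#' @return a `feature_distribution` with `mean`, `covariance`, `n`.
#' @export
feature_distribution <- function(feats, extractor_id = "unknown") {
  feats <- as.matrix(feats)
  if (nrow(feats) < 2) vs_input_error("need at least 2 samples for a Gaussian fit")
  structure(list(mean = colMeans(feats), covariance = stats::cov(feats),
                 n = nrow(feats), extractor_id = extractor_id),
            class = "feature_distribution")
}

sym_sqrtm <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Frechet distance between two Gaussian feature fits
#'
#' `||mu_a - mu_b||^2 + tr(S_a + S_b - 2 (S_a S_b)^{1/2})`, computed with
#' a small diagonal jitter and symmetric eigendecompositions so the matrix
#' square root stays real.
#'
#' @param dist_a,dist_b [feature_distribution()]s from the same extractor.
#' @param jitter added to covariance diagonals before the square root.
#' @export
frechet_distance <- function(dist_a, dist_b, jitter = 1e-6) {
  if (!identical(dist_a$extractor_id, dist_b$extractor_id))
    vs_input_error("feature distributions come from different extractors")
  if (length(dist_a$mean) != length(dist_b$mean))
    vs_input_error("feature dimensions differ")
  sa <- dist_a$covariance + diag(jitter, length(dist_a$mean))
  sb <- dist_b$covariance + diag(jitter, length(dist_b$mean))
  rs <- sym_sqrtm(sa)
  covmean <- sym_sqrtm(rs %*% sb %*% rs)
  dmu <- dist_a$mean - dist_b$mean
  sum(dmu^2) + sum(diag(sa)) + sum(diag(sb)) - 2 * sum(diag(covmean))
}

poly_kernel <- function(x, y) {
  d <- ncol(x)
  (tcrossprod(x, y) / d + 1)^3
}

mmd2_unbiased <- function(x, y) {
  m <- nrow(x); n <- nrow(y)
  kxx <- poly_kernel(x, x); kyy <- poly_kernel(y, y); kxy <- poly_kernel(x, y)
  (sum(kxx) - sum(diag(kxx))) / (m * (m - 1)) +
    (sum(kyy) - sum(diag(kyy))) / (n * (n - 1)) -
    2 * mean(kxy)
}

#' Kernel distance (KID) between two feature sets
#'
#' The unbiased squared maximum mean discrepancy under the polynomial
#' kernel `k(x, y) = (x'y / d + 1)^3`, averaged over seeded random
#' subsets; the spread over subsets is reported as `kid_std`.
#'
#' @param features_a,features_b n x d feature matrices.
#' @param subset_size samples drawn from each set per subset (>= 2).
#' @param n_subsets number of subsets averaged.
#' @param seed subset-sampling seed.
#' @return list with `kid_mean` and `kid_std`.
#' @export
kid <- function(features_a, features_b, subset_size = 100L,
                n_subsets = 10L, seed = 1L) {
  features_a <- as.matrix(features_a); features_b <- as.matrix(features_b)
  if (subset_size < 2) vs_config_error("subset_size must be >= 2")
  if (subset_size > min(nrow(features_a), nrow(features_b)))
    vs_input_error("subset_size exceeds the smaller feature set")
  vals <- with_seed(seed, vapply(seq_len(n_subsets), function(i) {
    ia <- sample.int(nrow(features_a), subset_size)
    ib <- sample.int(nrow(features_b), subset_size)
    mmd2_unbiased(features_a[ia, , drop = FALSE],
                  features_b[ib, , drop = FALSE])
  }, numeric(1)))
  list(kid_mean = mean(vals), kid_std = if (n_subsets > 1) sd(vals) else 0)
}

#' Evaluate two image sets against each other
#'
#' Computes FID and KID between the PNG images of two directories.
#'
#' @param dir_a,dir_b directories of PNG images (at least 2 each).
#' @param extractor a feature extractor.
#' @param subset_size,n_subsets,seed KID settings; `subset_size` is capped
#'   at the smaller set size.
#' @param report_path optional path for a JSON report.
#' @return a `metric_report` list: `fid`, `kid_mean`, `kid_std`, `n_a`,
#'   `n_b`, `extractor_id` and the KID settings used.
#' @export
evaluate_sets <- function(dir_a, dir_b, extractor = toy_extractor(),
                          subset_size = 100L, n_subsets = 10L, seed = 1L,
                          report_path = NULL) {
  fa <- sort(list.files(dir_a, pattern = "\\.png$", full.names = TRUE))
  fb <- sort(list.files(dir_b, pattern = "\\.png$", full.names = TRUE))
  if (length(fa) < 2 || length(fb) < 2)
    vs_input_error("both image sets need at least 2 images")
  xa <- extract_features(fa, extractor)
  xb <- extract_features(fb, extractor)
  ss <- min(subset_size, nrow(xa), nrow(xb))
  k <- kid(xa, xb, ss, n_subsets, seed)
  rep <- list(fid = frechet_distance(feature_distribution(xa, extractor$id),
                                     feature_distribution(xb, extractor$id)),
              kid_mean = k$kid_mean, kid_std = k$kid_std,
              n_a = nrow(xa), n_b = nrow(xb), extractor_id = extractor$id,
              subset_size = ss, n_subsets = n_subsets, seed = seed)
  class(rep) <- "metric_report"
  if (!is.null(report_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      vs_io_error("jsonlite is required to write JSON reports")
    jsonlite::write_json(unclass(rep), report_path, auto_unbox = TRUE,
                         digits = NA)
  }
  rep
}

#' FID between two in-memory image sets
#'
#' Convenience wrapper used in tests and experiments.
#' @param images_a,images_b lists of raster arrays.
#' @param extractor a feature extractor.
#' @export
fid_between <- function(images_a, images_b, extractor = toy_extractor()) {
  frechet_distance(
    feature_distribution(extract_features(images_a, extractor), extractor$id),
    feature_distribution(extract_features(images_b, extractor), extractor$id))
}
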
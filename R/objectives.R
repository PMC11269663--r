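# The five losses of the dual contrastive objective, as plain numeric
# functions.  The training loop evaluates the same formulas through the
# autodiff tape; tests assert the two routes agree.

#' Loss weights of the collective objective
#'
#' Defaults are the relative weights of the dual contrastive objective:
#' `lambda_gan = 1`, `lambda_nce = 2`, `lambda_idt = 1`.  The contrastive
#' temperature defaults to 0.07.
#'
#' @param lambda_gan,lambda_nce,lambda_idt non-negative weights.
#' @param temperature softmax temperature, > 0.
#' @export
loss_weights <- function(lambda_gan = 1, lambda_nce = 2, lambda_idt = 1,
                         temperature = 0.07) {
  if (any(c(lambda_gan, lambda_nce, lambda_idt) < 0))
    vs_config_error("loss weights must be >= 0")
  if (temperature <= 0) vs_config_error("temperature must be > 0")
  structure(list(lambda_gan = lambda_gan, lambda_nce = lambda_nce,
                 lambda_idt = lambda_idt, temperature = temperature),
            class = "loss_weights")
}

#' Cosine similarity
#'
#' `sim(u, v) = u'v / (||u|| ||v||)`, in `[-1, 1]`.
#' @param u,v non-zero numeric vectors of equal length.
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    vs_input_error("cosine similarity of a zero vector is undefined")
  sum(u * v) / (nu * nv)
}

#' A single contrastive classification batch
#'
#' Query `v`, positive `v+` and `N` negatives, classified as an
#' (N+1)-way problem at temperature `tau`.
#'
#' @param query,positive unit K-vectors.
#' @param negatives N x K matrix of unit vectors (0 rows allowed).
#' @param temperature tau > 0.
#' @export
nce_batch <- function(query, positive, negatives = NULL,
                      temperature = 0.07) {
  if (temperature <= 0) vs_config_error("temperature must be > 0")
  if (is.null(negatives)) negatives <- matrix(numeric(0), 0, length(query))
  negatives <- as.matrix(negatives)
  if (ncol(negatives) != length(query) && nrow(negatives) > 0)
    vs_input_error("negatives must be an N x K matrix")
  structure(list(query = query, positive = positive,
                 negatives = negatives, temperature = temperature),
            class = "nce_batch")
}

#' Contrastive cross-entropy of one batch
#'
#' The (N+1)-way classification loss
#' `-log[ exp(sim(v, v+)/tau) / (exp(sim(v, v+)/tau) +
#'   sum_n exp(sim(v, v_n-)/tau)) ]`,
#' evaluated with a log-sum-exp-stable formulation.  Zero when there are
#' no negatives and the query equals the positive; strictly positive
#' whenever N >= 1.
#'
#' @param batch an [nce_batch()].
#' @export
nce_cross_entropy <- function(batch) {
  if (!inherits(batch, "nce_batch")) vs_input_error("batch must be an nce_batch")
  tau <- batch$temperature
  sp <- cosine_similarity(batch$query, batch$positive) / tau
  if (nrow(batch$negatives) == 0) return(0)
  sn <- apply(batch$negatives, 1, function(n)
    cosine_similarity(batch$query, n)) / tau
  all_s <- c(sp, sn)
  mx <- max(all_s)
  (mx + log(sum(exp(all_s - mx)))) - sp
}

#' Multilayer patchwise contrastive (PatchNCE) loss
#'
#' For each tapped layer and each sampled location `s`, the translated
#' image's embedding at `s` is the query, the source image's embedding at
#' `s` is the positive, and the source embeddings at all other locations
#' of the same layer are the negatives.  The loss is the mean of the
#' per-location contrastive cross-entropies over locations and layers.
#'
#' For the A-to-B direction the input stack comes from the A-domain
#' encoder + head applied to `a` and the output stack from the B-domain
#' encoder + head applied to the translation of `a`; the B-to-A direction
#' is symmetric.
#'
#' @param direction `"A2B"` or `"B2A"` (bookkeeping; the formula is
#'   direction-symmetric).
#' @param input_stack,output_stack `embedding_stack`s sharing layers and
#'   locations (see [sample_and_project()]).
#' @param temperature contrastive temperature.
#' @export
patchnce_loss <- function(direction = c("A2B", "B2A"), input_stack,
                          output_stack, temperature = 0.07) {
  match.arg(direction)
  if (temperature <= 0) vs_config_error("temperature must be > 0")
  if (!identical(input_stack$layer_ids, output_stack$layer_ids) ||
      !identical(input_stack$locations, output_stack$locations))
    vs_input_error("stacks must share layers and sampled locations")
  per_layer <- vapply(seq_along(input_stack$vectors), function(li) {
    z <- input_stack$vectors[[li]]       # positives + negatives
    zhat <- output_stack$vectors[[li]]   # queries
    logits <- tcrossprod(zhat, z) / temperature
    mx <- apply(logits, 1, max)
    mean(mx + log(rowSums(exp(logits - mx))) - diag(logits))
  }, numeric(1))
  mean(per_layer)
}

#' Adversarial losses from discriminator output maps
#'
#' In the default `"log"` (cross-entropy) form the maps are realness
#' probabilities in (0, 1):
#' `d_loss = -mean(log D(real))/2 - mean(log(1 - D(fake)))/2` and the
#' non-saturating generator loss `g_loss = -mean(log D(fake))`.  The
#' `"lsgan"` form takes raw outputs and uses squared errors against the
#' 1/0 targets.
#'
#' @param direction `"A2B"` (discriminator on domain B) or `"B2A"`.
#' @param d_real,d_fake discriminator output maps on real and translated
#'   images.
#' @param form `"log"` or `"lsgan"`.
#' @return list with `d_loss` and `g_loss`.
#' @export
adversarial_losses <- function(direction = c("A2B", "B2A"), d_real, d_fake,
                               form = c("log", "lsgan")) {
  match.arg(direction)
  form <- tryCatch(match.arg(form),
                   error = function(e) vs_config_error(
                     "adversarial form must be \"log\" or \"lsgan\""))
  if (form == "log") {
    eps <- 1e-12
    d_loss <- -mean(log(d_real + eps)) / 2 - mean(log(1 - d_fake + eps)) / 2
    g_loss <- -mean(log(d_fake + eps))
  } else {
    d_loss <- mean((d_real - 1)^2) / 2 + mean(d_fake^2) / 2
    g_loss <- mean((d_fake - 1)^2)
  }
  list(d_loss = d_loss, g_loss = g_loss)
}

#' Identity loss
#'
#' `E||G2(a) - a||_1 + E||G1(b) - b||_1`: each generator, fed an image
#' already in its output domain, should act as the identity.  Keeps the
#' translators colour-preserving.
#'
#' @param g1 generator mapping A to B (a generator object or a plain
#'   image-to-image function).
#' @param g2 generator mapping B to A.
#' @param a,b images in `[-1, 1]` from domains A and B.
#' @export
identity_loss <- function(g1, g2, a, b) {
  if (!all(dim(a) == dim(b)))
    vs_input_error("identity loss images must share a shape")
  apply_gen <- function(g, img)
    if (is.function(g)) g(img) else generator_forward(g, img)
  mean(abs(apply_gen(g2, a) - a)) + mean(abs(apply_gen(g1, b) - b))
}

#' The collective training objective
#'
#' `lambda_gan (L_GAN1 + L_GAN2) + lambda_nce L_PatchNCE_A +
#'  lambda_nce L_PatchNCE_B + lambda_idt L_identity`.
#'
#' @param components list (or named numeric vector) with elements `gan1`,
#'   `gan2`, `nce_a`, `nce_b`, `idt`.
#' @param weights a [loss_weights()].
#' @export
total_objective <- function(components, weights = loss_weights()) {
  components <- as.list(components)
  need <- c("gan1", "gan2", "nce_a", "nce_b", "idt")
  for (k in need) {
    v <- components[[k]]
    if (is.null(v) || !is.finite(v))
      vs_numeric_error(paste0("objective component ", k,
                              " is missing or non-finite"))
  }
  weights$lambda_gan * (components$gan1 + components$gan2) +
    weights$lambda_nce * components$nce_a +
    weights$lambda_nce * components$nce_b +
    weights$lambda_idt * components$idt
}
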
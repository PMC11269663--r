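# Minimal reverse-mode autodiff over matrix-valued nodes, sized for the
# small convolutional networks this package trains on CPU.  Feature maps
# are C x (H*W) matrices (spatial index column-major of the H x W plane);
# embedding matrices are S x K.  A tape records operation nodes in
# execution order; backward() walks it in reverse.  Parameters live
# outside the tape and accumulate gradients across a whole forward graph.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tape_push <- function(tp, node) {
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- node
  tp$n <- n
  node
}

node_new <- function(tp, val, bw = NULL, H = NA_integer_, W = NA_integer_) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bw <- bw
  nd$H <- H; nd$W <- W
  tape_push(tp, nd)
}

accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
}

#' @keywords internal
tape_backward <- function(tp, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

# ---- parameters -------------------------------------------------------------

param_new <- function(val) {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- NULL
  p$m <- NULL; p$v <- NULL
  p
}

param_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

#' One Adam update over a set of parameters
#' @keywords internal
adam_step <- function(params, lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8, t = 1L) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad
    if (is.null(p$m)) { p$m <- g * 0; p$v <- g * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$val <- p$val - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

# ---- ops --------------------------------------------------------------------

op_input <- function(tp, val, H = NA_integer_, W = NA_integer_) {
  node_new(tp, val, bw = NULL, H = H, W = W)
}

op_conv <- function(tp, x, w, b, k, stride = 1L, pad = 0L,
                    pad_mode = c("zero", "reflect")) {
  pm <- if (match.arg(pad_mode) == "reflect") 1L else 0L
  H <- x$H; W <- x$W
  cols <- cpp_im2col(x$val, H, W, k, stride, pad, pm)
  val <- w$val %*% cols + b$val   # b recycles down columns (per channel)
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  cin <- nrow(x$val)
  nd <- node_new(tp, val, H = Ho, W = Wo)
  nd$bw <- function(g) {
    accum(w, tcrossprod(g, cols))
    accum(b, rowSums(g))
    accum(x, cpp_col2im(crossprod(w$val, g), cin, H, W, k, stride, pad, pm))
  }
  nd
}

op_instance_norm <- function(tp, x, eps = 1e-5) {
  fw <- cpp_instance_norm(x$val, eps)
  y <- fw$y
  nd <- node_new(tp, y, H = x$H, W = x$W)
  nd$bw <- function(g) {
    accum(x, cpp_instance_norm_back(g, y, fw$inv_sd))
  }
  nd
}

op_relu <- function(tp, x) {
  y <- cpp_relu(x$val)
  nd <- node_new(tp, y, H = x$H, W = x$W)
  nd$bw <- function(g) accum(x, cpp_relu_back(g, y))
  nd
}

op_lrelu <- function(tp, x, alpha = 0.2) {
  slope <- (x$val > 0) * (1 - alpha) + alpha
  nd <- node_new(tp, x$val * slope, H = x$H, W = x$W)
  nd$bw <- function(g) accum(x, g * slope)
  nd
}

op_tanh <- function(tp, x) {
  y <- tanh(x$val)
  nd <- node_new(tp, y, H = x$H, W = x$W)
  nd$bw <- function(g) accum(x, g * (1 - y * y))
  nd
}

op_add <- function(tp, a, b) {
  nd <- node_new(tp, a$val + b$val, H = a$H, W = a$W)
  nd$bw <- function(g) { accum(a, g); accum(b, g) }
  nd
}

op_upsample2 <- function(tp, x) {
  H <- x$H; W <- x$W
  nd <- node_new(tp, cpp_upsample2(x$val, H, W), H = 2L * H, W = 2L * W)
  nd$bw <- function(g) accum(x, cpp_upsample2_back(g, H, W))
  nd
}

# gather spatial locations (columns) and transpose to S x C
op_gather_t <- function(tp, x, idx) {
  nd <- node_new(tp, t(x$val[, idx, drop = FALSE]))
  cdim <- nrow(x$val); sdim <- ncol(x$val)
  nd$bw <- function(g) {
    xg <- matrix(0, cdim, sdim)
    xg[, idx] <- t(g)
    accum(x, xg)
  }
  nd
}

# x: n x din, w: dout x din, b: dout
op_linear <- function(tp, x, w, b) {
  val <- tcrossprod(x$val, w$val)
  val <- sweep(val, 2, b$val, "+")
  nd <- node_new(tp, val)
  nd$bw <- function(g) {
    accum(w, crossprod(g, x$val))
    accum(b, colSums(g))
    accum(x, g %*% w$val)
  }
  nd
}

op_l2norm_rows <- function(tp, x, eps = 1e-12) {
  r <- sqrt(rowSums(x$val * x$val) + eps)
  y <- x$val / r
  nd <- node_new(tp, y)
  nd$bw <- function(g) accum(x, (g - y * rowSums(g * y)) / r)
  nd
}

# mean_s CE(logits_s, target = s) with logits = zhat %*% t(z) / tau:
# the contrastive (N+1)-way classification over locations, positives on
# the diagonal, negatives = the other locations of the same layer.
op_patch_nce <- function(tp, zhat, z, tau) {
  s_n <- nrow(zhat$val)
  logits <- tcrossprod(zhat$val, z$val) / tau
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  den <- rowSums(ex)
  p <- ex / den
  loss <- mean(mx + log(den) - diag(logits))
  nd <- node_new(tp, loss)
  nd$bw <- function(g) {
    dl <- (p - diag(s_n)) * (g / s_n) / tau
    accum(zhat, dl %*% z$val)
    accum(z, crossprod(dl, zhat$val))
  }
  nd
}

# mean(softplus(sign * x)); -log sigmoid(x) = softplus(-x)
op_softplus_mean <- function(tp, x, sign = 1) {
  sx <- sign * x$val
  val <- mean(ifelse(sx > 30, sx, log1p(exp(pmin(sx, 30)))))
  nd <- node_new(tp, val)
  n <- length(x$val)
  nd$bw <- function(g) accum(x, g * sign * stats::plogis(sx) / n)
  nd
}

op_mean_sq <- function(tp, x, target) {
  d <- x$val - target
  nd <- node_new(tp, mean(d * d))
  n <- length(d)
  nd$bw <- function(g) accum(x, g * 2 * d / n)
  nd
}

op_mean_abs_diff <- function(tp, a, b) {
  d <- a$val - b$val
  nd <- node_new(tp, mean(abs(d)))
  n <- length(d)
  nd$bw <- function(g) {
    s <- g * sign(d) / n
    accum(a, s); accum(b, -s)
  }
  nd
}

op_weighted_sum <- function(tp, nodes, weights) {
  val <- sum(mapply(function(nd, w) w * nd$val, nodes, weights))
  nd <- node_new(tp, val)
  nd$bw <- function(g) {
    for (i in seq_along(nodes)) accum(nodes[[i]], g * weights[i])
  }
  nd
}

# detach: value enters a new graph as a constant
op_const <- function(tp, val, H = NA_integer_, W = NA_integer_) {
  node_new(tp, val, bw = NULL, H = H, W = W)
}
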
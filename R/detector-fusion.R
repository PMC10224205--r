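## Adaptive multiscale decision fusion (AMDF): softmax-parameterized scale
## reliabilities and the weighted fusion of per-scale pre-detection tensors.

#' Softmax scale reliabilities
#'
#' Maps three unconstrained real parameters (lambda) to reliabilities
#' \code{alpha = exp(l_a) / (exp(l_a) + exp(l_b) + exp(l_g))} (and cyclically
#' for beta, gamma). Numerically stabilized by max subtraction, so the
#' components always sum to 1 and each lies in \code{[0, 1]} even for large
#' inputs.
#'
#' @param lambda_alpha,lambda_beta,lambda_gamma Finite reals. Alternatively
#'   pass a length-3 vector as the first argument.
#' @return Named numeric vector \code{c(alpha, beta, gamma)}.
#' @export
softmax_reliabilities <- function(lambda_alpha, lambda_beta = NULL,
                                  lambda_gamma = NULL) {
  l <- if (is.null(lambda_beta) && length(lambda_alpha) == 3) {
    as.numeric(lambda_alpha)
  } else {
    c(lambda_alpha, lambda_beta, lambda_gamma)
  }
  if (length(l) != 3 || !all(is.finite(l))) {
    stopf("softmax_reliabilities requires three finite lambda values")
  }
  e <- exp(l - max(l))
  out <- e / sum(e)
  names(out) <- c("alpha", "beta", "gamma")
  out
}

#' Fusion weights
#'
#' Bundles the three learnable lambda parameters with their derived softmax
#' reliabilities.
#'
#' @param lambda Length-3 numeric (lambda_alpha, lambda_beta, lambda_gamma).
#' @return List of class \code{fusion_weights} with \code{lambda} and
#'   \code{reliabilities}.
#' @export
fusion_weights <- function(lambda = c(0, 0, 0)) {
  structure(list(lambda = as.numeric(lambda),
                 reliabilities = softmax_reliabilities(lambda)),
            class = "fusion_weights")
}

# Nearest-neighbour upsampling of an (N, N, C) array by integer factor f.
upsample_nearest <- function(a, f) {
  if (f == 1) return(a)
  idx_r <- rep(seq_len(dim(a)[1]), each = f)
  idx_c <- rep(seq_len(dim(a)[2]), each = f)
  a[idx_r, idx_c, , drop = FALSE]
}

# Adjoint of nearest-neighbour upsampling: sum over f x f blocks.
downsample_sum <- function(a, f) {
  if (f == 1) return(a)
  d <- dim(a)
  n <- d[1] / f
  grp <- rep(seq_len(n), each = f)
  out <- array(0, c(n, n, d[3]))
  for (ch in seq_len(d[3])) {
    tmp <- rowsum(a[, , ch], grp)
    out[, , ch] <- t(rowsum(t(tmp), grp))
  }
  out
}

#' Fuse per-scale pre-detection tensors
#'
#' Aligns the coarser grids (levels 4 and 5) to the level-3 grid by
#' nearest-neighbour upsampling and forms the reliability-weighted sum
#' \code{ys = alpha * d3 + beta * up(d4) + gamma * up(d5)} element-wise in
#' logit space. The sensitivity of \code{ys} to each \code{d_l} is exactly
#' that scale's reliability, which is the gradient contract the training
#' loop relies on.
#'
#' @param d3,d4,d5 Pre-detection arrays \code{(N_l, N_l, C)} with a common
#'   channel extent; \code{N_3 / N_4} and \code{N_3 / N_5} must be integers.
#' @param weights A [fusion_weights()] (or length-3 lambda vector).
#' @return Fused array on the level-3 grid.
#' @export
amdf_fuse <- function(d3, d4, d5, weights = fusion_weights()) {
  if (!inherits(weights, "fusion_weights")) weights <- fusion_weights(weights)
  if (dim(d3)[3] != dim(d4)[3] || dim(d3)[3] != dim(d5)[3]) {
    stopf("mismatched channel layouts across scales")
  }
  f4 <- dim(d3)[1] / dim(d4)[1]
  f5 <- dim(d3)[1] / dim(d5)[1]
  if (f4 != round(f4) || f5 != round(f5)) {
    stopf("coarse grids must divide the level-3 grid")
  }
  w <- weights$reliabilities
  w[["alpha"]] * d3 +
    w[["beta"]] * upsample_nearest(d4, as.integer(f4)) +
    w[["gamma"]] * upsample_nearest(d5, as.integer(f5))
}

#' Binary cross-entropy loss
#'
#' \code{l(y, yhat) = -sum_i [y_i log(yhat_i) + (1 - y_i) log(1 - yhat_i)]}
#' with predictions clipped to \code{[eps, 1 - eps]}, \code{eps = 1e-7}.
#'
#' @param y_true Vector of 0/1 targets.
#' @param y_pred Vector of predicted probabilities, same length.
#' @param eps Clipping constant.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(y_true, y_pred, eps = 1e-7) {
  if (length(y_true) != length(y_pred)) stopf("length mismatch in bce_loss")
  if (length(y_true) == 0) stopf("bce_loss needs at least one sample")
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  -sum(y_true * log(p) + (1 - y_true) * log(1 - p))
}

# Channel indices within the 21-channel anchor layout:
# per anchor a (1..3), channels (a-1)*7 + c(p=1, x=2, y=3, h=4, w=5, c1=6, c2=7).
anchor_channels <- function(what, n_anchors = 3L) {
  base <- (seq_len(n_anchors) - 1L) * 7L
  switch(what,
    obj = base + 1L,
    x = base + 2L, y = base + 3L, h = base + 4L, w = base + 5L,
    cls1 = base + 6L, cls2 = base + 7L,
    stopf("unknown channel group: %s", what)
  )
}

#' Per-image class confidence from detector output
#'
#' Reduces one or more pre-detection tensors to a per-class confidence in
#' \code{[0, 1]}: for every cell and anchor the product
#' \code{sigmoid(p_c) * sigmoid(c_class)} is formed, then reduced by the
#' maximum (default) or the mean of the top \code{k} products.
#'
#' @param heads A single pre-detection array (e.g. the fused \code{ys}) or a
#'   list of arrays (the baseline's three scale heads).
#' @param reduction \code{"max"} or \code{"mean_topk"}.
#' @param k Number of top products for \code{"mean_topk"}.
#' @return Named vector \code{c(benign, malignant)}.
#' @export
image_score <- function(heads, reduction = c("max", "mean_topk"), k = 5L) {
  reduction <- match.arg(reduction)
  if (is.array(heads) && !is.list(heads)) heads <- list(heads)
  if (length(heads) == 0) stopf("empty prediction tensor")
  vals <- c(benign = NA_real_, malignant = NA_real_)
  for (cls in c("benign", "malignant")) {
    ch <- if (cls == "benign") "cls1" else "cls2"
    prods <- unlist(lapply(heads, function(d) {
      if (length(d) == 0) stopf("empty prediction tensor")
      p <- sigmoid(d[, , anchor_channels("obj"), drop = FALSE])
      cc <- sigmoid(d[, , anchor_channels(ch), drop = FALSE])
      as.numeric(p * cc)
    }))
    vals[[cls]] <- if (reduction == "max") {
      max(prods)
    } else {
      mean(sort(prods, decreasing = TRUE)[seq_len(min(k, length(prods)))])
    }
  }
  vals
}
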
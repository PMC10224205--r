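## Reduced-scale single-stage pyramid detector. The backbone is a small
## cross-stage-partial design (Mish activations); three 1x1 heads emit the
## per-scale pre-detection tensors d3/d4/d5 at strides 8/16/32 with the
## standard 3 x (1 objectness + 4 box offsets + n_classes) channel layout.
## Forward and backward passes are written directly against im2col/col2im
## kernels; there is no external deep-learning runtime.

#' Detector configuration
#'
#' @param input_size Network input side in pixels; must be a multiple of 32.
#' @param width Base channel width of the backbone; parameter count grows
#'   monotonically with it.
#' @param depth Number of convolution blocks inside the cross-stage stage.
#' @param anchors 9 x 2 matrix of anchor (w, h) pairs in pixels, rows sorted
#'   small to large; rows 1-3 serve level 3, 4-6 level 4, 7-9 level 5.
#'   Defaults suit the phantom's lesion boxes; see [anchors_from_boxes()].
#' @param n_classes Number of classes (fixed at 2: benign, malignant).
#' @param variant \code{"amdf"} (decision-fusion head trained on the fused
#'   tensor) or \code{"baseline"} (independent per-scale heads).
#' @param fuse_box Whether the box-offset channels also flow through the
#'   fused tensor (\code{TRUE}) or only objectness/class do.
#' @param conf_threshold,nms_iou Decoding confidence threshold and NMS IoU.
#' @param loss_weights Named weights for the objectness/box/class loss terms.
#' @param noobj_weight Relative weight of negative-slot objectness loss.
#' @param head_activation \code{"linear"} (default) or \code{"leaky"} for the
#'   head convolutions.
#' @param score_reduction Reduction used by [image_score()].
#' @param seed Seed for deterministic weight initialization.
#' @return List of class \code{detector_config}.
#' @export
detector_config <- function(input_size = 128L, width = 8L, depth = 1L,
                            anchors = NULL, n_classes = 2L,
                            variant = c("amdf", "baseline"),
                            fuse_box = TRUE,
                            conf_threshold = 0.25, nms_iou = 0.45,
                            loss_weights = c(obj = 1, box = 1, cls = 1),
                            noobj_weight = 0.5,
                            head_activation = c("linear", "leaky"),
                            score_reduction = c("max", "mean_topk"),
                            seed = 1L) {
  variant <- match.arg(variant)
  head_activation <- match.arg(head_activation)
  score_reduction <- match.arg(score_reduction)
  if (input_size %% 32 != 0) stopf("input_size must be divisible by 32")
  if (n_classes != 2L) stopf("this detector is fixed at 2 classes")
  if (is.null(anchors)) {
    anchors <- cbind(
      w = c(8, 12, 16, 20, 26, 32, 40, 52, 64),
      h = c(8, 12, 16, 20, 26, 32, 40, 52, 64)
    )
  }
  if (!is.matrix(anchors) || nrow(anchors) != 9 || ncol(anchors) != 2) {
    stopf("anchors must be a 9 x 2 matrix of (w, h) pairs")
  }
  structure(list(
    input_size = as.integer(input_size), width = as.integer(width),
    depth = as.integer(depth), anchors = anchors, n_classes = as.integer(n_classes),
    variant = variant, fuse_box = fuse_box,
    conf_threshold = conf_threshold, nms_iou = nms_iou,
    loss_weights = loss_weights, noobj_weight = noobj_weight,
    head_activation = head_activation, score_reduction = score_reduction,
    seed = as.integer(seed)
  ), class = "detector_config")
}

#' Anchor priors from box statistics
#'
#' Clusters training box (width, height) pairs with k-means into 9 anchors,
#' sorted by area.
#'
#' @param boxes data.frame with \code{width}, \code{height} columns.
#' @param seed Seed for the k-means initialization.
#' @return 9 x 2 anchor matrix.
#' @export
anchors_from_boxes <- function(boxes, seed = 1L) {
  wh <- cbind(boxes$width, boxes$height)
  k <- min(9L, nrow(unique(wh)))
  centers <- with_seed(seed, kmeans(wh, centers = k, nstart = 5)$centers)
  if (k < 9) centers <- centers[rep(seq_len(k), length.out = 9), , drop = FALSE]
  centers <- centers[order(centers[, 1] * centers[, 2]), , drop = FALSE]
  dimnames(centers) <- list(NULL, c("w", "h"))
  centers
}

# Layer table for the fixed-topology network at a given width/depth.
layer_defs <- function(config) {
  w <- config$width
  nc <- 3L * (1L + 4L + config$n_classes)
  defs <- list(
    # full-resolution stem: particle shapes live at the 1-3 px scale, so the
    # first convolution must see the native grid before any downsampling
    b0 = list(k = 3L, s = 1L, cin = 1L, cout = w %/% 2L, act = "mish"),
    b1 = list(k = 3L, s = 2L, cin = w %/% 2L, cout = w, act = "mish"),
    b2 = list(k = 3L, s = 2L, cin = w, cout = 2L * w, act = "mish")
  )
  for (j in seq_len(config$depth)) {
    defs[[paste0("csp_path", j)]] <-
      list(k = 3L, s = 1L, cin = w, cout = w, act = "mish")
  }
  defs$csp_merge <- list(k = 1L, s = 1L, cin = 2L * w, cout = 2L * w, act = "mish")
  defs$b3 <- list(k = 3L, s = 2L, cin = 2L * w, cout = 4L * w, act = "mish")
  defs$b4 <- list(k = 3L, s = 2L, cin = 4L * w, cout = 4L * w, act = "mish")
  defs$b5 <- list(k = 3L, s = 2L, cin = 4L * w, cout = 4L * w, act = "mish")
  ha <- config$head_activation
  defs$h3 <- list(k = 1L, s = 1L, cin = 4L * w, cout = nc, act = ha)
  defs$h4 <- list(k = 1L, s = 1L, cin = 4L * w, cout = nc, act = ha)
  defs$h5 <- list(k = 1L, s = 1L, cin = 4L * w, cout = nc, act = ha)
  defs
}

#' Build a detector model
#'
#' Initializes all convolution weights (He-normal, deterministic under the
#' config seed), zero biases except a low objectness prior on the head
#' biases, and the three fusion parameters lambda at zero (equal
#' reliabilities).
#'
#' @param config A [detector_config()].
#' @return List of class \code{calc_detector} with \code{config},
#'   \code{params} and \code{lambda}.
#' @export
build_detector <- function(config = detector_config()) {
  defs <- layer_defs(config)
  params <- with_seed(config$seed, {
    lapply(defs, function(d) {
      fan_in <- d$cin * d$k * d$k
      W <- matrix(rnorm(d$cout * fan_in, 0, sqrt(2 / fan_in)), d$cout, fan_in)
      b <- numeric(d$cout)
      list(W = W, b = b)
    })
  })
  # objectness prior: start heads near "no object"
  for (h in c("h3", "h4", "h5")) {
    params[[h]]$b[anchor_channels("obj")] <- -3
  }
  structure(list(config = config, defs = defs, params = params,
                 lambda = c(0, 0, 0)),
            class = "calc_detector")
}

#' Number of trainable parameters
#' @param model A \code{calc_detector}.
#' @return Integer count (convolution weights, biases, and the three lambda).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1))) + 3
}

## -- conv layer forward/backward (fused C++ kernels) -------------------------

act_code <- function(act) switch(act, linear = 0L, leaky = 1L, mish = 2L)

conv_fwd <- function(x, def, par) {
  pad <- (def$k - 1L) %/% 2L
  r <- cpp_conv_fwd(x, par$W, par$b, def$k, def$s, pad, act_code(def$act))
  list(out = r$out, cache = list(pre = r$pre, x = x))
}

conv_bwd <- function(dout, def, par, cache, need_dx = TRUE) {
  pad <- (def$k - 1L) %/% 2L
  cpp_conv_bwd(dout, cache$pre, cache$x, par$W, def$k, def$s, pad,
               act_code(def$act), need_dx)
}

## -- full network ------------------------------------------------------------

#' Forward pass of the detector
#'
#' Maps a grayscale image to the three per-scale pre-detection tensors.
#'
#' @param model A \code{calc_detector}.
#' @param image Numeric matrix whose side is a stride-32 multiple.
#' @param keep_cache Whether to retain per-layer caches for backprop.
#' @return List with \code{d3}, \code{d4}, \code{d5} (arrays
#'   \code{N_l x N_l x 21}) and, if requested, \code{cache}.
#' @export
forward_detector <- function(model, image, keep_cache = FALSE) {
  defs <- model$defs; par <- model$params
  w <- model$config$width
  x <- array(image, c(dim(image), 1L))
  cache <- list()

  f <- conv_fwd(x, defs$b0, par$b0); a0 <- f$out; cache$b0 <- f$cache
  f <- conv_fwd(a0, defs$b1, par$b1); a1 <- f$out; cache$b1 <- f$cache
  f <- conv_fwd(a1, defs$b2, par$b2); a2 <- f$out; cache$b2 <- f$cache

  keep <- a2[, , seq_len(w), drop = FALSE]
  p <- a2[, , w + seq_len(w), drop = FALSE]
  for (j in seq_len(model$config$depth)) {
    nm <- paste0("csp_path", j)
    f <- conv_fwd(p, defs[[nm]], par[[nm]]); p <- f$out; cache[[nm]] <- f$cache
  }
  cc <- array(0, c(dim(keep)[1:2], 2L * w))
  cc[, , seq_len(w)] <- keep
  cc[, , w + seq_len(w)] <- p
  f <- conv_fwd(cc, defs$csp_merge, par$csp_merge)
  merged <- f$out; cache$csp_merge <- f$cache

  f <- conv_fwd(merged, defs$b3, par$b3); p3 <- f$out; cache$b3 <- f$cache
  f <- conv_fwd(p3, defs$b4, par$b4); p4 <- f$out; cache$b4 <- f$cache
  f <- conv_fwd(p4, defs$b5, par$b5); p5 <- f$out; cache$b5 <- f$cache

  f <- conv_fwd(p3, defs$h3, par$h3); d3 <- f$out; cache$h3 <- f$cache
  f <- conv_fwd(p4, defs$h4, par$h4); d4 <- f$out; cache$h4 <- f$cache
  f <- conv_fwd(p5, defs$h5, par$h5); d5 <- f$out; cache$h5 <- f$cache

  out <- list(d3 = d3, d4 = d4, d5 = d5)
  if (keep_cache) out$cache <- cache
  out
}

# Backward pass: gradients of the loss w.r.t. every convolution parameter,
# given gradients on the three head tensors.
backward_detector <- function(model, cache, dd3, dd4, dd5) {
  defs <- model$defs; par <- model$params
  w <- model$config$width
  grads <- list()

  g <- conv_bwd(dd3, defs$h3, par$h3, cache$h3)
  grads$h3 <- list(W = g$dW, b = g$db); dp3 <- g$dx
  g <- conv_bwd(dd4, defs$h4, par$h4, cache$h4)
  grads$h4 <- list(W = g$dW, b = g$db); dp4 <- g$dx
  g <- conv_bwd(dd5, defs$h5, par$h5, cache$h5)
  grads$h5 <- list(W = g$dW, b = g$db); dp5 <- g$dx

  g <- conv_bwd(dp5, defs$b5, par$b5, cache$b5)
  grads$b5 <- list(W = g$dW, b = g$db); dp4 <- dp4 + g$dx
  g <- conv_bwd(dp4, defs$b4, par$b4, cache$b4)
  grads$b4 <- list(W = g$dW, b = g$db); dp3 <- dp3 + g$dx
  g <- conv_bwd(dp3, defs$b3, par$b3, cache$b3)
  grads$b3 <- list(W = g$dW, b = g$db); dmerged <- g$dx

  g <- conv_bwd(dmerged, defs$csp_merge, par$csp_merge, cache$csp_merge)
  grads$csp_merge <- list(W = g$dW, b = g$db); dcc <- g$dx

  dkeep <- dcc[, , seq_len(w), drop = FALSE]
  dp <- dcc[, , w + seq_len(w), drop = FALSE]
  for (j in rev(seq_len(model$config$depth))) {
    nm <- paste0("csp_path", j)
    g <- conv_bwd(dp, defs[[nm]], par[[nm]], cache[[nm]])
    grads[[nm]] <- list(W = g$dW, b = g$db); dp <- g$dx
  }
  da2 <- array(0, c(dim(dkeep)[1:2], 2L * w))
  da2[, , seq_len(w)] <- dkeep
  da2[, , w + seq_len(w)] <- dp

  g <- conv_bwd(da2, defs$b2, par$b2, cache$b2)
  grads$b2 <- list(W = g$dW, b = g$db); da1 <- g$dx
  g <- conv_bwd(da1, defs$b1, par$b1, cache$b1)
  grads$b1 <- list(W = g$dW, b = g$db); da0 <- g$dx
  g <- conv_bwd(da0, defs$b0, par$b0, cache$b0, need_dx = FALSE)
  grads$b0 <- list(W = g$dW, b = g$db)

  grads[names(defs)]
}
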
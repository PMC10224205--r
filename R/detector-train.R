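## Target assignment, composite loss with analytic gradients (including the
## fusion reliabilities), Adam training loop, and box decoding with NMS.

#' Assign ground-truth boxes to per-scale targets
#'
#' Each box is assigned, at every scale, to the best shape-IoU anchor of that
#' scale at the responsible grid cell (the cell containing the box centre).
#' Objectness target is 1 there and 0 elsewhere; the class target is one-hot
#' over benign/malignant; box targets are the standard within-cell centre
#' offsets and log size ratios relative to the assigned anchor.
#'
#' @param boxes data.frame with \code{class, x_min, y_min, width, height}
#'   (absolute pixels, class 0 = benign / 1 = malignant).
#' @param config A [detector_config()].
#' @return List with elements \code{l3}, \code{l4}, \code{l5}; each holds
#'   \code{obj} (N,N,3), \code{cls} (N,N,3,2), \code{box} (N,N,3,4: x,y,h,w)
#'   and \code{pos} (logical N,N,3).
#' @export
assign_targets <- function(boxes, config) {
  S <- config$input_size
  if (nrow(boxes) > 0) {
    bad <- boxes$x_min < 0 | boxes$y_min < 0 |
      boxes$x_min + boxes$width > S | boxes$y_min + boxes$height > S |
      boxes$width <= 0 | boxes$height <= 0
    if (any(bad)) stopf("box outside image bounds (input_size %d)", S)
  }
  out <- list()
  for (li in 1:3) {
    l <- li + 2L
    stride <- 2^l
    n <- S %/% stride
    anchors <- config$anchors[(li - 1L) * 3L + 1:3, , drop = FALSE]
    obj <- array(0, c(n, n, 3))
    cls <- array(0, c(n, n, 3, config$n_classes))
    boxt <- array(0, c(n, n, 3, 4))
    pos <- array(FALSE, c(n, n, 3))
    for (i in seq_len(nrow(boxes))) {
      cx <- boxes$x_min[i] + boxes$width[i] / 2
      cy <- boxes$y_min[i] + boxes$height[i] / 2
      col <- min(n - 1L, floor(cx / stride)) + 1L
      row <- min(n - 1L, floor(cy / stride)) + 1L
      ious <- vapply(1:3, function(a) {
        shape_iou(boxes$width[i], boxes$height[i], anchors[a, 1], anchors[a, 2])
      }, numeric(1))
      a <- which.max(ious)
      obj[row, col, a] <- 1
      cls[row, col, a, boxes$class[i] + 1L] <- 1
      boxt[row, col, a, 1] <- cx / stride - (col - 1L)
      boxt[row, col, a, 2] <- cy / stride - (row - 1L)
      boxt[row, col, a, 3] <- log(boxes$height[i] / anchors[a, 2])
      boxt[row, col, a, 4] <- log(boxes$width[i] / anchors[a, 1])
      pos[row, col, a] <- TRUE
    }
    out[[paste0("l", l)]] <- list(obj = obj, cls = cls, box = boxt, pos = pos)
  }
  out
}

# IoU of two box shapes anchored at a common centre.
shape_iou <- function(w1, h1, w2, h2) {
  inter <- min(w1, w2) * min(h1, h2)
  inter / (w1 * h1 + w2 * h2 - inter)
}

# Elementwise BCE from logits (stable): softplus(z) - z * t.
bce_from_logits <- function(z, t) (log1p(exp(-abs(z))) + pmax(z, 0)) - z * t

## Loss on a single 21-channel tensor against one level's targets. Returns
## the loss components and the gradient array w.r.t. the tensor's logits.
head_loss <- function(d, tgt, cfg, include_box = TRUE) {
  lw <- cfg$loss_weights
  grad <- array(0, dim(d))
  oc <- anchor_channels("obj")
  zo <- d[, , oc, drop = FALSE]
  so <- sigmoid(zo)
  pos <- tgt$pos
  npos <- sum(pos); nneg <- sum(!pos)
  bce <- bce_from_logits(zo, tgt$obj)
  l_obj <- 0
  dz <- array(0, dim(zo))
  if (npos > 0) {
    l_obj <- l_obj + sum(bce[pos]) / npos
    dz[pos] <- (so[pos] - 1) / npos
  }
  if (nneg > 0) {
    l_obj <- l_obj + cfg$noobj_weight * sum(bce[!pos]) / nneg
    dz[!pos] <- cfg$noobj_weight * so[!pos] / nneg
  }
  grad[, , oc] <- grad[, , oc, drop = FALSE] + lw[["obj"]] * dz
  l_obj <- lw[["obj"]] * l_obj

  l_cls <- 0; l_box <- 0
  if (npos > 0) {
    idx <- which(pos, arr.ind = TRUE)          # row, col, anchor
    nc <- cfg$n_classes
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]; a <- idx[r, 3]
      base <- (a - 1L) * 7L
      for (c in seq_len(nc)) {
        ch <- base + 5L + c
        z <- d[i, j, ch]; t <- tgt$cls[i, j, a, c]
        l_cls <- l_cls + bce_from_logits(z, t) / (npos * nc)
        grad[i, j, ch] <- grad[i, j, ch] + lw[["cls"]] * (sigmoid(z) - t) / (npos * nc)
      }
      if (include_box) {
        for (b in 1:4) {                        # x, y, h, w
          ch <- base + 1L + b
          z <- d[i, j, ch]; t <- tgt$box[i, j, a, b]
          if (b <= 2) {                         # sigmoid-coded centre offsets
            s <- sigmoid(z)
            l_box <- l_box + (s - t)^2 / (npos * 4)
            grad[i, j, ch] <- grad[i, j, ch] +
              lw[["box"]] * 2 * (s - t) * s * (1 - s) / (npos * 4)
          } else {                              # log size ratios
            l_box <- l_box + (z - t)^2 / (npos * 4)
            grad[i, j, ch] <- grad[i, j, ch] + lw[["box"]] * 2 * (z - t) / (npos * 4)
          }
        }
      }
    }
    l_cls <- lw[["cls"]] * l_cls
    l_box <- lw[["box"]] * l_box
  }
  list(loss = l_obj + l_cls + l_box, obj = l_obj, cls = l_cls, box = l_box,
       grad = grad)
}

## Full per-image loss with gradients for all parameters and lambda.
detector_loss_grads <- function(model, image, targets, compute_grads = TRUE) {
  cfg <- model$config
  fw <- forward_detector(model, image, keep_cache = compute_grads)
  d3 <- fw$d3; d4 <- fw$d4; d5 <- fw$d5

  if (cfg$variant == "amdf") {
    rel <- softmax_reliabilities(model$lambda)
    f4 <- dim(d3)[1] %/% dim(d4)[1]
    f5 <- dim(d3)[1] %/% dim(d5)[1]
    u4 <- upsample_nearest(d4, f4)
    u5 <- upsample_nearest(d5, f5)
    ys <- rel[["alpha"]] * d3 + rel[["beta"]] * u4 + rel[["gamma"]] * u5
    hl <- head_loss(ys, targets$l3, cfg, include_box = cfg$fuse_box)
    dys <- hl$grad
    l_box_extra <- 0
    dd3_extra <- NULL
    if (!cfg$fuse_box) {
      # box offsets trained on the finest head directly
      box_only <- cfg; box_only$loss_weights[c("obj", "cls")] <- 0
      hb <- head_loss(d3, targets$l3, box_only, include_box = TRUE)
      l_box_extra <- hb$box
      dd3_extra <- hb$grad
      hl$box <- hb$box
    }
    loss <- hl$loss + l_box_extra
    comp <- c(obj = hl$obj, box = hl$box, cls = hl$cls)
    if (!compute_grads) {
      return(list(loss = loss, components = comp, ys = ys))
    }
    dd3 <- rel[["alpha"]] * dys
    if (!is.null(dd3_extra)) dd3 <- dd3 + dd3_extra
    dd4 <- rel[["beta"]] * downsample_sum(dys, f4)
    dd5 <- rel[["gamma"]] * downsample_sum(dys, f5)
    # chain rule for the reliabilities, then the softmax Jacobian
    drel <- c(sum(dys * d3), sum(dys * u4), sum(dys * u5))
    dlambda <- rel * (drel - sum(rel * drel))
    grads <- backward_detector(model, fw$cache, dd3, dd4, dd5)
    list(loss = loss, components = comp, grads = grads,
         dlambda = as.numeric(dlambda), ys = ys)
  } else {
    h3 <- head_loss(d3, targets$l3, cfg)
    h4 <- head_loss(d4, targets$l4, cfg)
    h5 <- head_loss(d5, targets$l5, cfg)
    loss <- h3$loss + h4$loss + h5$loss
    comp <- c(obj = h3$obj + h4$obj + h5$obj,
              box = h3$box + h4$box + h5$box,
              cls = h3$cls + h4$cls + h5$cls)
    if (!compute_grads) return(list(loss = loss, components = comp))
    grads <- backward_detector(model, fw$cache, h3$grad, h4$grad, h5$grad)
    list(loss = loss, components = comp, grads = grads, dlambda = c(0, 0, 0))
  }
}

zero_like_params <- function(params) {
  lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
}

#' Train a detector
#'
#' Minimizes the composite objectness + box + class loss with Adam; for the
#' AMDF variant the objectness/class (and by default box) terms are applied
#' to the fused tensor and the three lambda parameters are updated exactly
#' like the convolution weights. Deterministic under \code{seed}.
#'
#' @param model A freshly built or warm-started \code{calc_detector}.
#' @param dataset List of samples, each \code{list(image, boxes)} with the
#'   image at \code{config$input_size}.
#' @param epochs,batch_size,lr Optimization settings.
#' @param seed Integer seed driving shuffling and augmentation.
#' @param augment Optional [augment_config()]; when supplied, exposure jitter
#'   is applied to training images each epoch.
#' @return List with \code{model} (trained) and \code{trace} (one row per
#'   optimization step: losses, lambda, reliabilities).
#' @export
train_detector <- function(model, dataset, epochs = 10L, batch_size = 8L,
                           lr = 1e-3, seed = 1L, augment = NULL) {
  if (length(dataset) == 0) stopf("empty dataset")
  cfg <- model$config
  targets <- lapply(dataset, function(s) assign_targets(s$boxes, cfg))

  m_p <- zero_like_params(model$params); v_p <- zero_like_params(model$params)
  m_l <- c(0, 0, 0); v_l <- c(0, 0, 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  trace <- list()

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(dataset))
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      for (bt in batches) {
        acc <- zero_like_params(model$params)
        acc_l <- c(0, 0, 0)
        tot <- 0; comp <- c(obj = 0, box = 0, cls = 0)
        for (i in bt) {
          img <- dataset[[i]]$image
          if (!is.null(augment)) img <- jitter_intensity(img, augment)
          r <- detector_loss_grads(model, img, targets[[i]])
          if (!is.finite(r$loss)) {
            stopf("NaN/Inf loss at epoch %d (sample %d): obj=%.4g box=%.4g cls=%.4g",
                  ep, i, r$components[["obj"]], r$components[["box"]],
                  r$components[["cls"]])
          }
          tot <- tot + r$loss; comp <- comp + r$components
          for (nm in names(acc)) {
            acc[[nm]]$W <- acc[[nm]]$W + r$grads[[nm]]$W
            acc[[nm]]$b <- acc[[nm]]$b + r$grads[[nm]]$b
          }
          acc_l <- acc_l + r$dlambda
        }
        nb <- length(bt)
        t_step <- t_step + 1L
        corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
        for (nm in names(acc)) {
          gW <- acc[[nm]]$W / nb; gb <- acc[[nm]]$b / nb
          m_p[[nm]]$W <- beta1 * m_p[[nm]]$W + (1 - beta1) * gW
          v_p[[nm]]$W <- beta2 * v_p[[nm]]$W + (1 - beta2) * gW^2
          m_p[[nm]]$b <- beta1 * m_p[[nm]]$b + (1 - beta1) * gb
          v_p[[nm]]$b <- beta2 * v_p[[nm]]$b + (1 - beta2) * gb^2
          model$params[[nm]]$W <- model$params[[nm]]$W -
            lr * (m_p[[nm]]$W / corr1) / (sqrt(v_p[[nm]]$W / corr2) + eps)
          model$params[[nm]]$b <- model$params[[nm]]$b -
            lr * (m_p[[nm]]$b / corr1) / (sqrt(v_p[[nm]]$b / corr2) + eps)
        }
        gl <- acc_l / nb
        m_l <- beta1 * m_l + (1 - beta1) * gl
        v_l <- beta2 * v_l + (1 - beta2) * gl^2
        model$lambda <- model$lambda - lr * (m_l / corr1) / (sqrt(v_l / corr2) + eps)
        rel <- softmax_reliabilities(model$lambda)
        trace[[t_step]] <- data.frame(
          step = t_step, epoch = ep, loss = tot / nb,
          obj = comp[["obj"]] / nb, box = comp[["box"]] / nb,
          cls = comp[["cls"]] / nb,
          lambda_alpha = model$lambda[1], lambda_beta = model$lambda[2],
          lambda_gamma = model$lambda[3],
          alpha = rel[["alpha"]], beta = rel[["beta"]], gamma = rel[["gamma"]]
        )
      }
    }
  })
  list(model = model, trace = do.call(rbind, trace))
}

#' Per-image malignancy confidence from a detector
#'
#' Runs a forward pass and reduces the AMDF fused tensor (or the baseline's
#' three heads) with [image_score()].
#'
#' @param model A \code{calc_detector}.
#' @param image Input matrix.
#' @return Named vector \code{c(benign, malignant)}.
#' @export
score_image <- function(model, image) {
  fw <- forward_detector(model, image)
  if (model$config$variant == "amdf") {
    ys <- amdf_fuse(fw$d3, fw$d4, fw$d5, fusion_weights(model$lambda))
    image_score(ys, reduction = model$config$score_reduction)
  } else {
    image_score(list(fw$d3, fw$d4, fw$d5),
                reduction = model$config$score_reduction)
  }
}

#' Intersection-over-union of corner-format boxes
#'
#' @param a,b Vectors \code{(x_min, y_min, width, height)}.
#' @return IoU in \code{[0, 1]}.
#' @export
box_iou <- function(a, b) {
  x0 <- max(a[1], b[1]); y0 <- max(a[2], b[2])
  x1 <- min(a[1] + a[3], b[1] + b[3]); y1 <- min(a[2] + a[4], b[2] + b[4])
  iw <- max(0, x1 - x0); ih <- max(0, y1 - y0)
  inter <- iw * ih
  union <- a[3] * a[4] + b[3] * b[4] - inter
  if (union <= 0) 0 else inter / union
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-scoring box and removes all remaining boxes
#' overlapping it with IoU above the threshold.
#'
#' @param boxes Matrix/data.frame with columns \code{x_min, y_min, width,
#'   height}.
#' @param scores Numeric scores, one per box.
#' @param iou_threshold Suppression threshold.
#' @return Integer indices of the kept boxes, in decreasing score order.
#' @export
greedy_nms <- function(boxes, scores, iou_threshold) {
  boxes <- as.matrix(boxes[, c("x_min", "y_min", "width", "height")])
  remaining <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(remaining) > 0) {
    i <- remaining[1]
    keep <- c(keep, i)
    remaining <- remaining[-1]
    if (length(remaining) > 0) {
      ious <- vapply(remaining, function(j) box_iou(boxes[i, ], boxes[j, ]),
                     numeric(1))
      remaining <- remaining[ious <= iou_threshold]
    }
  }
  keep
}

# Decode one 21-channel tensor into scored absolute boxes.
decode_tensor <- function(d, stride, anchors, S, conf_threshold, n_classes = 2L) {
  n <- dim(d)[1]
  rows <- list(); k <- 0L
  for (a in 1:3) {
    base <- (a - 1L) * 7L
    obj <- sigmoid(d[, , base + 1L])
    cls <- array(sigmoid(d[, , base + 5L + seq_len(n_classes)]), c(n, n, n_classes))
    for (j in seq_len(n)) for (i in seq_len(n)) {
      pc <- cls[i, j, ]
      conf <- obj[i, j] * max(pc)
      if (conf >= conf_threshold) {
        cx <- (j - 1L + sigmoid(d[i, j, base + 2L])) * stride
        cy <- (i - 1L + sigmoid(d[i, j, base + 3L])) * stride
        h <- anchors[a, 2] * exp(d[i, j, base + 4L])
        w <- anchors[a, 1] * exp(d[i, j, base + 5L])
        x0 <- max(0, cx - w / 2); y0 <- max(0, cy - h / 2)
        x1 <- min(S, cx + w / 2); y1 <- min(S, cy + h / 2)
        if (x1 > x0 && y1 > y0) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            class = which.max(pc) - 1L, score = conf,
            x_min = x0, y_min = y0, width = x1 - x0, height = y1 - y0
          )
        }
      }
    }
  }
  if (k == 0) return(cbind(data.frame(score = numeric(0)), empty_boxes())[, c("class", "score", "x_min", "y_min", "width", "height")])
  do.call(rbind, rows)
}

#' Detect lesions in an image
#'
#' Decodes box offsets to absolute boxes, filters by the confidence
#' threshold and applies greedy class-wise NMS. The AMDF variant decodes the
#' fused tensor on the level-3 grid with the level-3 anchors; the baseline
#' decodes all three scale heads.
#'
#' @param model A trained \code{calc_detector}.
#' @param image Input matrix.
#' @param conf_threshold,nms_iou Optional overrides of the config values.
#' @return data.frame \code{class, score, x_min, y_min, width, height}.
#' @export
detect <- function(model, image, conf_threshold = NULL, nms_iou = NULL) {
  cfg <- model$config
  conf_threshold <- conf_threshold %||% cfg$conf_threshold
  nms_iou <- nms_iou %||% cfg$nms_iou
  S <- nrow(image)
  fw <- forward_detector(model, image)
  if (cfg$variant == "amdf") {
    ys <- amdf_fuse(fw$d3, fw$d4, fw$d5, fusion_weights(model$lambda))
    dets <- decode_tensor(ys, 8L, cfg$anchors[1:3, , drop = FALSE], S,
                          conf_threshold, cfg$n_classes)
  } else {
    dets <- rbind(
      decode_tensor(fw$d3, 8L, cfg$anchors[1:3, , drop = FALSE], S,
                    conf_threshold, cfg$n_classes),
      decode_tensor(fw$d4, 16L, cfg$anchors[4:6, , drop = FALSE], S,
                    conf_threshold, cfg$n_classes),
      decode_tensor(fw$d5, 32L, cfg$anchors[7:9, , drop = FALSE], S,
                    conf_threshold, cfg$n_classes)
    )
  }
  if (nrow(dets) == 0) return(dets)
  out <- list()
  for (cl in unique(dets$class)) {
    sub <- dets[dets$class == cl, , drop = FALSE]
    keep <- greedy_nms(sub, sub$score, nms_iou)
    out[[as.character(cl)]] <- sub[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$score, decreasing = TRUE), , drop = FALSE]
}
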
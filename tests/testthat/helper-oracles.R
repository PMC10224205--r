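# Independent brute-force oracles shared across test files. These are kept
# deliberately naive and separate from the package's implementations.

# Shift a matrix by (dr, dc) with edge replication.
shift_replicate <- function(x, dr, dc) {
  H <- nrow(x); W <- ncol(x)
  ri <- pmin(pmax(seq_len(H) + dr, 1), H)
  ci <- pmin(pmax(seq_len(W) + dc, 1), W)
  x[ri, ci, drop = FALSE]
}

# 3x3 median by stacking the nine shifted copies and taking per-pixel medians.
oracle_median3 <- function(x) {
  stack <- sapply(expand.grid(dr = -1:1, dc = -1:1) |> asplit(1),
                  function(o) as.numeric(shift_replicate(x, o[["dr"]], o[["dc"]])))
  matrix(apply(stack, 1, median), nrow(x), ncol(x))
}

# Grayscale erosion/dilation over a disc by shift-and-min / shift-and-max.
oracle_morph <- function(x, radius, dilate) {
  out <- NULL
  for (dr in -radius:radius) for (dc in -radius:radius) {
    if (dr^2 + dc^2 > radius^2 + 1e-9) next
    s <- shift_replicate(x, dr, dc)
    out <- if (is.null(out)) s else if (dilate) pmax(out, s) else pmin(out, s)
  }
  out
}

oracle_tophat <- function(x, radius) {
  x - oracle_morph(oracle_morph(x, radius, dilate = FALSE), radius, dilate = TRUE)
}

# Mann-Whitney concordance probability over all (positive, negative) pairs.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Corner-format IoU, vectorized over a matrix of boxes vs one box.
oracle_iou <- function(b, boxes) {
  x0 <- pmax(b[1], boxes[, 1]); y0 <- pmax(b[2], boxes[, 2])
  x1 <- pmin(b[1] + b[3], boxes[, 1] + boxes[, 3])
  y1 <- pmin(b[2] + b[4], boxes[, 2] + boxes[, 4])
  inter <- pmax(0, x1 - x0) * pmax(0, y1 - y0)
  inter / (b[3] * b[4] + boxes[, 3] * boxes[, 4] - inter)
}

# Greedy NMS formulated as "keep a box iff it overlaps no already-kept,
# higher-scoring box above the threshold".
oracle_nms <- function(boxes, scores, thr) {
  boxes <- as.matrix(boxes[, c("x_min", "y_min", "width", "height")])
  ord <- order(scores, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (oracle_iou(boxes[j, ], boxes[i, , drop = FALSE]) > thr) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

empty_boxes_df <- function() {
  data.frame(class = integer(0), x_min = numeric(0), y_min = numeric(0),
             width = numeric(0), height = numeric(0))
}

# A task whose class/objectness pattern is resolvable only on the finest
# (stride-8) grid: two opposite-class spots in adjacent fine cells inside a
# single coarse cell, so upsampled coarse heads cannot express it.
make_fine_pair_dataset <- function(n, S = 64, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    img <- matrix(rnorm(S * S, 0.3, 0.03), S, S)
    cx <- sample(seq(16, S - 24, by = 16), 1) + 4
    cy <- sample(seq(16, S - 24, by = 16), 1) + 4
    stamp <- function(x, y, amp, r) {
      for (dx in -r:r) for (dy in -r:r) {
        if (dx^2 + dy^2 <= r^2) img[y + dy, x + dx] <<- img[y + dy, x + dx] + amp
      }
    }
    stamp(cx, cy, 0.35, 2)          # benign: small dim spot
    stamp(cx + 8, cy, 0.7, 3)       # malignant: brighter, next fine cell
    boxes <- data.frame(class = c(0L, 1L),
                        x_min = c(cx - 4, cx + 4), y_min = c(cy - 4, cy - 4),
                        width = 8, height = 8)
    list(image = pmin(pmax(img, 0), 1), boxes = boxes)
  })
}

# A small annotated phantom dataset for detector tests.
make_detector_dataset <- function(n_cases, image_size = 64, seed = 100) {
  roster <- generate_roster(roster_config(
    n_benign = ceiling(n_cases / 2), n_malignant = floor(n_cases / 2),
    single_view_cases = 0L, seed = seed
  ))
  cfg <- phantom_image_config(image_size = image_size)
  views <- render_roster(roster, cfg, seed = seed + 1)
  lapply(views, function(v) {
    lab <- roster$label[roster$case_id == v$case_id]
    b <- v$lesion_box
    list(image = v$pixels,
         boxes = data.frame(class = if (lab == "malignant") 1L else 0L,
                            x_min = b[["x_min"]], y_min = b[["y_min"]],
                            width = b[["width"]], height = b[["height"]]))
  })
}
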
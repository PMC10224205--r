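#' Augmentation configuration
#'
#' Training-time augmentation settings: intensity (exposure/saturation)
#' jitter, geometric width/height jitter, periodic input-size resampling and
#' optional 4-image mosaic composition. Augmentations are applied only by the
#' training loop, never at inference.
#'
#' @param saturation,exposure Jitter ranges; a factor is drawn uniformly in
#'   \code{[1/x, x]}. Saturation is recorded but is a no-op on grayscale
#'   input. Both must be >= 1.
#' @param resize_min,resize_max Bounds for the independent width/height
#'   resize factors.
#' @param size_coefficient Input-size resampling coefficient \code{c}: a new
#'   size is drawn uniformly in \code{[base/c, base*c]}.
#' @param size_period Resample the input size every this many iterations.
#' @param base_input_size Base network input size (pixels).
#' @param stride Pyramid stride; every emitted size is a multiple of it.
#' @param mosaic Whether mosaic composition is enabled.
#' @param mosaic_min_box_frac Minimum fraction of a (rescaled) box's area
#'   that must survive mosaic clipping for the box to be kept.
#' @return A list of class \code{augment_config}.
#' @export
augment_config <- function(saturation = 1.5, exposure = 1.5,
                           resize_min = 0.7, resize_max = 1.3,
                           size_coefficient = 1.4, size_period = 10L,
                           base_input_size = 128L, stride = 32L,
                           mosaic = FALSE, mosaic_min_box_frac = 0.25) {
  if (saturation < 1 || exposure < 1) {
    stopf("saturation and exposure jitter factors must be >= 1")
  }
  if (resize_min > resize_max) stopf("resize_min must be <= resize_max")
  if (size_coefficient < 1) stopf("size_coefficient must be >= 1")
  structure(list(
    saturation = saturation, exposure = exposure,
    resize_min = resize_min, resize_max = resize_max,
    size_coefficient = size_coefficient, size_period = as.integer(size_period),
    base_input_size = as.integer(base_input_size), stride = as.integer(stride),
    mosaic = mosaic, mosaic_min_box_frac = mosaic_min_box_frac
  ), class = "augment_config")
}

#' Intensity (exposure) jitter
#'
#' Multiplies intensities by a factor drawn uniformly in
#' \code{[1/exposure, exposure]}, with clipping to \code{[0, 1]}. The
#' configured saturation jitter is a no-op on single-channel images.
#'
#' @param image Grayscale matrix in \code{[0, 1]}.
#' @param config An [augment_config()].
#' @return Jittered image.
#' @export
jitter_intensity <- function(image, config = augment_config()) {
  check_image2d(image)
  f <- runif(1, 1 / config$exposure, config$exposure)
  pmin(pmax(image * f, 0), 1)
}

#' Geometric (resize) jitter
#'
#' Draws independent width and height scale factors uniformly in
#' \code{[resize_min, resize_max]}, resizes the image bilinearly and rescales
#' the boxes consistently.
#'
#' @param image Matrix (rows = y, cols = x).
#' @param boxes data.frame of absolute corner boxes.
#' @param config An [augment_config()].
#' @param factors Optional length-2 numeric \code{(width, height)} to force
#'   the factors (used by tests); \code{NULL} draws them.
#' @return List with \code{image}, \code{boxes}, \code{factors}.
#' @export
jitter_geometry <- function(image, boxes, config = augment_config(),
                            factors = NULL) {
  check_image2d(image)
  if (nrow(image) == 0 || ncol(image) == 0) stopf("empty image")
  if (is.null(factors)) {
    factors <- runif(2, config$resize_min, config$resize_max)
  }
  fw <- factors[1]; fh <- factors[2]
  new_w <- max(1L, round(ncol(image) * fw))
  new_h <- max(1L, round(nrow(image) * fh))
  out <- resize_image(image, new_h, new_w)
  sx <- new_w / ncol(image); sy <- new_h / nrow(image)
  b <- boxes
  if (nrow(b) > 0) {
    b$x_min <- b$x_min * sx; b$width <- b$width * sx
    b$y_min <- b$y_min * sy; b$height <- b$height * sy
    b$x_min <- pmin(pmax(b$x_min, 0), new_w)
    b$y_min <- pmin(pmax(b$y_min, 0), new_h)
    b$width <- pmin(b$width, new_w - b$x_min)
    b$height <- pmin(b$height, new_h - b$y_min)
  }
  list(image = out, boxes = b, factors = c(width = fw, height = fh))
}

# Bilinear resize of a matrix to new_h x new_w.
resize_image <- function(image, new_h, new_w) {
  as.matrix(EBImage::resize(EBImage::Image(image), w = new_h, h = new_w))
}

#' Periodic input-size resampling
#'
#' Every \code{size_period} iterations draws a new network input size
#' uniformly in \code{[base/c, base*c]} (\code{c = size_coefficient}),
#' rounded to the nearest stride multiple (at least one stride); on other
#' iterations the current size is returned unchanged.
#'
#' @param iteration Iteration counter (>= 0).
#' @param config An [augment_config()].
#' @param current_size Size currently in use (\code{NULL} at iteration 0).
#' @return Input size in pixels.
#' @export
resample_input_size <- function(iteration, config = augment_config(),
                                current_size = NULL) {
  if (iteration %% config$size_period != 0 && !is.null(current_size)) {
    return(current_size)
  }
  lo <- config$base_input_size / config$size_coefficient
  hi <- config$base_input_size * config$size_coefficient
  s <- runif(1, lo, hi)
  max(config$stride, round(s / config$stride) * config$stride)
}

#' Mosaic composition of four annotated samples
#'
#' A random split point partitions the output canvas into four quadrants;
#' each input image is resized into its quadrant and its boxes are remapped.
#' Boxes whose clipped area falls below \code{mosaic_min_box_frac} of their
#' rescaled area are dropped.
#'
#' @param samples List of exactly four \code{list(image, boxes)} samples.
#' @param config An [augment_config()]; the canvas is
#'   \code{base_input_size} square.
#' @param split Optional forced split point \code{c(x, y)} in pixels (tests).
#' @return List with \code{image}, \code{boxes}, \code{split}.
#' @export
mosaic4 <- function(samples, config = augment_config(), split = NULL) {
  if (length(samples) != 4) stopf("mosaic requires exactly four samples")
  S <- config$base_input_size
  if (is.null(split)) {
    split <- round(runif(2, 0.3 * S, 0.7 * S))
  }
  sx <- as.integer(split[1]); sy <- as.integer(split[2])
  canvas <- matrix(0, S, S)
  quads <- list(                                   # x0, y0, w, h per quadrant
    c(0, 0, sx, sy), c(sx, 0, S - sx, sy),
    c(0, sy, sx, S - sy), c(sx, sy, S - sx, S - sy)
  )
  out_boxes <- list()
  for (q in 1:4) {
    g <- quads[[q]]
    img <- samples[[q]]$image
    b <- samples[[q]]$boxes
    qw <- g[3]; qh <- g[4]
    canvas[(g[2] + 1):(g[2] + qh), (g[1] + 1):(g[1] + qw)] <-
      resize_image(img, qh, qw)
    if (!is.null(b) && nrow(b) > 0) {
      fx <- qw / ncol(img); fy <- qh / nrow(img)
      x0 <- b$x_min * fx + g[1]; y0 <- b$y_min * fy + g[2]
      w <- b$width * fx; h <- b$height * fy
      cx0 <- pmin(pmax(x0, g[1]), g[1] + qw)
      cy0 <- pmin(pmax(y0, g[2]), g[2] + qh)
      cx1 <- pmin(pmax(x0 + w, g[1]), g[1] + qw)
      cy1 <- pmin(pmax(y0 + h, g[2]), g[2] + qh)
      cw <- pmax(cx1 - cx0, 0); ch <- pmax(cy1 - cy0, 0)
      keep <- (cw * ch) >= config$mosaic_min_box_frac * (w * h) & cw > 0 & ch > 0
      if (any(keep)) {
        out_boxes[[q]] <- data.frame(
          class = b$class[keep], x_min = cx0[keep], y_min = cy0[keep],
          width = cw[keep], height = ch[keep]
        )
      }
    }
  }
  boxes <- if (length(out_boxes)) {
    do.call(rbind, out_boxes[!vapply(out_boxes, is.null, TRUE)])
  } else {
    empty_boxes()
  }
  if (is.null(boxes)) boxes <- empty_boxes()
  rownames(boxes) <- NULL
  list(image = canvas, boxes = boxes, split = c(x = sx, y = sy))
}
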
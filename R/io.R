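#' Read a grayscale image
#'
#' Reads PNG or TIFF into a numeric matrix in \code{[0, 1]}. 8-bit files are
#' promoted by the usual \code{k/255} scaling, 16-bit by \code{k/65535}, so
#' intensities are preserved on a common scale. Multi-channel input is
#' averaged to one channel.
#'
#' @param path File path (\code{.png}, \code{.tif}, \code{.tiff}).
#' @return Numeric matrix (rows = y, cols = x).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stopf("unsupported image format: .%s (PNG/TIFF supported)", ext)
    ),
    error = function(e) stopf("failed to read %s: %s", path, conditionMessage(e))
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a grayscale image
#'
#' Writes 16-bit TIFF (uncompressed) or 8-bit PNG. Intensities are clipped to
#' \code{[0, 1]} and quantized to the target bit depth, so a 16-bit TIFF
#' round-trips losslessly for data already on the 16-bit grid.
#'
#' @param image Numeric matrix.
#' @param path Output path; format chosen by extension.
#' @export
write_image <- function(image, path) {
  if (!is.matrix(image)) stopf("image must be a 2-D matrix")
  x <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(round(x * 255) / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(round(x * 65535) / 65535, path,
                    bits.per.sample = 16L, compression = "none")
  } else {
    stopf("unsupported image format: .%s (PNG/TIFF supported)", ext)
  }
  invisible(path)
}

empty_boxes <- function() {
  data.frame(class = integer(0), x_min = numeric(0), y_min = numeric(0),
             width = numeric(0), height = numeric(0))
}

#' Convert between absolute corner boxes and normalized center format
#'
#' Boxes use 0-based, origin-top-left, half-open \code{[x, x + w)} pixel
#' coordinates. The YOLO text dialect stores \code{class cx cy w h} normalized
#' to \code{[0, 1]} in center format.
#'
#' @param boxes data.frame with \code{class, x_min, y_min, width, height}.
#' @param image_size Image side length in pixels (square images).
#' @return data.frame with \code{class, cx, cy, w, h} (normalized).
#' @export
boxes_to_yolo <- function(boxes, image_size) {
  data.frame(
    class = boxes$class,
    cx = (boxes$x_min + boxes$width / 2) / image_size,
    cy = (boxes$y_min + boxes$height / 2) / image_size,
    w = boxes$width / image_size,
    h = boxes$height / image_size
  )
}

#' @rdname boxes_to_yolo
#' @param yolo data.frame with normalized \code{class, cx, cy, w, h}.
#' @export
yolo_to_boxes <- function(yolo, image_size) {
  data.frame(
    class = yolo$class,
    x_min = (yolo$cx - yolo$w / 2) * image_size,
    y_min = (yolo$cy - yolo$h / 2) * image_size,
    width = yolo$w * image_size,
    height = yolo$h * image_size
  )
}

#' Write box annotations
#'
#' \code{"yolo"} writes one \code{class cx cy w h} normalized row per box;
#' \code{"csv"} writes absolute corner-format pixel boxes.
#'
#' @param boxes data.frame with \code{class, x_min, y_min, width, height}
#'   (absolute pixels).
#' @param path Output file.
#' @param image_size Image side (needed for the YOLO dialect).
#' @param format \code{"yolo"} or \code{"csv"}.
#' @export
write_annotations <- function(boxes, path, image_size, format = c("yolo", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(boxes, path, row.names = FALSE)
  } else {
    y <- boxes_to_yolo(boxes, image_size)
    lines <- sprintf("%d %.10f %.10f %.10f %.10f", y$class, y$cx, y$cy, y$w, y$h)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read box annotations
#'
#' Reads the YOLO text dialect (converted back to absolute corner boxes) or
#' the absolute CSV dialect. Malformed rows are reported with their line
#' numbers.
#'
#' @param path Annotation file.
#' @param image_size Image side (YOLO dialect only).
#' @param format \code{"yolo"} or \code{"csv"}; default inferred from the
#'   file extension.
#' @return data.frame with \code{class, x_min, y_min, width, height}.
#' @export
read_annotations <- function(path, image_size = NULL,
                             format = c("auto", "yolo", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "yolo"
  }
  if (format == "csv") {
    out <- read.csv(path)
    need <- c("class", "x_min", "y_min", "width", "height")
    if (!all(need %in% names(out))) {
      stopf("malformed CSV annotations in %s: need columns %s",
            path, paste(need, collapse = ", "))
    }
    return(out[, need])
  }
  if (is.null(image_size)) stopf("image_size is required for YOLO annotations")
  lines <- readLines(path)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0) return(empty_boxes())
  parts <- lapply(lines_keep, function(i) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(f) != 5 || anyNA(v)) {
      stopf("malformed annotation row at line %d of %s", i, path)
    }
    v
  })
  m <- do.call(rbind, parts)
  yolo_to_boxes(
    data.frame(class = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
               w = m[, 4], h = m[, 5]),
    image_size
  )
}
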
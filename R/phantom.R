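#' Phantom roster configuration
#'
#' Configuration for the synthetic case-roster generator. Defaults emulate the
#' composition of a diagnostic spot-magnification cohort in which every case
#' was judged suspicious (BI-RADS 4) and biopsied: 432 benign and 204
#' malignant cases, ages 29-81 (mean 54.4, sd 8.42), three cases with a
#' single view, and malignant histology dominated by DCIS and IDC.
#'
#' Descriptor linkage tables are class-conditional sampling probabilities:
#' benign cases skew towards punctate/round morphology with grouped
#' distribution, malignant cases towards pleomorphic/amorphous/fine-linear
#' morphology with grouped/segmental distribution, so the descriptors carry
#' class signal downstream.
#'
#' @param n_benign,n_malignant Number of benign / malignant cases.
#' @param age_mean,age_sd,age_min,age_max Age distribution (normal, truncated
#'   to \code{[age_min, age_max]} by rejection).
#' @param birads_probs_benign,birads_probs_malignant Probabilities over
#'   BI-RADS 4A/4B/4C per class.
#' @param histology_probs Probabilities over IDC/ILC/DCIS for malignant cases.
#' @param histology_mode \code{"sample"} draws histology from a multinomial;
#'   \code{"quota"} assigns exact largest-remainder counts.
#' @param morphology_probs_benign,morphology_probs_malignant Probabilities
#'   over the six morphology terms per class.
#' @param distribution_probs_benign,distribution_probs_malignant
#'   Probabilities over the five distribution terms per class.
#' @param p_second_morphology Probability that a case carries a second
#'   morphologic pattern.
#' @param single_view_cases Number of cases with only one view.
#' @param p_ml_view Probability the lateral view is ML rather than MLO.
#' @param seed Integer seed; all roster randomness flows from it.
#' @return A list of class \code{roster_config}.
#' @export
roster_config <- function(n_benign = 432L,
                          n_malignant = 204L,
                          age_mean = 54.4, age_sd = 8.42,
                          age_min = 29L, age_max = 81L,
                          birads_probs_benign = c(`4A` = 0.80, `4B` = 0.18, `4C` = 0.02),
                          birads_probs_malignant = c(`4A` = 0.435, `4B` = 0.49, `4C` = 0.075),
                          histology_probs = c(IDC = 61 / 204, ILC = 3 / 204, DCIS = 140 / 204),
                          histology_mode = c("sample", "quota"),
                          morphology_probs_benign = c(
                            punctate = 0.45, round = 0.30, amorphous = 0.10,
                            `coarse-heterogeneous` = 0.10, pleomorphic = 0.04,
                            `fine-linear-branching` = 0.01
                          ),
                          morphology_probs_malignant = c(
                            punctate = 0.05, round = 0.04, amorphous = 0.25,
                            `coarse-heterogeneous` = 0.06, pleomorphic = 0.40,
                            `fine-linear-branching` = 0.20
                          ),
                          distribution_probs_benign = c(
                            diffuse = 0.18, regional = 0.20, grouped = 0.52,
                            linear = 0.07, segmental = 0.03
                          ),
                          distribution_probs_malignant = c(
                            diffuse = 0.03, regional = 0.10, grouped = 0.45,
                            linear = 0.15, segmental = 0.27
                          ),
                          p_second_morphology = 0.3,
                          single_view_cases = 3L,
                          p_ml_view = 0.2,
                          seed = 20260101L) {
  histology_mode <- match.arg(histology_mode)
  cfg <- list(
    n_benign = as.integer(n_benign), n_malignant = as.integer(n_malignant),
    age_mean = age_mean, age_sd = age_sd,
    age_min = as.integer(age_min), age_max = as.integer(age_max),
    birads_probs_benign = birads_probs_benign,
    birads_probs_malignant = birads_probs_malignant,
    histology_probs = histology_probs, histology_mode = histology_mode,
    morphology_probs_benign = morphology_probs_benign,
    morphology_probs_malignant = morphology_probs_malignant,
    distribution_probs_benign = distribution_probs_benign,
    distribution_probs_malignant = distribution_probs_malignant,
    p_second_morphology = p_second_morphology,
    single_view_cases = as.integer(single_view_cases),
    p_ml_view = p_ml_view,
    seed = as.integer(seed)
  )
  validate_roster_config(cfg)
  structure(cfg, class = "roster_config")
}

validate_roster_config <- function(cfg) {
  if (cfg$n_benign < 0 || cfg$n_malignant < 0) {
    stopf("configuration error: case counts must be >= 0")
  }
  check_probs(cfg$birads_probs_benign, "benign BI-RADS")
  check_probs(cfg$birads_probs_malignant, "malignant BI-RADS")
  check_probs(cfg$histology_probs, "histology")
  check_probs(cfg$morphology_probs_benign, "benign morphology")
  check_probs(cfg$morphology_probs_malignant, "malignant morphology")
  check_probs(cfg$distribution_probs_benign, "benign distribution")
  check_probs(cfg$distribution_probs_malignant, "malignant distribution")
  stopifnot(
    identical(names(cfg$morphology_probs_benign), MORPHOLOGY_LEVELS),
    identical(names(cfg$morphology_probs_malignant), MORPHOLOGY_LEVELS),
    identical(names(cfg$distribution_probs_benign), DISTRIBUTION_LEVELS),
    identical(names(cfg$distribution_probs_malignant), DISTRIBUTION_LEVELS)
  )
  invisible(cfg)
}

# Truncated-normal ages by rejection.
sample_ages <- function(n, cfg) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rnorm(n, cfg$age_mean, cfg$age_sd))
    x <- x[x >= cfg$age_min & x <= cfg$age_max]
    out <- c(out, as.integer(x))
  }
  out[seq_len(n)]
}

# Largest-remainder apportionment of n among probabilities p.
quota_counts <- function(n, p) {
  raw <- p * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Generate a synthetic case roster
#'
#' Produces exactly \code{n_benign + n_malignant} patient-level cases with
#' class-conditional BI-RADS subcategory, histology (malignant only),
#' morphology/distribution descriptors, age, and 1-2 views per case.
#' Deterministic under the configured seed.
#'
#' @param config A [roster_config()].
#' @return A data.frame of class \code{calc_roster}, one row per case, with a
#'   list-column \code{morphology} and character column \code{views}
#'   (comma-separated view labels). The generating seed is attached as
#'   attribute \code{"seed"}.
#' @export
generate_roster <- function(config = roster_config()) {
  validate_roster_config(config)
  n <- config$n_benign + config$n_malignant
  empty <- data.frame(
    case_id = character(0), label = character(0), age_years = integer(0),
    birads = character(0), histology = character(0),
    distribution = character(0), views = character(0),
    stringsAsFactors = FALSE
  )
  empty$morphology <- list()
  if (n == 0L) {
    return(structure(empty, class = c("calc_roster", "data.frame"),
                     seed = config$seed))
  }
  with_seed(config$seed, {
    label <- c(rep("benign", config$n_benign), rep("malignant", config$n_malignant))
    case_id <- sprintf("case_%04d", seq_len(n))
    age <- sample_ages(n, config)

    birads <- character(n)
    is_mal <- label == "malignant"
    if (any(!is_mal)) {
      birads[!is_mal] <- sample(names(config$birads_probs_benign), sum(!is_mal),
                                replace = TRUE, prob = config$birads_probs_benign)
    }
    if (any(is_mal)) {
      birads[is_mal] <- sample(names(config$birads_probs_malignant), sum(is_mal),
                               replace = TRUE, prob = config$birads_probs_malignant)
    }

    histology <- rep("none", n)
    if (any(is_mal)) {
      if (config$histology_mode == "quota") {
        cnt <- quota_counts(sum(is_mal), config$histology_probs)
        pool <- sample(rep(names(config$histology_probs), cnt))
      } else {
        pool <- sample(names(config$histology_probs), sum(is_mal),
                       replace = TRUE, prob = config$histology_probs)
      }
      histology[is_mal] <- pool
    }

    morphology <- vector("list", n)
    distribution <- character(n)
    for (i in seq_len(n)) {
      mp <- if (is_mal[i]) config$morphology_probs_malignant else config$morphology_probs_benign
      dp <- if (is_mal[i]) config$distribution_probs_malignant else config$distribution_probs_benign
      m <- sample(MORPHOLOGY_LEVELS, 1L, prob = mp)
      if (runif(1) < config$p_second_morphology) {
        m2 <- sample(MORPHOLOGY_LEVELS, 1L, prob = mp)
        m <- unique(c(m, m2))
      }
      morphology[[i]] <- m
      distribution[i] <- sample(DISTRIBUTION_LEVELS, 1L, prob = dp)
    }

    n_single <- min(config$single_view_cases, n)
    single_idx <- if (n_single > 0) sample(n, n_single) else integer(0)
    views <- character(n)
    for (i in seq_len(n)) {
      if (i %in% single_idx) {
        views[i] <- "CC"
      } else {
        lateral <- if (runif(1) < config$p_ml_view) "ML" else "MLO"
        views[i] <- paste("CC", lateral, sep = ",")
      }
    }

    roster <- data.frame(
      case_id = case_id, label = label, age_years = age, birads = birads,
      histology = histology, distribution = distribution, views = views,
      stringsAsFactors = FALSE
    )
    roster$morphology <- morphology
    structure(roster, class = c("calc_roster", "data.frame"), seed = config$seed)
  })
}

#' Split a roster's view field into view labels
#' @param views Comma-separated view strings as stored in the roster.
#' @return List of character vectors.
#' @export
roster_views <- function(views) strsplit(views, ",", fixed = TRUE)

#' Number of images implied by a roster
#' @param roster A \code{calc_roster}.
#' @return Integer: total views across all cases.
#' @export
roster_image_count <- function(roster) {
  sum(lengths(roster_views(roster$views)))
}

#' Phantom image configuration
#'
#' Rendering parameters for synthetic magnification views. Intensities are
#' doubles in \code{[0, 1]} (stored as 16-bit on disk). The particle
#' intensity ranges are chosen so stamped calcifications are clearly brighter
#' than the textured background at default settings.
#'
#' @param image_size Square image side in pixels (>= 64).
#' @param background_level Mean background tissue intensity.
#' @param texture_amplitude Amplitude of the smooth low-frequency texture.
#' @param noise_sd Per-pixel Gaussian noise standard deviation.
#' @param particle_rate_scale Multiplier on morphology-specific mean particle
#'   counts; 0 renders a lesion-free image.
#' @param box_margin Padding (px) added around the tight particle box.
#' @return A list of class \code{phantom_image_config}.
#' @export
phantom_image_config <- function(image_size = 128L,
                                 background_level = 0.25,
                                 texture_amplitude = 0.06,
                                 noise_sd = 0.015,
                                 particle_rate_scale = 1,
                                 box_margin = 3L) {
  if (image_size < 64) stopf("image_size must be >= 64")
  structure(list(
    image_size = as.integer(image_size),
    background_level = background_level,
    texture_amplitude = texture_amplitude,
    noise_sd = noise_sd,
    particle_rate_scale = particle_rate_scale,
    box_margin = as.integer(box_margin)
  ), class = "phantom_image_config")
}

# Mean particle counts per morphology (before particle_rate_scale).
PARTICLE_RATES <- c(
  punctate = 12, round = 9, amorphous = 8, `coarse-heterogeneous` = 6,
  pleomorphic = 15, `fine-linear-branching` = 9
)

# Smooth low-frequency background texture: bilinear upsample of coarse noise.
render_background <- function(cfg) {
  S <- cfg$image_size
  coarse <- matrix(rnorm(64), 8, 8)
  tex <- as.matrix(EBImage::resize(EBImage::Image(coarse), w = S, h = S))
  img <- cfg$background_level + cfg$texture_amplitude * tex +
    matrix(rnorm(S * S, 0, cfg$noise_sd), S, S)
  pmax(img, 0)
}

# Sample particle centres (x, y in 0-based pixel coords) for a cluster whose
# footprint follows the distribution descriptor.
sample_cluster_positions <- function(n, distribution, S) {
  cx <- runif(1, 0.30 * S, 0.70 * S)
  cy <- runif(1, 0.30 * S, 0.70 * S)
  theta <- runif(1, 0, 2 * pi)
  if (distribution %in% c("grouped", "regional", "diffuse")) {
    r_max <- switch(distribution, grouped = 0.09, regional = 0.20, diffuse = 0.33) * S
    r <- r_max * sqrt(runif(n))
    a <- runif(n, 0, 2 * pi)
    x <- cx + r * cos(a); y <- cy + r * sin(a)
  } else if (distribution == "linear") {
    len <- 0.35 * S
    t <- runif(n, -0.5, 0.5) * len
    perp <- rnorm(n, 0, 0.015 * S)
    x <- cx + t * cos(theta) - perp * sin(theta)
    y <- cy + t * sin(theta) + perp * cos(theta)
  } else if (distribution == "segmental") {
    d <- 0.36 * S * sqrt(runif(n))
    a <- theta + runif(n, -1, 1) * (12 * pi / 180)
    x <- cx + d * cos(a); y <- cy + d * sin(a)
  } else {
    stopf("unknown distribution descriptor: %s", distribution)
  }
  cbind(x = pmin(pmax(x, 3), S - 4), y = pmin(pmax(y, 3), S - 4))
}

# Stamp one particle of the given morphology onto img; returns the updated
# image. Additive intensity, local window only.
stamp_particle <- function(img, morphology, px, py) {
  S <- nrow(img)
  win <- function(r) {
    r0 <- max(1L, floor(py) - r + 1L); r1 <- min(S, floor(py) + r + 1L)
    c0 <- max(1L, floor(px) - r + 1L); c1 <- min(S, floor(px) + r + 1L)
    list(rows = r0:r1, cols = c0:c1)
  }
  add_field <- function(r, field_fn) {
    w <- win(r)
    yy <- w$rows - 1; xx <- w$cols - 1
    dy <- outer(yy - py, rep(1, length(xx)))
    dx <- outer(rep(1, length(yy)), xx - px)
    img[w$rows, w$cols] <<- img[w$rows, w$cols] + field_fn(dx, dy)
    invisible(NULL)
  }
  if (morphology == "punctate") {
    amp <- runif(1, 0.50, 0.80); sg <- 0.7
    add_field(3L, function(dx, dy) amp * exp(-(dx^2 + dy^2) / (2 * sg^2)))
  } else if (morphology == "round") {
    amp <- runif(1, 0.45, 0.70); r <- runif(1, 1.5, 2.5)
    add_field(ceiling(r) + 1L, function(dx, dy) {
      d <- sqrt(dx^2 + dy^2); amp * pmin(1, pmax(0, r + 0.5 - d))
    })
  } else if (morphology == "amorphous") {
    amp <- runif(1, 0.18, 0.32); sg <- runif(1, 1.5, 3)
    add_field(ceiling(3 * sg), function(dx, dy) amp * exp(-(dx^2 + dy^2) / (2 * sg^2)))
  } else if (morphology == "coarse-heterogeneous") {
    amp <- runif(1, 0.45, 0.75); r <- runif(1, 2.5, 4)
    add_field(ceiling(r) + 1L, function(dx, dy) {
      d <- sqrt(dx^2 + dy^2)
      speck <- matrix(runif(length(d), 0.55, 1), nrow(d), ncol(d))
      amp * speck * pmin(1, pmax(0, r + 0.5 - d))
    })
  } else if (morphology == "pleomorphic") {
    amp <- runif(1, 0.50, 0.90)
    radii <- runif(8, 1.0, 3.5)
    add_field(5L, function(dx, dy) {
      d <- sqrt(dx^2 + dy^2)
      ang <- atan2(dy, dx) + pi              # [0, 2*pi)
      k <- pmin(8L, floor(ang / (2 * pi / 8)) + 1L)
      rboundary <- matrix(radii[k], nrow(d), ncol(d))
      amp * pmin(1, pmax(0, rboundary + 0.5 - d))
    })
  } else if (morphology == "fine-linear-branching") {
    amp <- runif(1, 0.50, 0.80)
    nstep <- sample(4:9, 1)
    ang <- runif(1, 0, 2 * pi)
    x <- px; y <- py
    pts <- matrix(c(x, y), 1, 2)
    for (s in seq_len(nstep)) {
      ang <- ang + rnorm(1, 0, 0.35)
      x <- x + cos(ang); y <- y + sin(ang)
      pts <- rbind(pts, c(x, y))
    }
    if (runif(1) < 0.5) {                    # one short branch
      mid <- pts[ceiling(nrow(pts) / 2), ]
      bang <- ang + runif(1, pi / 4, 3 * pi / 4)
      bx <- mid[1]; by <- mid[2]
      for (s in seq_len(3)) {
        bx <- bx + cos(bang); by <- by + sin(bang)
        pts <- rbind(pts, c(bx, by))
      }
    }
    for (i in seq_len(nrow(pts))) {
      qx <- pts[i, 1]; qy <- pts[i, 2]
      if (qx < 1 || qx > S - 2 || qy < 1 || qy > S - 2) next
      px_local <- qx; py_local <- qy
      r0 <- max(1L, floor(py_local)); r1 <- min(S, floor(py_local) + 2L)
      c0 <- max(1L, floor(px_local)); c1 <- min(S, floor(px_local) + 2L)
      yy <- (r0:r1) - 1; xx <- (c0:c1) - 1
      dy <- outer(yy - py_local, rep(1, length(xx)))
      dx <- outer(rep(1, length(yy)), xx - px_local)
      d <- sqrt(dx^2 + dy^2)
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amp * pmin(1, pmax(0, 1.2 - d))
    }
  } else {
    stopf("unknown morphology descriptor: %s", morphology)
  }
  img
}

#' Render one synthetic magnification view
#'
#' Draws a textured tissue background and stamps a cluster of calcification
#' particles whose spatial footprint follows the case's distribution
#' descriptor and whose shapes follow its morphology set. The ground-truth
#' lesion box is the tight bounding box of the stamped particles padded by
#' \code{box_margin}, using 0-based, origin-top-left, half-open
#' \code{[x, x + w)} pixel coordinates.
#'
#' @param case One-row slice of a \code{calc_roster} (or an equivalent list
#'   with \code{case_id}, \code{label}, \code{morphology}, \code{distribution}).
#' @param view View label (\code{"CC"}, \code{"MLO"} or \code{"ML"}).
#' @param config A [phantom_image_config()].
#' @param seed Integer seed; the render is bit-reproducible under it.
#' @return A list of class \code{calc_view}: \code{case_id}, \code{view},
#'   \code{pixels} (matrix in \code{[0,1]}), \code{lesion_box} (named vector
#'   \code{x_min, y_min, width, height} or \code{NULL}), \code{particle_count}.
#' @export
render_view <- function(case, view, config = phantom_image_config(), seed = NULL) {
  if (!view %in% VIEW_LEVELS) stopf("unknown view label: %s", view)
  morph <- if (is.list(case$morphology) && !is.character(case$morphology)) {
    case$morphology[[1]]
  } else {
    case$morphology
  }
  if (length(morph) == 0) stopf("morphology set must be non-empty")
  if (!all(morph %in% MORPHOLOGY_LEVELS)) {
    stopf("unknown morphology descriptor: %s", setdiff(morph, MORPHOLOGY_LEVELS)[1])
  }
  if (!case$distribution %in% DISTRIBUTION_LEVELS) {
    stopf("unknown distribution descriptor: %s", case$distribution)
  }
  with_seed(seed, {
    S <- config$image_size
    img <- render_background(config)
    base <- img

    counts <- vapply(morph, function(m) {
      rpois(1, PARTICLE_RATES[[m]] * config$particle_rate_scale)
    }, numeric(1))
    if (config$particle_rate_scale > 0) {
      # a rendered cluster always has at least a few particles
      while (sum(counts) < 3) counts[1] <- counts[1] + 1
    }
    total <- as.integer(sum(counts))

    box <- NULL
    if (total > 0) {
      pos <- sample_cluster_positions(total, case$distribution, S)
      kinds <- rep(morph, times = counts)
      for (i in seq_len(total)) {
        img <- stamp_particle(img, kinds[i], pos[i, 1], pos[i, 2])
      }
      added <- img - base
      hit <- which(added > 0.05, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        m <- config$box_margin
        y0 <- max(0L, min(hit[, 1]) - 1L - m)
        y1 <- min(S, max(hit[, 1]) + m)        # exclusive
        x0 <- max(0L, min(hit[, 2]) - 1L - m)
        x1 <- min(S, max(hit[, 2]) + m)
        box <- c(x_min = x0, y_min = y0, width = x1 - x0, height = y1 - y0)
      }
    }
    structure(list(
      case_id = case$case_id, view = view,
      pixels = pmin(pmax(img, 0), 1),
      lesion_box = box, particle_count = total
    ), class = "calc_view")
  })
}

#' Render all views of a roster
#'
#' Convenience wrapper calling [render_view()] for every (case, view) pair
#' with per-image seeds derived from \code{seed}.
#'
#' @param roster A \code{calc_roster}.
#' @param config A [phantom_image_config()].
#' @param seed Master seed (default: the roster's own seed).
#' @return A list of \code{calc_view} objects.
#' @export
render_roster <- function(roster, config = phantom_image_config(),
                          seed = attr(roster, "seed") %||% 1L) {
  views <- roster_views(roster$views)
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(roster))) {
    for (v in views[[i]]) {
      k <- k + 1L
      out[[k]] <- render_view(roster[i, ], v, config, seed = derive_seed(seed, k))
    }
  }
  out
}

#' Write a phantom dataset to disk
#'
#' Writes one image file per view (16-bit TIFF or 8-bit PNG), one YOLO-style
#' annotation text file per image, a combined absolute-pixel CSV, the roster
#' CSV and a JSON manifest with per-file checksums.
#'
#' @param roster A \code{calc_roster}.
#' @param output_dir Writable directory (created if missing).
#' @param format \code{"tiff"} (16-bit) or \code{"png"} (8-bit).
#' @param config A [phantom_image_config()].
#' @param seed Master seed for rendering (default: roster seed).
#' @return The manifest as a data.frame (invisibly); also written as
#'   \code{manifest.json}.
#' @export
emit_dataset <- function(roster, output_dir, format = c("tiff", "png"),
                         config = phantom_image_config(),
                         seed = attr(roster, "seed") %||% 1L) {
  format <- match.arg(format)
  if (anyDuplicated(roster$case_id)) stopf("duplicate case_id in roster")
  dir.create(file.path(output_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(output_dir, "labels"), showWarnings = FALSE)
  ext <- if (format == "tiff") "tif" else "png"

  views <- roster_views(roster$views)
  rows <- list(); ann_rows <- list()
  k <- 0L
  for (i in seq_len(nrow(roster))) {
    for (v in views[[i]]) {
      k <- k + 1L
      vw <- render_view(roster[i, ], v, config, seed = derive_seed(seed, k))
      stem <- sprintf("%s_%s", vw$case_id, vw$view)
      img_path <- file.path(output_dir, "images", paste0(stem, ".", ext))
      ann_path <- file.path(output_dir, "labels", paste0(stem, ".txt"))
      write_image(vw$pixels, img_path)
      cls <- if (roster$label[i] == "malignant") 1L else 0L
      boxes <- if (is.null(vw$lesion_box)) {
        empty_boxes()
      } else {
        data.frame(class = cls, x_min = vw$lesion_box[["x_min"]],
                   y_min = vw$lesion_box[["y_min"]],
                   width = vw$lesion_box[["width"]],
                   height = vw$lesion_box[["height"]])
      }
      write_annotations(boxes, ann_path, image_size = config$image_size, format = "yolo")
      rows[[k]] <- data.frame(
        case_id = vw$case_id, view = vw$view, label = roster$label[i],
        image = file.path("images", basename(img_path)),
        annotation = file.path("labels", basename(ann_path)),
        md5 = unname(tools::md5sum(img_path)),
        stringsAsFactors = FALSE
      )
      if (nrow(boxes) > 0) {
        ann_rows[[k]] <- cbind(data.frame(image = rows[[k]]$image), boxes)
      }
    }
  }
  manifest <- do.call(rbind, rows)

  roster_out <- roster
  roster_out$morphology <- vapply(roster$morphology, paste, "", collapse = ";")
  write.csv(roster_out, file.path(output_dir, "roster.csv"), row.names = FALSE)
  ann_all <- if (length(ann_rows)) do.call(rbind, ann_rows[!vapply(ann_rows, is.null, TRUE)]) else NULL
  if (!is.null(ann_all)) {
    write.csv(ann_all, file.path(output_dir, "annotations.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(n_images = nrow(manifest), image_size = config$image_size,
         format = format, seed = seed, images = manifest),
    file.path(output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}
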
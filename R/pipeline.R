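## End-to-end orchestration: schema-validated run configuration, the full
## phantom -> preprocess -> detectors -> ensemble -> evaluation pipeline,
## and artifact/log writing.

#' Default run configuration
#'
#' Nested configuration mirroring each module's settings. The default sizes
#' a desk-scale experiment: 200 cases (120 benign / 80 malignant, three
#' single-view) rendered at 128 px, both detector variants trained per
#' holdout, two Monte-Carlo holdouts with an 85/15 case-level split.
#'
#' @return Nested list of class \code{run_config}.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    output_dir = "runs",
    phantom = list(
      n_benign = 120L, n_malignant = 80L, single_view_cases = 3L,
      histology_mode = "sample", image_size = 128L, particle_rate_scale = 1
    ),
    preprocess = list(
      gamma_exponent = 2, tophat_radius = 3L, mask_threshold_mode = "otsu",
      fixed_threshold = 0.1, overlay_gain = 0.5
    ),
    augment = list(
      exposure = 1.2, saturation = 1.5, enabled = TRUE, mosaic = FALSE
    ),
    detector = list(
      width = 8L, depth = 1L, epochs = 14L, batch_size = 8L, lr = 1.5e-3,
      conf_threshold = 0.25, nms_iou = 0.45, fuse_box = TRUE,
      noobj_weight = 0.5
    ),
    ensemble = list(
      hidden_widths = c(16L, 8L), learning_rate_init = 0.005,
      l2_alpha = 1e-4, validation_fraction = 0.2, patience = 10L,
      max_epochs = 200L
    ),
    evaluation = list(
      n_holdouts = 2L, scheme = "fraction-85-15", per_class_test_n = 50L,
      n_boot = 0L, cutoff_method = "youden"
    ),
    pretrain = list(
      enabled = FALSE, n_benign = 40L, n_malignant = 33L, epochs = 4L
    )
  ), class = "run_config")
}

# Recursively merge a partial config over the defaults, rejecting unknown
# keys before any compute runs.
merge_run_config <- function(partial, defaults = default_run_config(),
                             path = "") {
  if (is.null(partial)) return(defaults)
  if (!is.list(partial)) return(partial)
  unknown <- setdiff(names(partial), names(defaults))
  if (length(unknown) > 0) {
    stopf("unknown config key%s: %s", if (length(unknown) > 1) "s" else "",
          paste0(path, unknown, collapse = ", "))
  }
  out <- defaults
  for (nm in names(partial)) {
    out[[nm]] <- if (is.list(defaults[[nm]])) {
      merge_run_config(partial[[nm]], defaults[[nm]], paste0(path, nm, "."))
    } else {
      partial[[nm]]
    }
  }
  out
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected; omitted keys take their defaults.
#'
#' @param path YAML file, or a named list already in memory.
#' @return Validated \code{run_config}.
#' @export
load_run_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg <- merge_run_config(raw)
  structure(cfg, class = "run_config")
}

log_stage <- function(state, stage, status = "done", ...) {
  rec <- c(list(stage = stage, status = status), list(...))
  if (!is.null(state$log_path)) {
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = state$log_path, append = TRUE, sep = "")
  }
  if (isTRUE(state$verbose)) {
    message(sprintf("[calcamdf] %s: %s", stage, status))
  }
}

# Per-image table + rendered pixel data for a roster.
build_image_set <- function(roster, phantom_cfg, pre_cfg, seed) {
  views <- roster_views(roster$views)
  tab <- list(); imgs <- list(); pre <- list(); boxes <- list()
  k <- 0L
  for (i in seq_len(nrow(roster))) {
    for (v in views[[i]]) {
      k <- k + 1L
      vw <- render_view(roster[i, ], v, phantom_cfg, seed = derive_seed(seed, k))
      imgs[[k]] <- vw$pixels
      pre[[k]] <- mask_overlap(vw$pixels, pre_cfg)
      cls <- if (roster$label[i] == "malignant") 1L else 0L
      boxes[[k]] <- if (is.null(vw$lesion_box)) empty_boxes() else {
        data.frame(class = cls, x_min = vw$lesion_box[["x_min"]],
                   y_min = vw$lesion_box[["y_min"]],
                   width = vw$lesion_box[["width"]],
                   height = vw$lesion_box[["height"]])
      }
      tab[[k]] <- data.frame(
        idx = k, case_id = roster$case_id[i], view = v,
        label = cls, age_years = roster$age_years[i],
        distribution = roster$distribution[i], stringsAsFactors = FALSE
      )
      tab[[k]]$morphology <- roster$morphology[i]
    }
  }
  list(table = do.call(rbind, tab), images = imgs, preprocessed = pre,
       boxes = boxes)
}

# Train both detector variants and the ensemble on a train split and score a
# test split at case level. Returns data.frame(case_id, label, score_*).
fit_and_score <- function(imageset, train_ids, test_ids, cfg, seed,
                          warm = NULL) {
  tab <- imageset$table
  tr <- which(tab$case_id %in% train_ids)
  te <- which(tab$case_id %in% test_ids)
  S <- cfg$phantom$image_size

  tr_boxes <- do.call(rbind, imageset$boxes[tr])
  anchors <- anchors_from_boxes(tr_boxes, seed = seed)
  aug <- if (isTRUE(cfg$augment$enabled)) {
    augment_config(saturation = cfg$augment$saturation,
                   exposure = cfg$augment$exposure,
                   base_input_size = S, mosaic = cfg$augment$mosaic)
  } else NULL

  make_cfg <- function(variant) {
    detector_config(
      input_size = S, width = cfg$detector$width, depth = cfg$detector$depth,
      anchors = anchors, variant = variant,
      conf_threshold = cfg$detector$conf_threshold,
      nms_iou = cfg$detector$nms_iou, fuse_box = cfg$detector$fuse_box,
      noobj_weight = cfg$detector$noobj_weight, seed = derive_seed(seed, 11)
    )
  }
  ds_base <- lapply(tr, function(i) list(image = imageset$preprocessed[[i]],
                                         boxes = imageset$boxes[[i]]))
  ds_amdf <- lapply(tr, function(i) list(image = imageset$images[[i]],
                                         boxes = imageset$boxes[[i]]))
  mb <- warm$baseline %||% build_detector(make_cfg("baseline"))
  ma <- warm$amdf %||% build_detector(make_cfg("amdf"))
  if (!is.null(warm)) { mb$config$anchors <- anchors; ma$config$anchors <- anchors }
  fit_b <- train_detector(mb, ds_base, epochs = cfg$detector$epochs,
                          batch_size = cfg$detector$batch_size,
                          lr = cfg$detector$lr, seed = derive_seed(seed, 12),
                          augment = aug)
  fit_a <- train_detector(ma, ds_amdf, epochs = cfg$detector$epochs,
                          batch_size = cfg$detector$batch_size,
                          lr = cfg$detector$lr, seed = derive_seed(seed, 13),
                          augment = aug)

  score_rows <- function(idx) {
    t(vapply(idx, function(i) {
      c(conf_baseline = unname(score_image(fit_b$model, imageset$preprocessed[[i]])["malignant"]),
        conf_amdf = unname(score_image(fit_a$model, imageset$images[[i]])["malignant"]))
    }, numeric(2)))
  }
  conf_tr <- score_rows(tr)
  conf_te <- score_rows(te)

  covar <- function(idx) {
    t(vapply(idx, function(i) {
      b <- imageset$boxes[[i]]
      if (nrow(b) > 0) {
        c(age_years = tab$age_years[i], roi_size = b$width[1] * b$height[1],
          roi_aspect = b$width[1] / b$height[1])
      } else {
        c(age_years = tab$age_years[i], roi_size = 0, roi_aspect = 1)
      }
    }, numeric(3)))
  }
  cov_tr <- covar(tr); cov_te <- covar(te)
  std <- fit_standardizer(cov_tr, case_ids = tab$case_id[tr])
  check_standardizer_leakage(std, tab$case_id[te])

  feats <- function(idx, conf, cov) {
    t(vapply(seq_along(idx), function(r) {
      i <- idx[r]
      build_features(conf[r, "conf_baseline"], conf[r, "conf_amdf"],
                     tab$morphology[[i]], tab$distribution[i],
                     cov[r, "age_years"], cov[r, "roi_size"],
                     cov[r, "roi_aspect"], std)
    }, numeric(length(ENSEMBLE_FEATURE_NAMES))))
  }
  X_tr <- feats(tr, conf_tr, cov_tr)
  X_te <- feats(te, conf_te, cov_te)
  mlp <- train_ensemble(X_tr, tab$label[tr],
                        mlp_config(hidden_widths = cfg$ensemble$hidden_widths,
                                   learning_rate_init = cfg$ensemble$learning_rate_init,
                                   l2_alpha = cfg$ensemble$l2_alpha,
                                   validation_fraction = cfg$ensemble$validation_fraction,
                                   patience = cfg$ensemble$patience,
                                   max_epochs = cfg$ensemble$max_epochs,
                                   seed = derive_seed(seed, 14)))

  p_te <- predict_ensemble(mlp, X_te)
  agg <- function(v) tapply(v, tab$case_id[te], mean)
  ens <- agg(p_te); amdf <- agg(conf_te[, "conf_amdf"])
  base <- agg(conf_te[, "conf_baseline"])
  lab <- tapply(tab$label[te], tab$case_id[te], function(x) x[1])
  ids <- names(ens)
  data.frame(case_id = ids, label = as.integer(lab[ids]),
             score_baseline = as.numeric(base[ids]),
             score_amdf = as.numeric(amdf[ids]),
             score_ensemble = as.numeric(ens[ids]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full pipeline
#'
#' Generates the phantom roster and images, preprocesses the baseline
#' inputs, trains both detector variants and the ensemble inside each
#' Monte-Carlo holdout, and evaluates case-level performance of all three
#' systems (baseline, AMDF, ensemble). When \code{write_artifacts} is TRUE,
#' a run directory is created containing the resolved configuration, the
#' evaluation report (JSON + CSV summary), per-case scores and a structured
#' JSON-lines log.
#'
#' @param config A \code{run_config} (see [default_run_config()],
#'   [load_run_config()]).
#' @param write_artifacts Whether to write the run directory.
#' @param verbose Print stage progress.
#' @return List with \code{report} (a \code{calc_eval_report}),
#'   \code{scores} (per-holdout case scores), \code{config}, and
#'   \code{run_dir} (or NULL).
#' @export
run_pipeline <- function(config = default_run_config(),
                         write_artifacts = TRUE, verbose = FALSE) {
  cfg <- merge_run_config(unclass(config))
  seed <- as.integer(cfg$seed)
  run_dir <- NULL
  state <- list(verbose = verbose, log_path = NULL)
  if (write_artifacts) {
    run_dir <- file.path(cfg$output_dir,
                         sprintf("run_%s_seed%d",
                                 format(Sys.time(), "%Y%m%d-%H%M%S"), seed))
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    state$log_path <- file.path(run_dir, "log.jsonl")
    resolved <- cfg
    resolved$package_version <- as.character(utils::packageVersion("calcamdf"))
    yaml::write_yaml(resolved, file.path(run_dir, "config.yaml"))
  }

  log_stage(state, "phantom", "start")
  roster <- generate_roster(roster_config(
    n_benign = cfg$phantom$n_benign, n_malignant = cfg$phantom$n_malignant,
    single_view_cases = cfg$phantom$single_view_cases,
    histology_mode = cfg$phantom$histology_mode,
    seed = derive_seed(seed, 1)
  ))
  phantom_cfg <- phantom_image_config(
    image_size = cfg$phantom$image_size,
    particle_rate_scale = cfg$phantom$particle_rate_scale
  )
  pre_cfg <- preprocess_config(
    gamma_exponent = cfg$preprocess$gamma_exponent,
    tophat_radius = cfg$preprocess$tophat_radius,
    mask_threshold_mode = cfg$preprocess$mask_threshold_mode,
    fixed_threshold = cfg$preprocess$fixed_threshold,
    overlay_gain = cfg$preprocess$overlay_gain
  )
  log_stage(state, "phantom", "done", n_cases = nrow(roster),
            n_images = roster_image_count(roster))

  log_stage(state, "preprocess", "start")
  imageset <- build_image_set(roster, phantom_cfg, pre_cfg, derive_seed(seed, 2))
  log_stage(state, "preprocess", "done")

  warm <- NULL
  if (isTRUE(cfg$pretrain$enabled)) {
    log_stage(state, "pretrain", "start")
    pub_cfg <- cfg
    pub_cfg$phantom$n_benign <- cfg$pretrain$n_benign
    pub_cfg$phantom$n_malignant <- cfg$pretrain$n_malignant
    pub_roster <- generate_roster(roster_config(
      n_benign = cfg$pretrain$n_benign, n_malignant = cfg$pretrain$n_malignant,
      single_view_cases = 0L, seed = derive_seed(seed, 3)
    ))
    pub_set <- build_image_set(pub_roster, phantom_cfg, pre_cfg,
                               derive_seed(seed, 4))
    plan <- split_fraction(pub_roster, 0.8, derive_seed(seed, 5))
    pre_cfg_det <- cfg; pre_cfg_det$detector$epochs <- cfg$pretrain$epochs
    anchors <- anchors_from_boxes(do.call(rbind, pub_set$boxes), seed = seed)
    for (variant in c("baseline", "amdf")) {
      dcfg <- detector_config(
        input_size = cfg$phantom$image_size, width = cfg$detector$width,
        depth = cfg$detector$depth, anchors = anchors, variant = variant,
        seed = derive_seed(seed, 6)
      )
      tr_idx <- which(pub_set$table$case_id %in% plan$train)
      ds <- lapply(tr_idx, function(i) {
        img <- if (variant == "baseline") pub_set$preprocessed[[i]] else pub_set$images[[i]]
        list(image = img, boxes = pub_set$boxes[[i]])
      })
      fit <- train_detector(build_detector(dcfg), ds,
                            epochs = cfg$pretrain$epochs,
                            batch_size = cfg$detector$batch_size,
                            lr = cfg$detector$lr, seed = derive_seed(seed, 7))
      warm[[variant]] <- fit$model
    }
    log_stage(state, "pretrain", "done")
  }

  split_fn <- switch(cfg$evaluation$scheme,
    "fraction-80-20" = function(r, s) split_fraction(r, 0.8, s),
    "fraction-85-15" = function(r, s) split_fraction(r, 0.85, s),
    "balanced-test-50-per-class" = function(r, s) {
      split_balanced_test(r, cfg$evaluation$per_class_test_n, s)
    },
    stopf("unknown evaluation scheme: %s", cfg$evaluation$scheme)
  )

  scores_log <- new.env(); scores_log$rows <- list()
  pipeline_fn <- function(train_roster, test_roster, hseed) {
    log_stage(state, "holdout", "train", seed = hseed)
    out <- fit_and_score(imageset, train_roster$case_id, test_roster$case_id,
                         cfg, hseed, warm = warm)
    scores_log$rows[[length(scores_log$rows) + 1L]] <-
      cbind(data.frame(holdout_seed = hseed), out)
    out
  }
  log_stage(state, "evaluate", "start")
  report <- monte_carlo_cv(pipeline_fn, roster,
                           n_holdouts = cfg$evaluation$n_holdouts,
                           split_fn = split_fn, seed = derive_seed(seed, 8),
                           cutoff_method = cfg$evaluation$cutoff_method,
                           n_boot = cfg$evaluation$n_boot)
  log_stage(state, "evaluate", "done")

  scores <- do.call(rbind, scores_log$rows)
  if (write_artifacts) {
    jsonlite::write_json(
      list(pooled = report$pooled, per_holdout = report$per_holdout,
           n_holdouts = report$n_holdouts, seed = report$seed),
      file.path(run_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows"
    )
    write.csv(report$pooled, file.path(run_dir, "summary.csv"), row.names = FALSE)
    write.csv(scores, file.path(run_dir, "case_scores.csv"), row.names = FALSE)
    curve <- roc_curve(scores$score_ensemble, scores$label)
    write.csv(curve, file.path(run_dir, "roc_ensemble.csv"), row.names = FALSE)
    log_stage(state, "artifacts", "done", run_dir = run_dir)
  }
  list(report = report, scores = scores, config = cfg, run_dir = run_dir)
}
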
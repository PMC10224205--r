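## Case-level splitting, Monte-Carlo cross-validation, ROC/AUC with optimal
## cutoff, and confusion-matrix metrics with confidence intervals.

new_split_plan <- function(train, test, seed, scheme) {
  if (length(intersect(train, test)) > 0) stopf("split leakage: overlapping case ids")
  structure(list(train = train, test = test, seed = seed, scheme = scheme),
            class = "split_plan")
}

#' Validate a split plan against a roster
#'
#' Asserts the train/test case id sets are disjoint, jointly cover the
#' roster, and that no case's views straddle the two sides (splitting is by
#' case id, so a case id appearing on both sides is the failure mode).
#'
#' @param plan A \code{split_plan}.
#' @param roster The roster the plan was drawn from.
#' @export
validate_split <- function(plan, roster) {
  if (length(intersect(plan$train, plan$test)) > 0) {
    stopf("split leakage: case(s) straddle train and test")
  }
  allids <- sort(c(plan$train, plan$test))
  if (!identical(allids, sort(roster$case_id))) {
    stopf("split does not partition the roster")
  }
  invisible(TRUE)
}

#' Random fraction split at case level
#'
#' @param roster A \code{calc_roster}.
#' @param train_fraction Fraction in (0, 1); the train count is
#'   \code{floor(train_fraction * n)}.
#' @param seed Split seed.
#' @return A \code{split_plan}.
#' @export
split_fraction <- function(roster, train_fraction = 0.8, seed = 1L) {
  if (nrow(roster) == 0) stopf("empty roster")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must be in (0, 1)")
  }
  n_train <- floor(train_fraction * nrow(roster))
  ids <- roster$case_id
  train <- with_seed(seed, sample(ids, n_train))
  new_split_plan(train, setdiff(ids, train), seed,
                 sprintf("fraction-%g", train_fraction))
}

#' Balanced test split at case level
#'
#' Draws \code{per_class_test_n} random cases per class into the test set;
#' all remaining cases train.
#'
#' @param roster A \code{calc_roster}.
#' @param per_class_test_n Test cases per class.
#' @param seed Split seed.
#' @return A \code{split_plan}.
#' @export
split_balanced_test <- function(roster, per_class_test_n = 50L, seed = 1L) {
  if (nrow(roster) == 0) stopf("empty roster")
  test <- with_seed(seed, {
    unlist(lapply(unique(roster$label), function(cl) {
      ids <- roster$case_id[roster$label == cl]
      if (length(ids) < per_class_test_n) {
        stopf("class %s has fewer than %d cases", cl, per_class_test_n)
      }
      if (per_class_test_n == 0) character(0) else sample(ids, per_class_test_n)
    }))
  })
  new_split_plan(setdiff(roster$case_id, test), test, seed,
                 sprintf("balanced-test-%d-per-class", per_class_test_n))
}

#' Empirical ROC curve
#'
#' Candidate thresholds are midpoints between consecutive distinct scores
#' (plus sentinels beyond the extremes); a case is called positive when its
#' score is >= the threshold.
#'
#' @param scores Numeric scores (higher = more malignant).
#' @param labels 0/1 vector (1 = malignant).
#' @return data.frame \code{threshold, sensitivity, specificity, fpr} sorted
#'   by increasing threshold, with class \code{roc_curve}.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  u <- sort(unique(scores))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else NULL,
           u[length(u)] + 1)
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[labels == 0] < t), numeric(1))
  structure(data.frame(threshold = thr, sensitivity = sens,
                       specificity = spec, fpr = 1 - spec),
            class = c("roc_curve", "data.frame"))
}

# Trapezoidal area under the empirical ROC curve.
trapezoid_auc <- function(curve) {
  o <- order(curve$fpr, curve$sensitivity)
  x <- c(curve$fpr[o]); y <- c(curve$sensitivity[o])
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' ROC analysis with AUC and bootstrap CI
#'
#' AUC is computed by the trapezoidal rule over the empirical ROC curve
#' (equal to the Mann-Whitney concordance probability with tie correction).
#' The 95% CI comes from a stratified bootstrap (resampling within each
#' class), seeded.
#'
#' @param scores,labels As in [roc_curve()].
#' @param ci Whether to bootstrap a confidence interval.
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @return List of class \code{roc_auc}: \code{curve}, \code{auc},
#'   \code{ci} (length-2 or NULL).
#' @export
roc_auc <- function(scores, labels, ci = TRUE, n_boot = 2000L, seed = 1L) {
  curve <- roc_curve(scores, labels)
  auc <- trapezoid_auc(curve)
  ci_v <- NULL
  if (ci) {
    labels <- as.integer(labels)
    pos <- which(labels == 1); neg <- which(labels == 0)
    ci_v <- with_seed(seed, {
      reps <- vapply(seq_len(n_boot), function(b) {
        idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
        trapezoid_auc(roc_curve(scores[idx], labels[idx]))
      }, numeric(1))
      unname(quantile(reps, c(0.025, 0.975)))
    })
  }
  structure(list(curve = curve, auc = auc, ci = ci_v), class = "roc_auc")
}

#' Optimal ROC cutoff
#'
#' Default index is Youden's J (maximize sensitivity + specificity - 1) over
#' the curve's thresholds; the alternative minimizes the Euclidean distance
#' to the ideal (0, 1) ROC corner. Ties are broken towards higher
#' specificity, then towards the higher threshold.
#'
#' @param curve A [roc_curve()] (or \code{roc_auc} object).
#' @param method \code{"youden"} or \code{"closest01"}.
#' @return The chosen threshold (numeric scalar).
#' @export
optimal_cutoff <- function(curve, method = c("youden", "closest01")) {
  method <- match.arg(method)
  if (inherits(curve, "roc_auc")) curve <- curve$curve
  if (nrow(curve) < 2) stopf("degenerate ROC curve")
  crit <- if (method == "youden") {
    curve$sensitivity + curve$specificity - 1
  } else {
    -sqrt((1 - curve$sensitivity)^2 + (1 - curve$specificity)^2)
  }
  best <- which(crit == max(crit))
  if (length(best) > 1) {
    best <- best[order(curve$specificity[best], curve$threshold[best],
                       decreasing = TRUE)][1]
  }
  curve$threshold[best]
}

# Wilson 95% score interval for a proportion.
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Operating-point metrics at a threshold
#'
#' Sensitivity, specificity, accuracy and PPV of the classification rule
#' \code{score >= threshold}, each with a Wilson 95% CI.
#'
#' @param scores,labels As in [roc_curve()].
#' @param threshold Decision threshold.
#' @return data.frame with one row per metric: \code{metric, value, lo, hi,
#'   k, n}.
#' @export
metrics_at_cutoff <- function(scores, labels, threshold) {
  if (!is.finite(threshold)) stopf("threshold must be finite")
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  mk <- function(metric, k, n) {
    ci <- wilson_ci(k, n)
    data.frame(metric = metric, value = if (n > 0) k / n else NA_real_,
               lo = ci[1], hi = ci[2], k = k, n = n)
  }
  rbind(
    mk("sensitivity", tp, tp + fn),
    mk("specificity", tn, tn + fp),
    mk("accuracy", tp + tn, tp + fn + tn + fp),
    mk("ppv", tp, tp + fp)
  )
}

#' Monte-Carlo cross-validation
#'
#' Repeated random case-level splitting with full retraining per holdout.
#' The pipeline function receives the train/test rosters and a derived seed
#' and returns one case-level score data.frame with columns \code{case_id},
#' \code{label} and one or more \code{score_*} columns (one per scored
#' system). Per-holdout AUC, optimal cutoff and operating-point metrics are
#' computed for every score column; pooled metrics are means across holdouts
#' with normal-approximation 95% CIs from the across-holdout variation.
#'
#' @param pipeline \code{function(train_roster, test_roster, seed)}.
#' @param roster A \code{calc_roster}.
#' @param n_holdouts Number of independent re-splits (the reference protocol
#'   uses 5).
#' @param split_fn \code{function(roster, seed)} returning a
#'   \code{split_plan}.
#' @param seed Master seed; holdout seeds are derived from it.
#' @param cutoff_method Passed to [optimal_cutoff()].
#' @param n_boot Bootstrap replicates for per-holdout AUC CIs (0 disables).
#' @return List of class \code{calc_eval_report}: \code{per_holdout} (long
#'   data.frame), \code{pooled} (mean, lo, hi per system x metric),
#'   \code{n_holdouts}, \code{seed}.
#' @export
monte_carlo_cv <- function(pipeline, roster, n_holdouts = 5L,
                           split_fn = function(r, s) split_fraction(r, 0.85, s),
                           seed = 1L, cutoff_method = "youden",
                           n_boot = 0L) {
  if (n_holdouts < 1) stopf("n_holdouts must be >= 1")
  rows <- list()
  for (h in seq_len(n_holdouts)) {
    hseed <- derive_seed(seed, h)
    plan <- split_fn(roster, hseed)
    validate_split(plan, roster)
    res <- tryCatch(
      pipeline(roster[roster$case_id %in% plan$train, ],
               roster[roster$case_id %in% plan$test, ],
               hseed),
      error = function(e) stopf("pipeline failed in holdout %d: %s",
                                h, conditionMessage(e))
    )
    score_cols <- grep("^score_", names(res), value = TRUE)
    if (length(score_cols) == 0) stopf("pipeline returned no score_* columns")
    for (sc in score_cols) {
      ra <- roc_auc(res[[sc]], res$label, ci = n_boot > 0,
                    n_boot = max(n_boot, 1L), seed = hseed)
      cut <- optimal_cutoff(ra$curve, cutoff_method)
      mets <- metrics_at_cutoff(res[[sc]], res$label, cut)
      rows[[length(rows) + 1L]] <- data.frame(
        holdout = h, system = sub("^score_", "", sc),
        metric = c("auc", as.character(mets$metric)),
        value = c(ra$auc, mets$value),
        lo = c(if (is.null(ra$ci)) NA_real_ else ra$ci[1], mets$lo),
        hi = c(if (is.null(ra$ci)) NA_real_ else ra$ci[2], mets$hi),
        cutoff = cut,
        n_test = nrow(res)
      )
    }
  }
  per_holdout <- do.call(rbind, rows)
  pooled <- do.call(rbind, lapply(
    split(per_holdout, list(per_holdout$system, per_holdout$metric), drop = TRUE),
    function(g) {
      m <- mean(g$value)
      se <- if (nrow(g) > 1) sd(g$value) / sqrt(nrow(g)) else NA_real_
      data.frame(system = g$system[1], metric = g$metric[1], mean = m,
                 lo = m - 1.96 * se, hi = m + 1.96 * se)
    }))
  rownames(pooled) <- NULL
  structure(list(per_holdout = per_holdout, pooled = pooled,
                 n_holdouts = n_holdouts, seed = seed),
            class = "calc_eval_report")
}

#' @export
print.calc_eval_report <- function(x, ...) {
  cat(sprintf("Monte-Carlo cross-validation report (%d holdout%s, seed %d)\n",
              x$n_holdouts, if (x$n_holdouts > 1) "s" else "", x$seed))
  p <- x$pooled
  for (sys in unique(p$system)) {
    cat(sprintf("  %s:\n", sys))
    sub <- p[p$system == sys, ]
    for (i in seq_len(nrow(sub))) {
      ci <- if (is.na(sub$lo[i])) "" else sprintf(" (95%% CI %.3f-%.3f)", sub$lo[i], sub$hi[i])
      cat(sprintf("    %-12s %.3f%s\n", sub$metric[i], sub$mean[i], ci))
    }
  }
  invisible(x)
}
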
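## Deep-ensemble MLP: merges the two detector variants' confidence scores
## with multi-hot morphology, one-hot distribution and standardized
## continuous covariates into a final malignancy probability.

#' MLP configuration
#'
#' Two hidden layers with hyperbolic-tangent activation, trained with Adam,
#' L2 penalty 1e-4, initial learning rate 0.005 and 20% of the training rows
#' held out internally for early stopping.
#'
#' @param hidden_widths Sizes of the two hidden layers.
#' @param learning_rate_init Initial Adam learning rate.
#' @param l2_alpha L2 regularization strength.
#' @param validation_fraction Fraction of training rows held out for early
#'   stopping.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param max_epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param seed Seed for init, shuffling and the validation split.
#' @return List of class \code{mlp_config}.
#' @export
mlp_config <- function(hidden_widths = c(16L, 8L),
                       learning_rate_init = 0.005,
                       l2_alpha = 1e-4,
                       validation_fraction = 0.2,
                       patience = 10L,
                       max_epochs = 300L,
                       batch_size = 32L,
                       seed = 1L) {
  if (length(hidden_widths) != 2) stopf("exactly two hidden layers")
  structure(list(
    hidden_widths = as.integer(hidden_widths),
    learning_rate_init = learning_rate_init, l2_alpha = l2_alpha,
    validation_fraction = validation_fraction, patience = as.integer(patience),
    max_epochs = as.integer(max_epochs), batch_size = as.integer(batch_size),
    seed = as.integer(seed)
  ), class = "mlp_config")
}

#' Fit a feature standardizer
#'
#' Records training mean and standard deviation per continuous feature; the
#' transform is \code{z = (x - u) / s}. Refuses zero-variance features by
#' name. Optionally records the training case ids so downstream code can
#' verify no test rows leaked into the fit.
#'
#' @param x Numeric matrix or data.frame of training values (columns =
#'   features).
#' @param case_ids Optional character vector of the training case ids.
#' @return List of class \code{standardizer} with \code{mean}, \code{sd},
#'   \code{case_ids}.
#' @export
fit_standardizer <- function(x, case_ids = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stopf("standardizer needs at least two rows")
  u <- colMeans(x)
  s <- apply(x, 2, sd)
  zero <- s == 0 | !is.finite(s)
  if (any(zero)) {
    nm <- colnames(x)[zero] %||% which(zero)
    stopf("zero-variance feature(s): %s", paste(nm, collapse = ", "))
  }
  structure(list(mean = u, sd = s, case_ids = unique(case_ids)),
            class = "standardizer")
}

#' Apply a standardizer
#' @param std A \code{standardizer}.
#' @param x Matrix/data.frame with the same columns as fitted.
#' @return Matrix of z-scores.
#' @export
standardize <- function(std, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, std$mean), 2, std$sd, "/")
}

#' Leakage guard for the standardizer
#'
#' Fails if any of the supplied test case ids were part of the
#' standardizer's fit.
#'
#' @param std A \code{standardizer} fitted with \code{case_ids}.
#' @param test_case_ids Case ids of the evaluation split.
#' @export
check_standardizer_leakage <- function(std, test_case_ids) {
  if (is.null(std$case_ids)) stopf("standardizer was fitted without case ids")
  bad <- intersect(std$case_ids, test_case_ids)
  if (length(bad) > 0) {
    stopf("standardizer leakage: fitted on test case(s) %s",
          paste(head(bad, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Encode descriptor labels
#'
#' Multi-hot over the six morphology terms (a lesion can show more than one
#' morphologic pattern) concatenated with one-hot over the five distribution
#' terms. Unknown labels are an error; there is no catch-all bucket.
#'
#' @param morphology Non-empty character vector of morphology terms.
#' @param distribution Single distribution term.
#' @return Named 0/1 integer vector of length 11.
#' @export
encode_descriptors <- function(morphology, distribution) {
  if (length(morphology) == 0) stopf("morphology set must be non-empty")
  if (!all(morphology %in% MORPHOLOGY_LEVELS)) {
    stopf("unknown morphology label: %s",
          paste(setdiff(morphology, MORPHOLOGY_LEVELS), collapse = ", "))
  }
  if (length(distribution) != 1 || !distribution %in% DISTRIBUTION_LEVELS) {
    stopf("unknown distribution label: %s", paste(distribution, collapse = ", "))
  }
  m <- as.integer(MORPHOLOGY_LEVELS %in% morphology)
  d <- as.integer(DISTRIBUTION_LEVELS == distribution)
  stats::setNames(c(m, d), c(paste0("morph_", MORPHOLOGY_LEVELS),
                             paste0("dist_", DISTRIBUTION_LEVELS)))
}

ENSEMBLE_FEATURE_NAMES <- c(
  "conf_baseline", "conf_amdf",
  paste0("morph_", MORPHOLOGY_LEVELS), paste0("dist_", DISTRIBUTION_LEVELS),
  "age_z", "roi_size_z", "roi_aspect_z"
)

#' Build one ensemble feature vector
#'
#' Fixed concatenation order: the two detector confidences, the multi-hot
#' morphology flags, the one-hot distribution flags, then the standardized
#' continuous covariates (age, ROI area in px^2, ROI width/height ratio) —
#' 16 features with the default vocabularies.
#'
#' @param conf_baseline,conf_amdf Detector malignancy confidences in
#'   \code{[0, 1]} (baseline variant on the mask-overlap image, AMDF variant
#'   on the original image).
#' @param morphology,distribution Descriptor labels.
#' @param age_years,roi_size,roi_aspect Raw continuous covariates.
#' @param standardizer A \code{standardizer} fitted on the training split
#'   only, over columns \code{age_years, roi_size, roi_aspect}.
#' @return Named numeric vector of length 16.
#' @export
build_features <- function(conf_baseline, conf_amdf, morphology, distribution,
                           age_years, roi_size, roi_aspect, standardizer) {
  if (any(is.na(c(conf_baseline, conf_amdf, age_years, roi_size, roi_aspect)))) {
    stopf("missing feature component")
  }
  z <- standardize(standardizer,
                   matrix(c(age_years, roi_size, roi_aspect), 1, 3,
                          dimnames = list(NULL, c("age_years", "roi_size", "roi_aspect"))))
  v <- c(conf_baseline = conf_baseline, conf_amdf = conf_amdf,
         encode_descriptors(morphology, distribution),
         age_z = z[1, 1], roi_size_z = z[1, 2], roi_aspect_z = z[1, 3])
  names(v) <- ENSEMBLE_FEATURE_NAMES
  v
}

init_mlp <- function(n_in, cfg) {
  h1 <- cfg$hidden_widths[1]; h2 <- cfg$hidden_widths[2]
  glorot <- function(nin, nout) {
    matrix(runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nout, nin)
  }
  list(W1 = glorot(n_in, h1), b1 = numeric(h1),
       W2 = glorot(h1, h2), b2 = numeric(h2),
       W3 = glorot(h2, 1), b3 = 0)
}

mlp_forward <- function(par, X) {
  # X: n x p
  a1 <- tanh(X %*% t(par$W1) + matrix(par$b1, nrow(X), length(par$b1), byrow = TRUE))
  a2 <- tanh(a1 %*% t(par$W2) + matrix(par$b2, nrow(a1), length(par$b2), byrow = TRUE))
  z3 <- as.numeric(a2 %*% t(par$W3) + par$b3)
  list(a1 = a1, a2 = a2, z3 = z3, p = sigmoid(z3))
}

mlp_loss_grads <- function(par, X, y, l2) {
  n <- nrow(X)
  fw <- mlp_forward(par, X)
  loss <- bce_loss(y, fw$p) / n +
    l2 * (sum(par$W1^2) + sum(par$W2^2) + sum(par$W3^2)) / 2
  dz3 <- (fw$p - y) / n                       # n
  gW3 <- matrix(dz3, 1, n) %*% fw$a2 + l2 * par$W3
  gb3 <- sum(dz3)
  da2 <- outer(dz3, as.numeric(par$W3))       # n x h2
  dz2 <- da2 * (1 - fw$a2^2)
  gW2 <- t(dz2) %*% fw$a1 + l2 * par$W2
  gb2 <- colSums(dz2)
  da1 <- dz2 %*% par$W2
  dz1 <- da1 * (1 - fw$a1^2)
  gW1 <- t(dz1) %*% X + l2 * par$W1
  gb1 <- colSums(dz1)
  list(loss = loss,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3))
}

#' Train the deep-ensemble MLP
#'
#' Two-hidden-layer tanh network with a sigmoid output, trained by Adam on
#' binary cross-entropy with L2 penalty. A fraction of the training rows
#' (\code{validation_fraction}) is held out internally; training stops when
#' the validation loss has not improved for \code{patience} epochs and the
#' best-validation parameters are kept. Deterministic under the config seed.
#'
#' @param features Numeric matrix (rows = images, 16 columns by default).
#' @param labels 0/1 vector (1 = malignant).
#' @param config An [mlp_config()].
#' @return List of class \code{calc_ensemble} with parameters, config and
#'   training history.
#' @export
train_ensemble <- function(features, labels, config = mlp_config()) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stopf("training labels contain a single class")
  cfg <- config
  with_seed(cfg$seed, {
    n <- nrow(X)
    n_val <- max(1L, round(cfg$validation_fraction * n))
    val_idx <- sample(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    par <- init_mlp(ncol(X), cfg)
    m <- lapply(par, function(p) p * 0); v <- m
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0L
    best <- list(loss = Inf, par = par, epoch = 0L)
    hist <- list()
    stall <- 0L
    for (ep in seq_len(cfg$max_epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (bt in batches) {
        g <- mlp_loss_grads(par, X[bt, , drop = FALSE], y[bt], cfg$l2_alpha)
        t_step <- t_step + 1L
        c1 <- 1 - beta1^t_step; c2 <- 1 - beta2^t_step
        for (nm in names(par)) {
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g$grads[[nm]]
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g$grads[[nm]]^2
          par[[nm]] <- par[[nm]] -
            cfg$learning_rate_init * (m[[nm]] / c1) / (sqrt(v[[nm]] / c2) + eps)
        }
      }
      val_p <- mlp_forward(par, X[val_idx, , drop = FALSE])$p
      val_loss <- bce_loss(y[val_idx], val_p) / length(val_idx)
      hist[[ep]] <- data.frame(epoch = ep, val_loss = val_loss)
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, par = par, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    structure(list(par = best$par, config = cfg,
                   feature_names = colnames(X),
                   history = do.call(rbind, hist),
                   best_epoch = best$epoch),
              class = "calc_ensemble")
  })
}

#' Predict malignancy probabilities for feature rows
#' @param model A \code{calc_ensemble}.
#' @param features Matrix of feature rows.
#' @return Numeric vector of probabilities.
#' @export
predict_ensemble <- function(model, features) {
  mlp_forward(model$par, as.matrix(features))$p
}

#' Case-level prediction by view averaging
#'
#' Per-view probabilities are averaged over the case's 1-2 views;
#' single-view cases pass through unchanged.
#'
#' @param model A \code{calc_ensemble}.
#' @param view_features Matrix with one row per view of the case.
#' @return Scalar probability in \code{[0, 1]}.
#' @export
predict_case <- function(model, view_features) {
  vf <- as.matrix(view_features)
  if (nrow(vf) == 0) stopf("a case needs at least one view")
  mean(predict_ensemble(model, vf))
}
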
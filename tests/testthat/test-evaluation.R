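test_that("fraction splits reproduce the public-cohort arithmetic", {
  roster <- generate_roster(roster_config(n_benign = 414, n_malignant = 339,
                                          single_view_cases = 0, seed = 18))
  plan <- split_fraction(roster, 0.8, seed = 1)
  expect_equal(length(plan$train), 602)
  expect_equal(length(plan$test), 151)
  expect_true(validate_split(plan, roster))
  # small even split
  r10 <- generate_roster(roster_config(n_benign = 5, n_malignant = 5,
                                       single_view_cases = 0, seed = 19))
  p10 <- split_fraction(r10, 0.5, seed = 1)
  expect_equal(length(p10$train), 5)
  # different seeds change membership, not sizes
  p2 <- split_fraction(roster, 0.8, seed = 2)
  expect_equal(length(p2$train), 602)
  expect_false(setequal(plan$train, p2$train))
  expect_error(split_fraction(roster, 1.2), "train_fraction")
})

test_that("balanced test split matches the in-house cohort arithmetic", {
  roster <- generate_roster(roster_config(seed = 20))   # 432 + 204 cases
  plan <- split_balanced_test(roster, 50, seed = 1)
  expect_equal(length(plan$train), 536)
  expect_equal(length(plan$test), 100)
  train_lab <- roster$label[roster$case_id %in% plan$train]
  expect_equal(sum(train_lab == "benign"), 382)   # 432 - 50
  expect_equal(sum(train_lab == "malignant"), 154)
  # zero test size keeps everything in training
  p0 <- split_balanced_test(roster, 0, seed = 1)
  expect_equal(length(p0$train), 636)
  small <- generate_roster(roster_config(n_benign = 10, n_malignant = 10,
                                         single_view_cases = 0, seed = 4))
  expect_error(split_balanced_test(small, 50), "fewer than")
})

test_that("a case straddling train and test fails the harness", {
  roster <- generate_roster(roster_config(n_benign = 5, n_malignant = 5,
                                          single_view_cases = 0, seed = 22))
  plan <- split_fraction(roster, 0.5, seed = 1)
  tampered <- plan
  tampered$test <- c(tampered$test, tampered$train[1])
  expect_error(validate_split(tampered, roster), "straddle")
  incomplete <- plan
  incomplete$test <- incomplete$test[-1]
  expect_error(validate_split(incomplete, roster), "partition")
})

test_that("trapezoidal AUC equals the all-pairs concordance oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), ci = FALSE)$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5), ci = FALSE)$auc, 0.5)
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)   # ties likely
    expect_equal(roc_auc(scores, labels, ci = FALSE)$auc,
                 oracle_auc_pairs(scores, labels))
  }
  expect_error(roc_auc(runif(5), rep(1, 5), ci = FALSE), "both classes")
})

test_that("bootstrap CI brackets the point AUC and pROC agrees", {
  set.seed(24)
  labels <- rbinom(60, 1, 0.5)
  scores <- labels * 0.5 + runif(60)
  ra <- roc_auc(scores, labels, ci = TRUE, n_boot = 300, seed = 9)
  expect_true(ra$ci[1] <= ra$auc && ra$auc <= ra$ci[2])
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(ra$auc, ref, tolerance = 1e-10)
})

test_that("optimal cutoff maximizes Youden's J with documented tie-breaks", {
  # toy curve: (sens, spec) = (1.0, 0.5) vs (0.8, 0.9) -> J picks the latter
  toy <- data.frame(threshold = c(0.4, 0.6), sensitivity = c(1.0, 0.8),
                    specificity = c(0.5, 0.9), fpr = c(0.5, 0.1))
  expect_equal(optimal_cutoff(toy), 0.6)
  # perfectly separated scores: cutoff sits strictly in the gap
  scores <- c(0.1, 0.2, 0.8, 0.9); labels <- c(0, 0, 1, 1)
  cut <- optimal_cutoff(roc_curve(scores, labels))
  expect_gt(cut, 0.2); expect_lt(cut, 0.8)
  # exhaustive enumeration agrees on random instances; ties break to the
  # higher-specificity (higher) threshold
  set.seed(25)
  for (rep in 1:20) {
    labels <- c(0, 1, rbinom(28, 1, 0.4))
    scores <- round(runif(30), 1)
    curve <- roc_curve(scores, labels)
    j <- curve$sensitivity + curve$specificity - 1
    best <- which(j == max(j))
    pick <- optimal_cutoff(curve)
    expect_true(pick %in% curve$threshold[best])
    cands <- curve[best, ]
    expect_equal(curve$specificity[curve$threshold == pick],
                 max(cands$specificity))
  }
  # the two indices agree on a symmetric curve
  sym <- data.frame(threshold = c(0.3, 0.5, 0.7),
                    sensitivity = c(0.9, 0.8, 0.6),
                    specificity = c(0.6, 0.8, 0.9),
                    fpr = c(0.4, 0.2, 0.1))
  expect_equal(optimal_cutoff(sym, "youden"), optimal_cutoff(sym, "closest01"))
  expect_error(optimal_cutoff(sym[1, ]), "degenerate")
})

test_that("operating-point metrics match the hand-counted confusion matrix", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.4, 0.3, 0.3, 0.1, 0.1)
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  m <- metrics_at_cutoff(scores, labels, 0.5)
  expect_equal(m$value[m$metric == "sensitivity"], 0.8)
  expect_equal(m$value[m$metric == "specificity"], 1.0)
  expect_equal(m$value[m$metric == "accuracy"], 0.9)
  expect_equal(m$value[m$metric == "ppv"], 1.0)
  # CIs contain their point estimates
  expect_true(all(m$lo <= m$value & m$value <= m$hi))
  # all-correct calls give metric 1.0 everywhere
  perf <- metrics_at_cutoff(c(0.9, 0.9, 0.1), c(1, 1, 0), 0.5)
  expect_true(all(perf$value == 1))
  # specificity equals sensitivity of the label-swapped, mirrored problem
  set.seed(26)
  s <- runif(40); l <- rbinom(40, 1, 0.5); l[1:2] <- 0:1
  thr <- 0.47
  a <- metrics_at_cutoff(s, l, thr)
  b <- metrics_at_cutoff(-s, 1 - l, -thr + 1e-12)
  expect_equal(a$value[a$metric == "specificity"],
               b$value[b$metric == "sensitivity"])
  expect_error(metrics_at_cutoff(s, l, NA), "finite")
})

test_that("case-averaged AUC is invariant to per-case view order", {
  set.seed(27)
  n <- 30
  v1 <- runif(n); v2 <- runif(n)
  labels <- rbinom(n, 1, 0.5); labels[1:2] <- 0:1
  auc_a <- roc_auc((v1 + v2) / 2, labels, ci = FALSE)$auc
  auc_b <- roc_auc((v2 + v1) / 2, labels, ci = FALSE)$auc
  expect_equal(auc_a, auc_b)
})

test_that("Monte-Carlo CV pools holdouts deterministically", {
  roster <- generate_roster(roster_config(n_benign = 20, n_malignant = 20,
                                          single_view_cases = 0, seed = 28))
  # deterministic pipeline: score = 1 for malignant, noise-free structure
  fake <- function(train_roster, test_roster, seed) {
    lab <- as.integer(test_roster$label == "malignant")
    data.frame(case_id = test_roster$case_id, label = lab,
               score_sys = lab * 0.6 + 0.2)
  }
  rep1 <- monte_carlo_cv(fake, roster, n_holdouts = 1,
                         split_fn = function(r, s) split_fraction(r, 0.8, s),
                         seed = 3)
  expect_equal(rep1$pooled$mean[rep1$pooled$metric == "auc"], 1)
  # a single holdout equals the single-split evaluation
  expect_equal(nrow(rep1$per_holdout), 5)   # auc + 4 operating metrics
  rep5a <- monte_carlo_cv(fake, roster, n_holdouts = 3, seed = 4)
  rep5b <- monte_carlo_cv(fake, roster, n_holdouts = 3, seed = 4)
  expect_identical(rep5a, rep5b)
  expect_error(monte_carlo_cv(fake, roster, n_holdouts = 0), "n_holdouts")
})
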
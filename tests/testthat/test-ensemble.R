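test_that("standardizer reproduces training moments and guards leakage", {
  std <- fit_standardizer(matrix(c(1, 2, 3), ncol = 1,
                                 dimnames = list(NULL, "age_years")))
  expect_equal(unname(std$mean), 2)
  z <- standardize(std, matrix(c(1, 2, 3), ncol = 1))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(standardize(std, matrix(2, 1, 1))[1, 1], 0)
  # random sample matches the brute-force mean/sd oracle
  set.seed(14)
  x <- matrix(rnorm(50, 5, 3), ncol = 1, dimnames = list(NULL, "v"))
  std2 <- fit_standardizer(x)
  expect_equal(unname(std2$mean), sum(x) / 50)
  expect_equal(unname(std2$sd), sqrt(sum((x - mean(x))^2) / 49))
  # zero variance is refused by feature name
  expect_error(fit_standardizer(cbind(ok = rnorm(5), flat = rep(1, 5))), "flat")
  # test-row leakage is detected
  std3 <- fit_standardizer(x, case_ids = c("a", "b", "c"))
  expect_error(check_standardizer_leakage(std3, c("c", "d")), "leakage")
  expect_true(check_standardizer_leakage(std3, c("d", "e")))
  # refitting with extra rows shifts the z-values (what the guard protects)
  std4 <- fit_standardizer(rbind(x, 40))
  expect_false(isTRUE(all.equal(standardize(std2, x), standardize(std4, x))))
})

test_that("descriptor encoding is multi-hot + one-hot over fixed vocabularies", {
  e1 <- encode_descriptors("pleomorphic", "grouped")
  expect_equal(sum(e1), 2)
  expect_equal(e1[["morph_pleomorphic"]], 1L)
  expect_equal(e1[["dist_grouped"]], 1L)
  # a lesion with two morphologic patterns sets three flags in total
  e2 <- encode_descriptors(c("amorphous", "fine-linear-branching"), "segmental")
  expect_equal(sum(e2), 3)
  expect_equal(length(e2), 11)
  expect_error(encode_descriptors(character(0), "grouped"), "non-empty")
  expect_error(encode_descriptors("spiculated", "grouped"), "unknown")
  expect_error(encode_descriptors("round", "clustered"), "unknown")
})

test_that("feature vectors have the documented length and order", {
  std <- fit_standardizer(
    matrix(rnorm(30), 10, 3,
           dimnames = list(NULL, c("age_years", "roi_size", "roi_aspect")))
  )
  v <- build_features(0.2, 0.8, c("round", "punctate"), "grouped",
                      55, 400, 1.2, std)
  expect_equal(length(v), 16)
  expect_identical(names(v), calcamdf:::ENSEMBLE_FEATURE_NAMES)
  expect_equal(unname(v[1:2]), c(0.2, 0.8))
  # identical inputs give identical vectors
  expect_identical(v, build_features(0.2, 0.8, c("round", "punctate"),
                                     "grouped", 55, 400, 1.2, std))
  expect_error(build_features(NA, 0.8, "round", "grouped", 55, 400, 1.2, std),
               "missing")
})

test_that("the MLP learns separable data and is seed-deterministic", {
  set.seed(15)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  X <- cbind(y + rnorm(n, 0, 0.1), matrix(rnorm(n * 3), n, 4 - 1))
  m <- train_ensemble(X, y, mlp_config(seed = 5))
  acc <- mean((predict_ensemble(m, X) >= 0.5) == y)
  expect_gte(acc, 0.95)
  m2 <- train_ensemble(X, y, mlp_config(seed = 5))
  expect_equal(predict_ensemble(m, X), predict_ensemble(m2, X))
  expect_error(train_ensemble(X, rep(1, n)), "single class")
})

test_that("label-shuffled training yields chance-level held-out AUC", {
  set.seed(16)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  X <- cbind(y + rnorm(n, 0, 0.3), matrix(rnorm(n * 3), n, 3))
  y_perm <- sample(y)
  tr <- 1:200; te <- 201:400
  m <- train_ensemble(X[tr, ], y_perm[tr], mlp_config(seed = 6))
  auc <- roc_auc(predict_ensemble(m, X[te, ]), y_perm[te], ci = FALSE)$auc
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("case prediction averages the per-view probabilities", {
  set.seed(17)
  X <- matrix(rnorm(40), 10, 4)
  y <- rbinom(10, 1, 0.5); y[1:2] <- c(0, 1)
  m <- train_ensemble(X, y, mlp_config(seed = 7, max_epochs = 20))
  vf <- matrix(rnorm(8), 2, 4)
  p <- predict_ensemble(m, vf)
  expect_equal(predict_case(m, vf), mean(p))
  # order invariance and single-view pass-through
  expect_equal(predict_case(m, vf), predict_case(m, vf[2:1, ]))
  expect_equal(predict_case(m, vf[1, , drop = FALSE]), p[1])
  expect_error(predict_case(m, vf[0, , drop = FALSE]), "at least one view")
})
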
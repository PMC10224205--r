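test_that("detector build honours grid sizes, channel layout and seeding", {
  cfg <- detector_config(input_size = 128, width = 4, seed = 2)
  m <- build_detector(cfg)
  fw <- forward_detector(m, matrix(0.5, 128, 128))
  expect_equal(dim(fw$d3), c(16, 16, 21))
  expect_equal(dim(fw$d4), c(8, 8, 21))
  expect_equal(dim(fw$d5), c(4, 4, 21))
  # same seed, same initial parameters; parameter count grows with width
  m2 <- build_detector(cfg)
  expect_identical(m$params, m2$params)
  wide <- build_detector(detector_config(input_size = 128, width = 8, seed = 2))
  expect_gt(n_parameters(wide), n_parameters(m))
  expect_error(detector_config(input_size = 100), "divisible by 32")
})

test_that("softmax reliabilities are a proper, stable, shift-invariant simplex", {
  expect_equal(unname(softmax_reliabilities(0, 0, 0)), rep(1 / 3, 3))
  set.seed(3)
  for (rep in 1:50) {
    l <- rnorm(3, 0, 5)
    r <- softmax_reliabilities(l)
    expect_lt(abs(sum(r) - 1), 1e-12)
    expect_true(all(r >= 0 & r <= 1))
    # invariant to adding a constant to all lambda
    expect_equal(unname(r), unname(softmax_reliabilities(l + 17.3)))
  }
  # extreme inputs do not overflow
  r <- softmax_reliabilities(1000, 0, 0)
  expect_true(all(is.finite(r)))
  expect_gt(r[["alpha"]], 1 - 1e-12)
  expect_error(softmax_reliabilities(Inf, 0, 0), "finite")
})

test_that("amdf_fuse matches the brute-force weighted-sum oracle", {
  set.seed(4)
  d3 <- array(rnorm(4 * 4 * 21), c(4, 4, 21))
  d4 <- array(rnorm(2 * 2 * 21), c(2, 2, 21))
  d5 <- array(rnorm(1 * 1 * 21), c(1, 1, 21))
  w <- fusion_weights(c(0.7, -0.3, 1.1))
  ys <- amdf_fuse(d3, d4, d5, w)
  r <- w$reliabilities
  # double-loop oracle with explicit nearest-neighbour indexing
  expected <- array(0, dim(d3))
  for (i in 1:4) for (j in 1:4) for (c in 1:21) {
    expected[i, j, c] <- r[["alpha"]] * d3[i, j, c] +
      r[["beta"]] * d4[ceiling(i / 2), ceiling(j / 2), c] +
      r[["gamma"]] * d5[1, 1, c]
  }
  expect_equal(ys, expected, tolerance = 1e-12)
  # identical tensors at all scales pass through (weights sum to 1)
  same <- array(rnorm(4 * 4 * 21), c(4, 4, 21))
  expect_equal(amdf_fuse(same, same, same, fusion_weights(c(0.5, -1, 2))),
               same, tolerance = 1e-12)
  # degenerate weights select one scale
  expect_equal(amdf_fuse(d3, d4, d5, fusion_weights(c(1000, 0, 0))), d3,
               tolerance = 1e-9)
  # linearity: doubling d3 changes ys by exactly alpha * d3
  expect_equal(amdf_fuse(2 * d3, d4, d5, w) - ys, r[["alpha"]] * d3,
               tolerance = 1e-12)
  expect_error(amdf_fuse(d3, d4, d5[, , 1:7, drop = FALSE], w), "channel")
})

test_that("image_score reduces objectness-class products as documented", {
  d <- array(-Inf, c(2, 2, 21))
  expect_equal(unname(image_score(d)), c(0, 0))
  # one live anchor slot with logit-0 objectness and malignant class
  d[1, 1, 1] <- 0    # p_c, anchor 1
  d[1, 1, 7] <- 0    # c_2 (malignant), anchor 1
  expect_equal(image_score(d)[["malignant"]], 0.25)
  # random tensor equals the brute-force product maximum
  set.seed(8)
  z <- array(rnorm(4 * 4 * 21), c(4, 4, 21))
  best <- -Inf
  for (i in 1:4) for (j in 1:4) for (a in 1:3) {
    p <- 1 / (1 + exp(-z[i, j, (a - 1) * 7 + 1]))
    cc <- 1 / (1 + exp(-z[i, j, (a - 1) * 7 + 7]))
    best <- max(best, p * cc)
  }
  expect_equal(image_score(z)[["malignant"]], best)
  expect_error(image_score(list()), "empty")
})

test_that("bce_loss matches its definition and analytic values", {
  expect_lt(bce_loss(c(1, 0), c(1, 0)), 1e-6)
  expect_equal(bce_loss(c(1, 0, 1), rep(0.5, 3)), 3 * log(2))
  set.seed(9)
  y <- rbinom(20, 1, 0.5); p <- runif(20, 0.01, 0.99)
  manual <- 0
  for (i in 1:20) manual <- manual - (y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))
  expect_equal(bce_loss(y, p), manual)
  expect_error(bce_loss(c(1, 0), 0.5), "length")
})

test_that("target assignment picks the responsible cell and best anchor", {
  cfg <- detector_config(input_size = 128, width = 4)
  # centred box: responsible cell is at the grid midpoint of every scale
  ctr <- data.frame(class = 1L, x_min = 56, y_min = 56, width = 16, height = 16)
  tg <- assign_targets(ctr, cfg)
  for (l in c("l3", "l4", "l5")) {
    n <- dim(tg[[l]]$obj)[1]
    pos <- which(tg[[l]]$obj == 1, arr.ind = TRUE)
    expect_equal(nrow(pos), 1)
    expect_equal(unname(pos[1, 1:2]), c(n / 2 + 1, n / 2 + 1))
    expect_equal(sum(tg[[l]]$cls), 1)  # one-hot
  }
  # no boxes: all-zero objectness
  tg0 <- assign_targets(empty_boxes_df(), cfg)
  expect_equal(sum(tg0$l3$obj) + sum(tg0$l4$obj) + sum(tg0$l5$obj), 0)
  # two disjoint boxes: exactly two positive slots per scale, and the
  # chosen anchor is the shape-IoU argmax computed by brute force
  two <- data.frame(class = c(0L, 1L), x_min = c(8, 80), y_min = c(8, 80),
                    width = c(12, 40), height = c(10, 44))
  tg2 <- assign_targets(two, cfg)
  for (li in 1:3) {
    l <- paste0("l", li + 2)
    expect_equal(sum(tg2[[l]]$pos), 2)
    anchors <- cfg$anchors[(li - 1) * 3 + 1:3, , drop = FALSE]
    for (bi in 1:2) {
      ious <- apply(anchors, 1, function(a) {
        inter <- min(two$width[bi], a[1]) * min(two$height[bi], a[2])
        inter / (two$width[bi] * two$height[bi] + a[1] * a[2] - inter)
      })
      stride <- 2^(li + 2)
      row <- floor((two$y_min[bi] + two$height[bi] / 2) / stride) + 1
      col <- floor((two$x_min[bi] + two$width[bi] / 2) / stride) + 1
      expect_true(tg2[[l]]$pos[row, col, which.max(ious)])
    }
  }
  expect_error(assign_targets(data.frame(class = 0L, x_min = -4, y_min = 0,
                                         width = 10, height = 10), cfg),
               "outside")
})

test_that("lambda gradients match central finite differences on a frozen batch", {
  cfg <- detector_config(input_size = 64, width = 4, variant = "amdf", seed = 3)
  m <- build_detector(cfg)
  m$lambda <- c(0.4, -0.1, 0.2)
  set.seed(10)
  img <- matrix(runif(64 * 64), 64, 64)
  tg <- assign_targets(data.frame(class = 1L, x_min = 18, y_min = 26,
                                  width = 20, height = 14), cfg)
  lg <- calcamdf:::detector_loss_grads(m, img, tg)
  eps <- 1e-5
  for (i in 1:3) {
    mp <- m; mp$lambda[i] <- mp$lambda[i] + eps
    mm <- m; mm$lambda[i] <- mm$lambda[i] - eps
    fd <- (calcamdf:::detector_loss_grads(mp, img, tg, compute_grads = FALSE)$loss -
             calcamdf:::detector_loss_grads(mm, img, tg, compute_grads = FALSE)$loss) /
      (2 * eps)
    expect_lt(abs(lg$dlambda[i] - fd) / max(abs(fd), 1e-8), 1e-3)
  }
})

test_that("training overfits a single batch and is trace-deterministic", {
  ds <- make_detector_dataset(4, image_size = 64, seed = 300)[1:4]
  cfg <- detector_config(input_size = 64, width = 4, variant = "amdf", seed = 6)
  fit <- train_detector(build_detector(cfg), ds, epochs = 200, batch_size = 4,
                        lr = 2e-3, seed = 7)
  tr <- fit$trace
  expect_lt(tail(tr$loss, 1), 0.10 * tr$loss[1])
  # smoothed trace is non-increasing over a window
  smooth <- stats::filter(tr$loss, rep(1 / 20, 20), sides = 1)
  smooth <- smooth[!is.na(smooth)]
  expect_true(all(diff(smooth) <= 1e-3))
  # identical seed reproduces the whole trace
  fit2 <- train_detector(build_detector(cfg), ds, epochs = 5, batch_size = 4,
                         lr = 2e-3, seed = 7)
  fit3 <- train_detector(build_detector(cfg), ds, epochs = 5, batch_size = 4,
                         lr = 2e-3, seed = 7)
  expect_identical(fit2$trace, fit3$trace)
  expect_error(train_detector(build_detector(cfg), list()), "empty")
})

test_that("decoding and NMS behave at the extremes and match the oracle", {
  ds <- make_detector_dataset(2, image_size = 64, seed = 310)
  cfg <- detector_config(input_size = 64, width = 4, variant = "amdf", seed = 8)
  m <- build_detector(cfg)
  # nothing clears an impossible confidence threshold
  expect_equal(nrow(detect(m, ds[[1]]$image, conf_threshold = 1.0)), 0)
  # duplicate boxes collapse to one survivor
  b2 <- data.frame(x_min = c(10, 10), y_min = c(10, 10),
                   width = c(20, 20), height = c(20, 20))
  expect_equal(length(greedy_nms(b2, c(0.9, 0.8), 0.5)), 1)
  # random box sets match the independent greedy formulation
  set.seed(12)
  for (rep in 1:30) {
    n <- sample(5:25, 1)
    boxes <- data.frame(x_min = runif(n, 0, 80), y_min = runif(n, 0, 80),
                        width = runif(n, 5, 40), height = runif(n, 5, 40))
    scores <- runif(n)
    thr <- runif(1, 0.2, 0.7)
    expect_equal(sort(greedy_nms(boxes, scores, thr)),
                 sort(oracle_nms(boxes, scores, thr)))
  }
})

test_that("reliability recovery: finest-scale signal drives alpha up", {
  ds <- make_fine_pair_dataset(16, seed = 2)
  cfg <- detector_config(input_size = 64, width = 4, variant = "amdf", seed = 9)
  fit <- train_detector(build_detector(cfg), ds, epochs = 100, batch_size = 16,
                        lr = 2e-3, seed = 10)
  rel <- softmax_reliabilities(fit$model$lambda)
  expect_gt(rel[["alpha"]], rel[["beta"]])
  expect_gt(rel[["alpha"]], rel[["gamma"]])
})
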
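test_that("roster composition is exact and class-conditionally structured", {
  roster <- generate_roster(roster_config(seed = 7))
  expect_equal(nrow(roster), 636)
  expect_equal(sum(roster$label == "benign"), 432)
  expect_equal(sum(roster$label == "malignant"), 204)
  # benign cases never carry a malignant histology
  expect_true(all(roster$histology[roster$label == "benign"] == "none"))
  expect_true(all(roster$histology[roster$label == "malignant"] %in%
                    c("IDC", "ILC", "DCIS")))
  expect_true(all(roster$age_years >= 29 & roster$age_years <= 81))
  expect_true(all(lengths(roster$morphology) >= 1))
  nviews <- lengths(roster_views(roster$views))
  expect_true(all(nviews %in% 1:2))
  expect_equal(sum(nviews == 1), 3)
  expect_equal(roster_image_count(roster), 2 * 636 - 3)
  # deterministic under the seed
  expect_identical(roster, generate_roster(roster_config(seed = 7)))
  expect_false(identical(roster$views,
                         generate_roster(roster_config(seed = 8))$views))
})

test_that("empty and invalid roster configurations are handled", {
  empty <- generate_roster(roster_config(n_benign = 0, n_malignant = 0,
                                         single_view_cases = 0))
  expect_equal(nrow(empty), 0)
  bad <- roster_config()
  bad$histology_probs <- c(IDC = 0.5, ILC = 0.2, DCIS = 0.2)
  expect_error(generate_roster(bad), "probabilities")
})

test_that("histology sampling matches the multinomial and quota arithmetic", {
  # quota mode reproduces the exact cohort counts 61 IDC / 3 ILC / 140 DCIS
  rq <- generate_roster(roster_config(histology_mode = "quota", seed = 3))
  counts <- table(factor(rq$histology[rq$label == "malignant"],
                         levels = c("IDC", "ILC", "DCIS")))
  expect_equal(as.integer(counts), c(61, 3, 140))
  # sampled mode stays inside the multinomial bulk (chi-square GOF)
  rs <- generate_roster(roster_config(histology_mode = "sample", seed = 3))
  cs <- table(factor(rs$histology[rs$label == "malignant"],
                     levels = c("IDC", "ILC", "DCIS")))
  gof <- suppressWarnings(
    stats::chisq.test(as.integer(cs), p = c(61, 3, 140) / 204)
  )
  expect_gt(gof$p.value, 0.001)
})

test_that("rendered lesions are brighter than background and reproducible", {
  roster <- generate_roster(roster_config(n_benign = 2, n_malignant = 2,
                                          single_view_cases = 0, seed = 21))
  v <- render_view(roster[3, ], "CC", phantom_image_config(), seed = 5)
  expect_s3_class(v, "calc_view")
  expect_true(v$particle_count > 0)
  b <- v$lesion_box
  S <- nrow(v$pixels)
  expect_true(b[["x_min"]] >= 0 && b[["y_min"]] >= 0)
  expect_true(b[["x_min"]] + b[["width"]] <= S)
  expect_true(b[["y_min"]] + b[["height"]] <= S)
  sel <- function(img) img[(b[["y_min"]] + 1):(b[["y_min"]] + b[["height"]]),
                           (b[["x_min"]] + 1):(b[["x_min"]] + b[["width"]])]
  # particle-free render under the same seed is the exact background oracle
  bg <- render_view(roster[3, ], "CC",
                    phantom_image_config(particle_rate_scale = 0), seed = 5)
  expect_gt(mean(sel(v$pixels)), mean(sel(bg$pixels)))
  # bit-identical under the same seed
  v2 <- render_view(roster[3, ], "CC", phantom_image_config(), seed = 5)
  expect_identical(v$pixels, v2$pixels)
})

test_that("zero particle budget renders a lesion-free image", {
  roster <- generate_roster(roster_config(n_benign = 1, n_malignant = 0,
                                          single_view_cases = 0, seed = 2))
  v <- render_view(roster[1, ], "CC",
                   phantom_image_config(particle_rate_scale = 0), seed = 1)
  expect_equal(v$particle_count, 0)
  expect_null(v$lesion_box)
})

test_that("malignant-morphology renders separate from background at alpha 0.01", {
  for (m in c("pleomorphic", "amorphous", "fine-linear-branching")) {
    case <- list(case_id = "t", label = "malignant", morphology = list(m),
                 distribution = "grouped")
    v <- render_view(case, "CC", phantom_image_config(), seed = 31)
    b <- v$lesion_box
    S <- nrow(v$pixels)
    msk <- matrix(FALSE, S, S)
    msk[(b[["y_min"]] + 1):(b[["y_min"]] + b[["height"]]),
        (b[["x_min"]] + 1):(b[["x_min"]] + b[["width"]])] <- TRUE
    tt <- t.test(v$pixels[msk], v$pixels[!msk], alternative = "greater")
    expect_lt(tt$p.value, 0.01)
  }
})

test_that("unknown descriptors are rejected by the renderer", {
  case <- list(case_id = "t", label = "benign", morphology = list("spiky"),
               distribution = "grouped")
  expect_error(render_view(case, "CC", seed = 1), "morphology")
  case$morphology <- list("round"); case$distribution <- "scattered"
  expect_error(render_view(case, "CC", seed = 1), "distribution")
})

test_that("emit_dataset writes one image and annotation per view plus manifest", {
  roster <- generate_roster(roster_config(n_benign = 1, n_malignant = 1,
                                          single_view_cases = 0, seed = 13))
  dir1 <- tempfile("phantom")
  man <- emit_dataset(roster, dir1, config = phantom_image_config(image_size = 64))
  expect_equal(nrow(man), 4)
  expect_equal(length(list.files(file.path(dir1, "images"))), 4)
  expect_equal(length(list.files(file.path(dir1, "labels"))), 4)
  expect_true(file.exists(file.path(dir1, "roster.csv")))
  expect_true(file.exists(file.path(dir1, "manifest.json")))

  # box coordinates round-trip exactly through the YOLO writer/reader
  ann <- read_annotations(file.path(dir1, man$annotation[1]), image_size = 64)
  csv <- read.csv(file.path(dir1, "annotations.csv"))
  ref <- csv[csv$image == man$image[1], c("x_min", "y_min", "width", "height")]
  expect_equal(unlist(ann[, c("x_min", "y_min", "width", "height")]),
               unlist(ref), tolerance = 1e-8, ignore_attr = TRUE)

  # identical re-run gives identical image checksums
  dir2 <- tempfile("phantom")
  man2 <- emit_dataset(roster, dir2, config = phantom_image_config(image_size = 64))
  expect_identical(man$md5, man2$md5)

  roster2 <- roster
  roster2$case_id <- rep("dup", 2)
  expect_error(emit_dataset(roster2, tempfile()), "duplicate")
})
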
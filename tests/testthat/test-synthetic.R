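# synthetic image generator: textures, scenes, datasets

test_that("class textures are deterministic and validate their inputs", {
  a <- gen_class_texture("dense", c(64, 64), seed = 0)
  b <- gen_class_texture("dense", c(64, 64), seed = 0)
  expect_identical(a, b)
  expect_false(identical(a, gen_class_texture("dense", c(64, 64), seed = 1)))
  expect_true(all(a >= 0 & a <= 1))
  expect_error(gen_class_texture("dense", c(4, 4), seed = 0),
               class = "ipb_invalid_argument")
  expect_error(gen_class_texture("blob", c(64, 64), seed = 0),
               class = "ipb_invalid_argument")
})

test_that("texture statistic separates all four classes over 100 seeds", {
  stats <- sapply(ipb_classes(), function(cl)
    sapply(1:100, function(s)
      texture_stat(gen_class_texture(cl, c(64, 64), seed = s))))
  # statistic bands must not overlap between adjacent classes, with margin
  ord <- order(colMeans(stats))
  for (i in 1:3) {
    lo <- stats[, ord[i]]; hi <- stats[, ord[i + 1]]
    expect_gt(min(hi), max(lo) * 1.5)
  }
  # debris and dense differ by far more than the adjacent-band margin
  expect_gt(min(stats[, "debris"]), max(stats[, "dense"]) * 5)
})

test_that("nearest-centroid classifier on the statistic exceeds 90%", {
  train <- sapply(ipb_classes(), function(cl)
    sapply(1:20, function(s)
      texture_stat(gen_class_texture(cl, c(64, 64), seed = s))))
  cent <- colMeans(train)
  test <- sapply(ipb_classes(), function(cl)
    sapply(101:200, function(s)
      texture_stat(gen_class_texture(cl, c(64, 64), seed = s))))
  pred <- apply(test, 2, function(col)
    sapply(col, function(v) names(which.min(abs(cent - v)))))
  expect_gt(mean(pred == rep(colnames(test), each = 100)), 0.9)
})

test_that("gen_scene renders descriptors onto the canvas", {
  empty <- gen_scene(scene_spec(c(40, 40)), seed = 1)
  expect_true(all(empty$label_mask == 0L))
  expect_true(all(abs(empty$image - 0.85) < 0.1))

  one <- gen_scene(scene_spec(
    c(64, 64), list(list(class = 3, center = c(32, 32), radius = 20))),
    seed = 2)
  expect_setequal(unique(as.vector(one$label_mask)), c(0L, 3L))
  comps <- label_components(one$label_mask > 0)
  expect_equal(max(comps), 1L)

  two <- gen_scene(scene_spec(
    c(80, 140),
    list(list(class = 1, center = c(40, 40), radius = 20),
         list(class = 2, center = c(40, 100), radius = 20))), seed = 3)
  expect_setequal(sort(unique(as.vector(two$label_mask))), c(0L, 1L, 2L))
  # pixel counts match the analytic disk area within rasterisation error
  for (cl in 1:2) {
    expect_lt(abs(sum(two$label_mask == cl) - pi * 20^2), 0.05 * pi * 20^2)
  }

  expect_error(scene_spec(c(30, 30), list(list(class = 1,
                                               center = c(5, 5),
                                               radius = 10))),
               class = "ipb_invalid_argument")
})

test_that("gen_dataset honours counts exactly and is deterministic", {
  small_range <- list(min = c(55, 85), max = c(80, 120))
  d1 <- withr::local_tempdir()
  man <- gen_dataset(c(dense = 2, spread = 1), 0, d1, seed = 5,
                     size_range = small_range)
  expect_equal(nrow(man), 3L)
  cc <- manifest_counts(man)
  expect_equal(cc$dense, 2L)
  expect_equal(cc$spread, 1L)
  expect_equal(sum(unlist(cc)), nrow(man))
  expect_true(all(file.exists(man$path)))
  # multi-label records never carry a single-class label
  expect_false(any(man$label == "multilabel" & man$label %in% ipb_classes()))

  # determinism: same counts and seed give identical manifests and pixels
  d2 <- withr::local_tempdir()
  man2 <- gen_dataset(c(dense = 2, spread = 1), 0, d2, seed = 5,
                      size_range = small_range)
  expect_equal(man$height, man2$height)
  expect_equal(man$width, man2$width)
  expect_identical(read_pgm(man$path[1]), read_pgm(man2$path[1]))

  d3 <- withr::local_tempdir()
  man0 <- gen_dataset(c(), 0, d3, seed = 1)
  expect_equal(nrow(man0), 0L)
  expect_length(list.files(d3, pattern = "pgm$"), 0L)
})

test_that("scaled real-dataset composition generates with exact counts", {
  # published per-class sizes scaled by 1/100 (rounded) for test runtime
  counts <- c(debris = 36, dense = 39, diff = 7, spread = 105)
  d <- withr::local_tempdir()
  man <- gen_dataset(counts, 27, d, seed = 9,
                     size_range = list(min = c(55, 85), max = c(96, 150)))
  expect_equal(nrow(man), sum(counts) + 27)
  cc <- manifest_counts(man)
  expect_equal(cc$multilabel, 27L)
  expect_equal(cc$diff, 7L)
  # every record's file exists and dimensions in manifest match the pixels
  i <- which.max(man$height)
  img <- read_pgm(man$path[i])
  expect_equal(dim(img), c(man$height[i], man$width[i]))
})

test_that("manifests round-trip through CSV", {
  d <- withr::local_tempdir()
  man <- gen_dataset(c(diff = 2), 1, d, seed = 2,
                     size_range = list(min = c(55, 85), max = c(60, 95)))
  man2 <- read_manifest(file.path(d, "manifest.csv"))
  expect_equal(as.data.frame(man), as.data.frame(man2))
  expect_equal(manifest_counts(man), manifest_counts(man2))
})

test_that("pgm files round-trip in both flavours", {
  x <- gen_class_texture("debris", c(20, 30), seed = 1)
  q <- round(x * 255) / 255  # 8-bit quantisation
  f1 <- withr::local_tempfile(fileext = ".pgm")
  f2 <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(x, f1, format = "raw")
  write_pgm(x, f2, format = "ascii")
  expect_equal(read_pgm(f1), q, tolerance = 1e-12)
  expect_equal(read_pgm(f2), q, tolerance = 1e-12)
  m <- x > 0.5
  f3 <- withr::local_tempfile(fileext = ".pgm")
  write_mask_pgm(m, f3)
  expect_equal(read_pgm(f3) > 0.5, m)
})
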
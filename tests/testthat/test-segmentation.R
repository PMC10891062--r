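# six-step colony segmentation and ROI extraction

test_that("degenerate inputs give empty foreground", {
  expect_false(any(binarize_colonies(matrix(0.5, 64, 64))))
  expect_error(binarize_colonies(array(0.5, c(4, 4, 2))),
               class = "ipb_invalid_argument")
  expect_true(is.infinite(otsu_threshold(matrix(1, 10, 10))))
})

test_that("a textured disk is recovered with high IoU", {
  sc <- gen_scene(scene_spec(
    c(200, 200), list(list(class = "dense", center = c(100, 100),
                           radius = 50))), seed = 3)
  fg <- binarize_colonies(sc$image)
  expect_equal(max(label_components(fg)), 1L)
  truth <- sc$label_mask > 0
  iou <- sum(fg & truth) / sum(fg | truth)
  expect_gt(iou, 0.7)
})

test_that("objects under the 2000 px filter size are removed", {
  r_small <- sqrt(1500 / pi)
  sc <- gen_scene(scene_spec(
    c(150, 150), list(list(class = "debris", center = c(75, 75),
                           radius = r_small))), seed = 4)
  expect_lt(sum(sc$label_mask > 0), 2000)
  expect_false(any(binarize_colonies(sc$image)))
  # the same object survives a lower threshold: the filter is the cause
  p <- seg_params(min_area = 500)
  expect_gt(sum(binarize_colonies(sc$image, p)), 0)
})

test_that("small-object threshold is monotone in ROI count", {
  sc <- gen_scene(scene_spec(
    c(220, 120),
    list(list(class = "dense", center = c(60, 60), radius = 45),
         list(class = "debris", center = c(165, 60), radius = 30))),
    seed = 8)
  counts <- sapply(c(200, 1500, 3000, 7000), function(a) {
    max(label_components(binarize_colonies(sc$image,
                                           seg_params(min_area = a))))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("re-binarising the masked foreground stays within the mask", {
  sc <- gen_scene(scene_spec(
    c(160, 160), list(list(class = "diff", center = c(80, 80),
                           radius = 50))), seed = 5)
  fg <- binarize_colonies(sc$image)
  masked <- sc$image
  masked[!fg] <- 0
  fg2 <- binarize_colonies(masked)
  # subset up to the structuring-element halo introduced by re-opening
  halo <- binary_dilate(fg, 3L)
  expect_true(all(!fg2 | halo))
})

test_that("extract_rois returns sorted, tight, area-consistent ROIs", {
  img <- matrix(0.5, 60, 90)
  bm <- matrix(FALSE, 60, 90)
  bm[31:55, 61:80] <- TRUE            # 25x20 = 500 px, lower-right
  bm[6:25, 6:30] <- TRUE              # 20x25 = 500 px, upper-left
  rois <- extract_rois(bm, img)
  expect_length(rois, 2L)
  # sorted by (row0, col0)
  expect_equal(rois[[1]]$bbox, c(5L, 5L, 25L, 30L))
  expect_equal(rois[[2]]$bbox, c(30L, 60L, 55L, 80L))
  expect_equal(rois[[1]]$area, 500L)
  expect_equal(rois[[2]]$area, 500L)
  for (r in rois) {
    expect_equal(sum(r$mask), r$area)                 # area invariant
    expect_equal(dim(r$mask),
                 c(r$bbox[3] - r$bbox[1], r$bbox[4] - r$bbox[2]))
    expect_true(any(r$mask[1, ]) && any(r$mask[nrow(r$mask), ]) &&
                  any(r$mask[, 1]) && any(r$mask[, ncol(r$mask)]))  # tight
  }
  expect_length(extract_rois(matrix(FALSE, 5, 5), matrix(0, 5, 5)), 0L)
  expect_error(extract_rois(matrix(FALSE, 5, 5), matrix(0, 6, 5)),
               class = "ipb_invalid_argument")
})

test_that("component labelling agrees with the igraph oracle", {
  skip_if_not_installed("igraph")
  for (s in 1:50) {
    m <- random_blob_mask(s)
    expect_equal(max(label_components(m, 8L)),
                 igraph_component_count(m, 8L), label = paste("seed", s))
  }
  # 4-connectivity agrees too on a few cases
  for (s in 1:5) {
    m <- random_blob_mask(s + 100)
    expect_equal(max(label_components(m, 4L)),
                 igraph_component_count(m, 4L))
  }
})

test_that("every ROI map is a subset of the whole-image foreground", {
  sc <- gen_scene(scene_spec(
    c(220, 120),
    list(list(class = "dense", center = c(60, 60), radius = 45),
         list(class = "spread", center = c(165, 60), radius = 40))),
    seed = 11)
  fg <- binarize_colonies(sc$image)
  rois <- extract_rois(fg, sc$image)
  for (r in rois) {
    sub <- fg[(r$bbox[1] + 1):r$bbox[3], (r$bbox[2] + 1):r$bbox[4]]
    expect_true(all(!r$mask | sub))
  }
})

test_that("hole filling and opening behave on constructed masks", {
  m <- matrix(FALSE, 30, 30)
  m[5:25, 5:25] <- TRUE
  m[12:18, 12:18] <- FALSE            # a hole
  expect_true(all(fill_holes(m)[12:18, 12:18]))
  # border-touching background is not a hole
  m2 <- matrix(FALSE, 30, 30); m2[1:15, 5:25] <- TRUE
  expect_equal(fill_holes(m2), m2)
  # opening removes a 1-px spur but keeps a fat square
  m3 <- matrix(FALSE, 30, 30); m3[10:20, 10:20] <- TRUE; m3[5, 15] <- TRUE
  op <- binary_opening(m3, 2L)
  expect_false(op[5, 15])
  expect_true(all(op[12:18, 12:18]))
})
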
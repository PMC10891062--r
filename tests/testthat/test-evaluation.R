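# splits, budgets, scoring, fold comparison

fake_manifest <- function(per_class, multilabel = 0L) {
  labs <- c(rep(ipb_classes(), each = per_class),
            rep("multilabel", multilabel))
  ipbalance:::new_manifest(data.frame(
    image_id = sprintf("im%04d", seq_along(labs)),
    path = sprintf("im%04d.pgm", seq_along(labs)),
    label = labs, height = 64L, width = 64L, stringsAsFactors = FALSE))
}

test_that("80:10:10 stratified split has the expected block sizes", {
  man <- fake_manifest(100)
  sp <- make_splits(man, fold = 0, seed = 4)
  df <- as.data.frame(man)
  for (cl in ipb_classes()) {
    ids <- df$image_id[df$label == cl]
    expect_equal(sum(sp$labeled %in% ids), 10L)
    expect_equal(sum(sp$test %in% ids), 10L)
    expect_equal(sum(sp$unlabeled %in% ids), 80L)
  }
})

test_that("folds rotate disjoint test blocks; multilabel stays in U", {
  man <- fake_manifest(40, multilabel = 7L)
  sp0 <- make_splits(man, fold = 0, seed = 9)
  sp1 <- make_splits(man, fold = 1, seed = 9)
  expect_length(intersect(sp0$test, sp1$test), 0L)
  df <- as.data.frame(man)
  ml <- df$image_id[df$label == "multilabel"]
  expect_true(all(ml %in% sp0$unlabeled))
  expect_length(intersect(ml, c(sp0$labeled, sp0$test)), 0L)
})

test_that("split partitions satisfy set algebra on random manifests", {
  set.seed(5)
  for (i in 1:20) {
    per <- sample(10:40, 1)
    ml <- sample(0:10, 1)
    man <- fake_manifest(per, ml)
    sp <- make_splits(man, fold = sample(0:9, 1), seed = i)
    all_ids <- as.data.frame(man)$image_id
    got <- c(sp$unlabeled, sp$labeled, sp$test)
    expect_length(got, length(all_ids))          # partition: no loss
    expect_setequal(got, all_ids)
    expect_length(intersect(sp$unlabeled, sp$labeled), 0L)
    expect_length(intersect(sp$unlabeled, sp$test), 0L)
    expect_length(intersect(sp$labeled, sp$test), 0L)
  }
})

test_that("classes with fewer records than folds are rejected", {
  man <- fake_manifest(5)   # 5 < 10 folds
  expect_error(make_splits(man, fold = 0, seed = 1),
               class = "ipb_invalid_argument")
})

test_that("labeled budgets reproduce the published 50% and 80% counts", {
  n_single <- 21342 - 2659            # single-class records
  expect_equal(n_single, 18683)
  expect_equal(labeled_budget(0.5, n_single), 9341L)
  expect_equal(labeled_budget(0.8, n_single), 14946L)
  expect_equal(labeled_budget(1.0, 1234), 1234L)
  expect_equal(labeled_budget(0.01, n_single), 186L)  # floor convention
  expect_error(labeled_budget(0, 10), class = "ipb_invalid_argument")
})

test_that("published confusion matrix yields the derived TPR and F1", {
  # rows = predicted, columns = actual; order Debris, Dense, Diff, Spread
  C <- rbind(c(301, 18, 2, 37),
             c(11, 326, 0, 56),
             c(1, 0, 66, 22),
             c(32, 39, 6, 973))
  met <- metrics_from_confusion(C)
  expect_equal(met$tpr[1], 301 / (301 + 11 + 1 + 32), tolerance = 1e-12)
  expect_equal(met$tpr[1], 0.8725, tolerance = 5e-5)
  expect_equal(met$f1[1], 2 * 301 / (2 * 301 + 57 + 44), tolerance = 1e-12)
  expect_equal(met$f1[1], 0.8563, tolerance = 5e-5)
  # column sums equal per-class actual counts; trace / total = accuracy
  expect_equal(colSums(C), met$tp + met$fn, ignore_attr = TRUE)
  expect_equal(met$accuracy, sum(diag(C)) / sum(C))
})

test_that("score handles perfect, empty-class and invalid inputs", {
  met <- score(c(1, 2, 3, 4), c(1, 2, 3, 4), m = 4)
  expect_equal(met$tpr, rep(1, 4))
  expect_equal(met$f1, rep(1, 4))
  # class absent from labels and predictions -> undefined, excluded
  met2 <- score(c(1, 1, 2), c(1, 2, 2), m = 4)
  expect_true(all(met2$undefined[3:4]))
  expect_equal(met2$macro_tpr, mean(c(1, 0.5)))
  expect_error(score(c(1, 5), c(1, 2), m = 4),
               class = "ipb_invalid_argument")
  expect_error(score(1:3, 1:2, m = 4), class = "ipb_invalid_argument")
})

test_that("one-vs-rest F1 equals the harmonic mean of precision/recall", {
  set.seed(8)
  preds <- sample(1:4, 200, replace = TRUE)
  labels <- sample(1:4, 200, replace = TRUE)
  met <- score(preds, labels, m = 4)
  for (cl in 1:4) {
    tp <- sum(preds == cl & labels == cl)
    prec <- tp / sum(preds == cl)
    rec <- tp / sum(labels == cl)
    hm <- 2 * prec * rec / (prec + rec)
    if (!is.nan(hm)) expect_equal(met$f1[cl], hm, tolerance = 1e-12)
  }
})

test_that("compare_folds matches the closed-form pooled t statistic", {
  a <- c(0.81, 0.84, 0.80, 0.86, 0.83)
  b <- c(0.78, 0.80, 0.77, 0.79, 0.81)
  res <- compare_folds(a, b)
  or <- stats::t.test(a, b, var.equal = TRUE)   # independent oracle
  expect_equal(res$t, unname(or$statistic), tolerance = 1e-12)
  expect_equal(res$p, or$p.value, tolerance = 1e-12)
  expect_equal(res$df, unname(or$parameter))

  same <- compare_folds(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  shifted <- compare_folds(c(2, 2, 2), c(1, 1, 1))
  expect_true(shifted$degenerate)
  expect_true(is.infinite(shifted$t))

  expect_error(compare_folds(1, 1:3), class = "ipb_invalid_argument")
})

test_that("predictions with a zeroed head collapse to class 1", {
  m <- build_model(arch_config("tiny_test"), seed = 4)
  last <- sprintf("fc%d", length(m$cfg$head))
  m$layers[[last]]$W[] <- 0; m$layers[[last]]$b[] <- 0
  te <- class_images(2)
  task <- make_patch_task(te$images, te$labels, patch_size = 32,
                          augment = FALSE)
  preds <- predict_images(m, task)
  expect_true(all(preds$pred == 1L))
  # duplicate image -> identical prediction (eval determinism)
  task2 <- make_patch_task(te$images[c(1, 1)], c(1L, 1L), patch_size = 32,
                           augment = FALSE)
  p2 <- predict_images(trained_tiny_model(), task2)
  expect_equal(p2$pred[1], p2$pred[2])
})
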
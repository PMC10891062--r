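# Splitting, prediction and metrics.
#
# Records are split 80:10:10 into unlabeled-training (U), labeled-training
# (L) and testing (T) sets, stratified per class, with the test block
# rotating across folds for cross-validation.  Multi-label records can
# only ever be unlabeled, so they always go to U.  Classification quality
# is reported per class as the true positive rate TPR = TP / (TP + FN)
# and the F1 score F1 = 2TP / (2TP + FP + FN).

#' Stratified train/label/test split
#'
#' @param manifest An `ipb_manifest` (or data.frame with `image_id`,
#'   `label`).
#' @param fractions `(U, L, T)` fractions summing to 1 (default
#'   80:10:10).
#' @param fold Fold index (0-based); rotates which block of each class
#'   becomes the test set, with the labeled block immediately after it.
#' @param seed Integer seed for the per-class shuffles (fold-independent,
#'   so different folds of one seed have disjoint test blocks).
#' @param include_multilabel Keep multi-label records (in U) or drop them.
#' @return An `ipb_split`: list of `image_id` vectors `unlabeled`,
#'   `labeled`, `test`, plus `fold` and `fractions`.
#' @export
make_splits <- function(manifest, fractions = c(0.8, 0.1, 0.1), fold = 0L,
                        seed = 1L, include_multilabel = TRUE) {
  if (abs(sum(fractions) - 1) > 1e-9)
    invalid_argument("fractions must sum to 1")
  if (length(fractions) != 3 || any(fractions <= 0))
    invalid_argument("fractions must be three positive numbers")
  df <- as.data.frame(manifest)
  nfolds <- as.integer(round(1 / fractions[3]))
  single <- df[df$label %in% IPB_CLASSES, , drop = FALSE]
  ml <- df[df$label == IPB_MULTILABEL, , drop = FALSE]
  u <- character(0); l <- character(0); tt <- character(0)
  for (cl in intersect(IPB_CLASSES, unique(single$label))) {
    ids <- single$image_id[single$label == cl]
    if (length(ids) < nfolds)
      invalid_argument(sprintf(
        "class %s has %d records, fewer than %d folds", cl, length(ids),
        nfolds))
    ids <- with_seed(derive_seed(seed, paste0("split_", cl)),
                     sample(ids))
    # block boundaries: nfolds equal-ish blocks; test = block `fold`,
    # labeled = the next block (cyclically), unlabeled = the rest
    blocks <- split(ids, (seq_along(ids) - 1L) %% nfolds)
    ti <- (fold %% nfolds) + 1L
    li <- ((fold + 1L) %% nfolds) + 1L
    # labeled block size follows the labeled fraction (may span blocks)
    n_lab_blocks <- max(1L, round(fractions[2] * nfolds))
    lis <- ((fold + seq_len(n_lab_blocks)) %% nfolds) + 1L
    tt <- c(tt, blocks[[ti]])
    l <- c(l, unlist(blocks[lis], use.names = FALSE))
    u <- c(u, unlist(blocks[setdiff(seq_len(nfolds), c(ti, lis))],
                     use.names = FALSE))
  }
  if (include_multilabel) u <- c(u, ml$image_id)
  structure(list(unlabeled = u, labeled = l, test = tt,
                 fold = as.integer(fold), fractions = fractions),
            class = "ipb_split")
}

#' Labeled-data budget
#'
#' Number of labeled images available at a given fraction of the
#' single-class record count: `floor(fraction * n_single_class)`.
#'
#' @param fraction Fraction in (0, 1].
#' @param n_single_class Number of single-class records.
#' @return Integer budget.
#' @export
labeled_budget <- function(fraction, n_single_class) {
  if (fraction <= 0 || fraction > 1)
    invalid_argument("fraction must be in (0, 1]")
  as.integer(floor(fraction * n_single_class))
}

#' Predict classes for a test task
#'
#' One deterministic in-mask patch per image (mask-bbox-centred, no
#' augmentation; centre-patch fallback for unsegmentable images),
#' prediction by argmax softmax with lowest-index tie-break.
#'
#' @param student A trained `ipb_model`.
#' @param task An `ipb_task`.
#' @return data.frame with `image_id` and integer `pred`.
#' @export
predict_images <- function(student, task) {
  patches <- task_eval_patches(task)
  probs <- forward_probs(student, patches)
  data.frame(image_id = task$image_ids,
             pred = max.col(probs, ties.method = "first"))
}

#' Per-class TPR/F1 metrics from predictions
#'
#' Builds the `m x m` confusion matrix `C[pred, actual]` and reports
#' per-class true positive rate `TP / (TP + FN)` and F1 score
#' `2TP / (2TP + FP + FN)`, with unweighted macro averages.  Classes
#' absent from the denominators are reported `NaN` and excluded from the
#' macro average (flagged in `undefined`).
#'
#' @param preds Integer predicted classes (1..m).
#' @param labels Integer actual classes (1..m).
#' @param m Number of classes.
#' @return An `ipb_metrics`: list with `confusion`, `tp`, `fp`, `fn`,
#'   `tpr`, `f1`, `macro_tpr`, `macro_f1`, `accuracy`, `undefined`.
#' @export
score <- function(preds, labels, m = 4L) {
  if (length(preds) != length(labels))
    invalid_argument("preds and labels must align")
  if (any(!labels %in% seq_len(m)) || any(!preds %in% seq_len(m)))
    invalid_argument("labels outside 1..m")
  C <- matrix(0L, m, m, dimnames = list(pred = NULL, actual = NULL))
  for (i in seq_along(preds)) C[preds[i], labels[i]] <- C[preds[i], labels[i]] + 1L
  metrics_from_confusion(C)
}

#' Metrics from a confusion matrix
#'
#' @param C `m x m` count matrix, rows = predicted, columns = actual.
#' @return An `ipb_metrics` (see [score()]).
#' @export
metrics_from_confusion <- function(C) {
  m <- nrow(C)
  tp <- diag(C)
  fn <- colSums(C) - tp
  fp <- rowSums(C) - tp
  tpr <- ifelse(tp + fn > 0, tp / (tp + fn), NaN)
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), NaN)
  undefined <- is.nan(tpr) | is.nan(f1)
  structure(list(confusion = C, tp = tp, fp = fp, fn = fn, tpr = tpr,
                 f1 = f1, macro_tpr = mean(tpr[!is.nan(tpr)]),
                 macro_f1 = mean(f1[!is.nan(f1)]),
                 accuracy = sum(tp) / sum(C), undefined = undefined),
            class = "ipb_metrics")
}

#' Compare per-fold metrics between two arms
#'
#' Classic (pooled-variance) two-sample Student t test at the 95% level,
#' the convention used for the published significance statements.  Lists
#' with zero pooled variance are flagged as degenerate: `t` is 0 with
#' `p = 1` when the means agree, and infinite with `p = 0` otherwise.
#'
#' @param a,b Numeric vectors of per-fold metric values (>= 2 folds each,
#'   equal lengths).
#' @return List with `mean_a`, `mean_b`, `sd_a`, `sd_b`, `t`, `df`, `p`,
#'   `significant` (p < 0.05), `degenerate`.
#' @export
compare_folds <- function(a, b) {
  if (length(a) < 2 || length(b) < 2 || length(a) != length(b))
    invalid_argument("need equal fold counts of at least 2 per arm")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  d <- mean(a) - mean(b)
  degenerate <- sp2 <= 0
  if (degenerate) {
    tstat <- if (abs(d) < 1e-15) 0 else sign(d) * Inf
    p <- if (tstat == 0) 1 else 0
  } else {
    tstat <- d / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
  }
  list(mean_a = mean(a), mean_b = mean(b), sd_a = stats::sd(a),
       sd_b = stats::sd(b), t = tstat, df = na + nb - 2, p = p,
       significant = p < 0.05, degenerate = degenerate)
}
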
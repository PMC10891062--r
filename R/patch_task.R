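# Patch tasks: the dataset abstraction the training loop consumes.
#
# A task owns a list of images (with optional foreground masks and
# labels) and knows how to produce one training patch per image per epoch
# (random in-mask location + augmentation) and one deterministic
# evaluation patch per image (mask-centred, unaugmented).  Tasks can be
# built from in-memory matrices (tests, scaled-down runs) or from a
# manifest on disk (full pipeline).

#' Build a patch task from in-memory images
#'
#' @param images List of numeric matrices in `[0,1]`.
#' @param labels Optional integer class codes (1..m); `NA`/`NULL` for
#'   unlabeled tasks.
#' @param masks Optional list of logical foreground masks (default: whole
#'   image is foreground).
#' @param scale_mode `"dual224_112"` or `"single128"`.
#' @param patch_size Coarse patch side.
#' @param min_coverage,max_trials In-mask sampling parameters, see
#'   [sample_patch_location()].
#' @param augment Whether training patches are augmented.
#' @param augment_prob Per-transform probability.
#' @param image_ids Optional identifiers (default `img_<i>`).
#' @return An object of class `ipb_task`.
#' @export
make_patch_task <- function(images, labels = NULL, masks = NULL,
                            scale_mode = "dual224_112", patch_size = 32L,
                            min_coverage = 0.5, max_trials = 50L,
                            augment = TRUE, augment_prob = 0.25,
                            image_ids = NULL) {
  n <- length(images)
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  if (is.null(image_ids)) image_ids <- sprintf("img_%05d", seq_len(n))
  structure(list(n = n, images = images, masks = masks,
                 labels = as.integer(labels), image_ids = image_ids,
                 scale_mode = scale_mode, patch_size = as.integer(patch_size),
                 min_coverage = min_coverage, max_trials = as.integer(max_trials),
                 augment = augment, augment_prob = augment_prob,
                 fallback_log = new.env(parent = emptyenv())),
            class = "ipb_task")
}

#' Build a patch task from a dataset manifest
#'
#' Reads each image, segments the colony foreground with
#' [binarize_colonies()], and keeps the mask for in-mask sampling.
#'
#' @param manifest An `ipb_manifest`.
#' @param ids Optional subset of `image_id`s.
#' @param seg An [seg_params()] object.
#' @param ... Passed to [make_patch_task()].
#' @return An `ipb_task`.
#' @export
make_patch_task_from_manifest <- function(manifest, ids = NULL,
                                          seg = seg_params(), ...) {
  df <- as.data.frame(manifest)
  if (!is.null(ids)) df <- df[match(ids, df$image_id), , drop = FALSE]
  images <- lapply(df$path, read_pgm)
  masks <- lapply(images, binarize_colonies, params = seg)
  labels <- ifelse(df$label %in% IPB_CLASSES,
                   match(df$label, IPB_CLASSES), NA_integer_)
  make_patch_task(images, labels = labels, masks = masks,
                  image_ids = df$image_id, ...)
}

task_image_mask <- function(task, i) {
  img <- task$images[[i]]
  mask <- if (is.null(task$masks)) {
    matrix(TRUE, nrow(img), ncol(img))
  } else task$masks[[i]]
  # too-small images trigger the resize normalisation (image and mask)
  if (min(dim(img)) < task$patch_size) {
    img <- normalize_resize(img, task$patch_size)
    mask <- bilinear_resize(matrix(as.numeric(mask), nrow = nrow(mask)),
                            nrow(img), ncol(img)) >= 0.5
  }
  list(image = img, mask = mask)
}

# one random in-mask training patch (augmented if the task says so);
# draws from the current RNG stream
task_patch <- function(task, i, augment = task$augment) {
  im <- task_image_mask(task, i)
  if (!any(im$mask)) {
    anchor <- pmax(0L, round((dim(im$image) - task$patch_size) / 2))
    task$fallback_log$empty_mask <- c(task$fallback_log$empty_mask, i)
  } else {
    loc <- sample_patch_location(list(mask = im$mask), task$patch_size,
                                 task$min_coverage, task$max_trials)
    if (loc$fallback)
      task$fallback_log$coverage <- c(task$fallback_log$coverage, i)
    anchor <- c(loc$row, loc$col)
  }
  p <- extract_multiscale(im$image, anchor, task$scale_mode,
                          task$patch_size, image_id = task$image_ids[i])
  if (augment) p <- augment_patch(p, prob = task$augment_prob)
  p
}

# deterministic evaluation patch: anchored at the centre of the mask
# bounding box (image centre if the mask is empty), never augmented
task_eval_patch <- function(task, i) {
  im <- task_image_mask(task, i)
  h <- nrow(im$image); w <- ncol(im$image); ps <- task$patch_size
  if (any(im$mask)) {
    idx <- which(im$mask, arr.ind = TRUE)
    ctr <- c(mean(range(idx[, 1])), mean(range(idx[, 2])))
  } else {
    ctr <- c((h + 1) / 2, (w + 1) / 2)
    task$fallback_log$empty_mask_eval <-
      c(task$fallback_log$empty_mask_eval, i)
  }
  anchor <- round(ctr - (ps + 1) / 2)
  anchor <- pmin(pmax(anchor, 0), c(h, w) - ps)
  extract_multiscale(im$image, anchor, task$scale_mode, ps,
                     image_id = task$image_ids[i])
}

# patches for a vector of record indices
task_patches <- function(task, idx, augment = task$augment) {
  lapply(idx, function(i) task_patch(task, i, augment = augment))
}

task_eval_patches <- function(task, idx = seq_len(task$n)) {
  lapply(idx, function(i) task_eval_patch(task, i))
}
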
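# Colony detection.
#
# Colonies are segmented from the bright background with a six-step
# morphological pipeline applied in this order: (1) 3x3 Gaussian blur,
# (2) local entropy filter with a disk of radius 3, (3) Otsu global
# threshold of the rescaled entropy map, (4) morphological opening with a
# disk of radius 3, (5) binary hole filling, (6) removal of objects
# smaller than 2000 pixels.  Textured colony area has high local entropy;
# flat background does not, so entropy + Otsu separates them without any
# intensity calibration.

#' Segmentation parameters
#'
#' @param blur_kernel Gaussian kernel size; only the standard 3 is
#'   supported (kept as an explicit parameter for config round-trips).
#' @param disk_radius Disk radius for the entropy filter and opening.
#' @param min_area Small-object removal threshold in pixels.
#' @param entropy_bins Gray-level bins for the entropy filter.
#' @return An object of class `ipb_seg_params`.
#' @export
seg_params <- function(blur_kernel = 3L, disk_radius = 3L,
                       min_area = 2000L, entropy_bins = 64L) {
  if (blur_kernel != 3L)
    invalid_argument("only the 3x3 blur kernel is supported")
  structure(list(blur_kernel = 3L, disk_radius = as.integer(disk_radius),
                 min_area = as.integer(min_area),
                 entropy_bins = as.integer(entropy_bins)),
            class = "ipb_seg_params")
}

#' Binarise colony foreground
#'
#' Runs the six-step morphological segmentation pipeline.  Deterministic;
#' a constant (texture-free) image yields an all-false map because the
#' degenerate entropy histogram is treated as empty foreground.
#'
#' @param image Numeric matrix in `[0,1]`.
#' @param params An [seg_params()] object.
#' @return Logical matrix; every connected component has at least
#'   `params$min_area` pixels.
#' @export
binarize_colonies <- function(image, params = seg_params()) {
  if (!is.matrix(image)) invalid_argument("`image` must be a 2-D matrix")
  assert_image(image)
  x <- gaussian_blur3(image)
  ent <- entropy_filter(x, radius = params$disk_radius,
                        nbins = params$entropy_bins)
  rng <- range(ent)
  if (diff(rng) < 1e-9)
    return(matrix(FALSE, nrow(image), ncol(image)))
  ent <- (ent - rng[1]) / diff(rng)   # rescale to [0,1] before Otsu
  thr <- otsu_threshold(ent)
  if (!is.finite(thr)) return(matrix(FALSE, nrow(image), ncol(image)))
  fg <- ent > thr
  fg <- binary_opening(fg, params$disk_radius)
  fg <- fill_holes(fg)
  remove_small_objects(fg, params$min_area, connectivity = 8L)
}

#' Colony region of interest
#'
#' Constructor for one detected colony: a bbox-local binary map plus the
#' tight bounding box within the source image.  Boxes are 0-based,
#' half-open `(row0, col0, row1, col1)`, the convention used by every
#' external interface of this package.
#'
#' @param mask Logical matrix covering the bbox (colony pixels `TRUE`).
#' @param bbox Integer `(row0, col0, row1, col1)`, 0-based half-open.
#' @param image Optional image crop of the same size as `mask`.
#' @return An object of class `ipb_roi` with fields `mask`, `bbox`,
#'   `area` and optionally `image`.
#' @export
colony_roi <- function(mask, bbox, image = NULL) {
  stopifnot(is.logical(mask), length(bbox) == 4)
  bbox <- as.integer(bbox)
  if (nrow(mask) != bbox[3] - bbox[1] || ncol(mask) != bbox[4] - bbox[2])
    invalid_argument("bbox does not match mask dimensions")
  structure(list(mask = mask, bbox = bbox, area = sum(mask), image = image),
            class = "ipb_roi")
}

#' Extract colony ROIs from a foreground map
#'
#' One ROI per 8-connected component, each with its tight bounding box and
#' the corresponding image crop.  ROIs are sorted by `(row0, col0)` for
#' determinism.
#'
#' @param binary_map Logical foreground matrix.
#' @param image Numeric image of the same shape.
#' @return List of [colony_roi()] objects.
#' @export
extract_rois <- function(binary_map, image) {
  if (!is.matrix(binary_map) || !is.logical(binary_map))
    invalid_argument("`binary_map` must be a logical matrix")
  if (!all(dim(binary_map) == dim(image)))
    invalid_argument("binary_map and image shapes differ")
  lab <- label_components(binary_map, 8L)
  k <- max(lab)
  if (k == 0L) return(list())
  rois <- lapply(seq_len(k), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    colony_roi(lab[r0:r1, c0:c1, drop = FALSE] == i,
               c(r0 - 1L, c0 - 1L, r1, c1),
               image = image[r0:r1, c0:c1, drop = FALSE])
  })
  ord <- order(vapply(rois, function(r) r$bbox[1], 0),
               vapply(rois, function(r) r$bbox[2], 0))
  rois[ord]
}

#' Write ROI table as CSV
#'
#' Columns `roi_id,row0,col0,row1,col1,area` with 0-based half-open boxes.
#'
#' @param rois List of [colony_roi()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_csv <- function(rois, path) {
  df <- data.frame(
    roi_id = seq_along(rois),
    row0 = vapply(rois, function(r) r$bbox[1], 0L),
    col0 = vapply(rois, function(r) r$bbox[2], 0L),
    row1 = vapply(rois, function(r) r$bbox[3], 0L),
    col1 = vapply(rois, function(r) r$bbox[4], 0L),
    area = vapply(rois, function(r) as.integer(r$area), 0L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
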
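# Synthetic colony scenes: textured colony disks on a bright background,
# with a per-pixel ground-truth class mask.  Multi-label scenes place
# colonies of two or more distinct classes on one canvas, emulating the
# composite colonies that cannot carry an image-level label.

#' Describe a synthetic scene
#'
#' @param canvas Integer `(H, W)` canvas size in pixels.
#' @param colonies List of colony descriptors, each a list with `class`
#'   (label or code 1..4), `center` `(row, col)`, `radius` (px) and
#'   optionally `seed` for the colony texture.
#' @param background Background intensity in `[0,1]` (default 0.85; the
#'   background is bright relative to colony textures, as in
#'   phase-contrast imaging).
#' @param noise_sd Gaussian background noise s.d. (default 0.01).
#' @return An object of class `ipb_scene_spec`.
#' @export
scene_spec <- function(canvas, colonies = list(), background = 0.85,
                       noise_sd = 0.01) {
  canvas <- as.integer(canvas)
  if (length(canvas) != 2 || any(canvas < 1))
    invalid_argument("canvas must be positive (H, W)")
  if (background < 0 || background > 1)
    invalid_argument("background level must be in [0,1]")
  for (col in colonies) {
    if (is.null(col$class) || is.null(col$center) || is.null(col$radius))
      invalid_argument("each colony needs class, center and radius")
    ctr <- col$center; rad <- col$radius
    if (ctr[1] - rad < 1 || ctr[1] + rad > canvas[1] ||
        ctr[2] - rad < 1 || ctr[2] + rad > canvas[2])
      invalid_argument("colony descriptor extends outside the canvas")
  }
  structure(list(canvas = canvas, colonies = colonies,
                 background = background, noise_sd = noise_sd),
            class = "ipb_scene_spec")
}

#' Render a synthetic scene
#'
#' Pixels inside each colony disk carry that class's texture; the label
#' mask carries the class code (background 0).  Overlaps are resolved in
#' descriptor order (later descriptors win).
#'
#' @param spec An [scene_spec()] object.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return List with `image` (matrix in `[0,1]`) and `label_mask`
#'   (integer matrix, 0 = background).
#' @export
gen_scene <- function(spec, seed = NULL) {
  if (!inherits(spec, "ipb_scene_spec"))
    invalid_argument("`spec` must be an ipb_scene_spec")
  render <- function() {
    h <- spec$canvas[1]; w <- spec$canvas[2]
    img <- matrix(clip01(spec$background +
                           stats::rnorm(h * w, 0, spec$noise_sd)), h, w)
    mask <- matrix(0L, h, w)
    for (col in spec$colonies) {
      cid <- if (is.numeric(col$class)) as.integer(col$class)
             else class_to_id(col$class)
      ctr <- col$center; rad <- col$radius
      rr <- max(1L, floor(ctr[1] - rad)):min(h, ceiling(ctr[1] + rad))
      cc <- max(1L, floor(ctr[2] - rad)):min(w, ceiling(ctr[2] + rad))
      inside <- outer((rr - ctr[1])^2, (cc - ctr[2])^2, `+`) <= rad^2
      tex <- gen_class_texture(cid, c(length(rr), length(cc)),
                               seed = col$seed)
      subi <- img[rr, cc, drop = FALSE]
      subm <- mask[rr, cc, drop = FALSE]
      subi[inside] <- tex[inside]
      subm[inside] <- cid
      img[rr, cc] <- subi
      mask[rr, cc] <- subm
    }
    list(image = img, label_mask = mask)
  }
  if (is.null(seed)) render() else with_seed(seed, render())
}

# a standard single-colony (or multi-colony) scene for a given canvas;
# used by gen_dataset and by tests
single_colony_spec <- function(class, h, w, radius_frac = 0.38,
                               background = 0.85) {
  rad <- radius_frac * min(h, w)
  scene_spec(c(h, w),
             list(list(class = class, center = c((h + 1) / 2, (w + 1) / 2),
                       radius = rad)),
             background = background)
}

multilabel_spec <- function(classes, h, w, background = 0.85) {
  stopifnot(length(classes) >= 2)
  k <- length(classes)
  rad <- 0.22 * min(h, w)
  # place colonies on a ring so they fit any canvas aspect
  ang <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  ring <- 0.25 * min(h, w)
  cols <- lapply(seq_len(k), function(i) {
    list(class = classes[i],
         center = c((h + 1) / 2 + ring * sin(ang[i]),
                    (w + 1) / 2 + ring * cos(ang[i])),
         radius = rad)
  })
  scene_spec(c(h, w), cols, background = background)
}
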
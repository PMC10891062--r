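# In-mask patch sampling, multi-scale extraction, and the stochastic
# augmentation stack.
#
# Training patches are drawn inside colony masks so that patches carry
# class-relevant texture rather than background.  The multi-scale input
# pairs a coarse patch (default 224x224, a global view of colony shape)
# with its exact centre crop at half size (112x112, local texture); the
# single-scale alternative is one 128x128 patch.  At the instrument's
# 0.8 um pixel size these correspond to 179.2, 89.6 and 102.4 um fields.

#' Physical extent of a patch side
#'
#' @param pixels Patch side length in pixels.
#' @param pixel_size_um Microns per pixel (default 0.8, the 10x
#'   phase-contrast configuration of the source instrument).
#' @return Extent in microns.
#' @export
patch_extent_um <- function(pixels, pixel_size_um = 0.8) {
  pixels * pixel_size_um
}

#' Sample a patch location inside a colony mask
#'
#' Rejection-samples a `patch_size` window top-left until the window's
#' foreground coverage reaches `min_coverage`, falling back after
#' `max_trials` to the maximum-coverage window seen (flagged, so callers
#' can log the fallback path).
#'
#' @param roi An [colony_roi()] object (or any list with a logical
#'   `mask`).
#' @param patch_size Window side in pixels.
#' @param min_coverage Required foreground fraction (default 0.5).
#' @param max_trials Rejection-sampling budget (default 50).
#' @param seed Optional integer seed.
#' @return List with 0-based `row`, `col` of the window top-left within
#'   the ROI frame, the achieved `coverage`, and `fallback`.
#' @export
sample_patch_location <- function(roi, patch_size, min_coverage = 0.5,
                                  max_trials = 50L, seed = NULL) {
  mask <- roi$mask
  if (is.null(mask) || sum(mask) == 0L)
    degenerate_input("empty ROI: no foreground to sample from")
  h <- nrow(mask); w <- ncol(mask)
  if (h < patch_size || w < patch_size)
    degenerate_input("ROI smaller than patch size; resize first")
  draw <- function() {
    # summed-area table for O(1) window coverage
    sat <- rbind(0, apply(rbind(mask * 1), 2, cumsum))
    sat <- cbind(0, t(apply(sat, 1, cumsum)))
    cov_at <- function(r, c) { # r, c are 1-based top-left
      (sat[r + patch_size, c + patch_size] - sat[r, c + patch_size] -
         sat[r + patch_size, c] + sat[r, c]) / patch_size^2
    }
    best <- list(cov = -1, r = 1L, c = 1L)
    for (t in seq_len(max_trials)) {
      r <- sample.int(h - patch_size + 1L, 1L)
      c <- sample.int(w - patch_size + 1L, 1L)
      cv <- cov_at(r, c)
      if (cv >= min_coverage) {
        return(list(row = r - 1L, col = c - 1L, coverage = cv,
                    fallback = FALSE))
      }
      if (cv > best$cov) best <- list(cov = cv, r = r, c = c)
    }
    list(row = best$r - 1L, col = best$c - 1L, coverage = best$cov,
         fallback = TRUE)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Extract a single- or multi-scale patch
#'
#' In dual mode the fine patch is the exact centre crop of the coarse
#' patch at half its side (`coarse[P/4 + 1 .. 3P/4, P/4 + 1 .. 3P/4]` in
#' 1-based terms), so both views share one anchor.
#'
#' @param image Numeric matrix.
#' @param anchor 0-based `(row, col)` of the patch top-left.
#' @param scale_mode `"dual224_112"` or `"single128"`.
#' @param patch_size Coarse side; defaults to 224 (dual) / 128 (single).
#'   Must be divisible by 4 in dual mode.
#' @param image_id Optional source identifier carried on the patch.
#' @return An object of class `ipb_patch` with fields `coarse`, `fine`
#'   (dual mode only), `anchor`, `scale_mode`, `image_id`.
#' @export
extract_multiscale <- function(image, anchor,
                               scale_mode = c("dual224_112", "single128"),
                               patch_size = NULL, image_id = NA_character_) {
  assert_image(image)
  scale_mode <- match.arg(scale_mode)
  if (is.null(patch_size))
    patch_size <- if (scale_mode == "dual224_112") 224L else 128L
  patch_size <- as.integer(patch_size)
  anchor <- as.integer(anchor)
  if (any(anchor < 0L) || anchor[1] + patch_size > nrow(image) ||
      anchor[2] + patch_size > ncol(image))
    invalid_argument("anchor places the patch outside the image")
  coarse <- image[anchor[1] + seq_len(patch_size),
                  anchor[2] + seq_len(patch_size), drop = FALSE]
  fine <- NULL
  if (scale_mode == "dual224_112") {
    if (patch_size %% 4L != 0L)
      invalid_argument("dual-scale patch size must be divisible by 4")
    q <- patch_size %/% 4L
    fine <- coarse[(q + 1L):(3L * q), (q + 1L):(3L * q), drop = FALSE]
  }
  structure(list(coarse = coarse, fine = fine, anchor = anchor,
                 scale_mode = scale_mode, image_id = image_id),
            class = "ipb_patch")
}

#' Default augmentation magnitude parameters
#' @return Named list of magnitude ranges.
#' @export
augment_params <- function() {
  list(rot_range = c(0, 180),      # degrees
       bc_range = c(0.8, 1.2),     # brightness/contrast jitter factors
       blur_sigma = c(0.3, 1.0))   # Gaussian blur s.d. in pixels
}

# Gaussian blur with arbitrary sigma (separable, replicate-padded)
gaussian_blur_sigma <- function(x, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  xp <- pad_replicate(x, r)
  h <- nrow(x); w <- ncol(x)
  tmp <- matrix(0, h, ncol(xp))
  for (i in -r:r)
    tmp <- tmp + k[i + r + 1] * xp[r + i + seq_len(h), , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in -r:r)
    out <- out + k[j + r + 1] * tmp[, r + j + seq_len(w), drop = FALSE]
  out
}

#' Stochastic patch augmentation
#'
#' Five transforms -- horizontal flip, vertical flip, rotation by
#' U(0, 180) degrees, joint contrast/brightness jitter (factors
#' U(0.8, 1.2), contrast pivots at mid-gray 0.5), and Gaussian blur with
#' sigma U(0.3, 1.0) -- are applied independently, each with probability
#' `prob` (default 0.25).  In dual-scale mode the coarse patch is
#' transformed and the fine patch re-derived as its centre crop, so one
#' transform realisation governs both scales and the centre-crop
#' invariant holds exactly.  Output is clipped to `[0,1]`.
#'
#' @param patch An `ipb_patch` or a plain numeric matrix.
#' @param prob Per-transform application probability.
#' @param params Magnitude ranges, see [augment_params()].
#' @param seed Optional integer seed.
#' @return Augmented patch of the same type; attribute `"applied"` is a
#'   named logical vector of the transforms applied.
#' @export
augment_patch <- function(patch, prob = 0.25, params = augment_params(),
                          seed = NULL) {
  run <- function() {
    x <- if (inherits(patch, "ipb_patch")) patch$coarse else patch
    on <- stats::runif(5) < prob
    names(on) <- c("hflip", "vflip", "rotate", "bright_contrast", "blur")
    if (on["hflip"]) x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
    if (on["vflip"]) x <- x[rev(seq_len(nrow(x))), , drop = FALSE]
    if (on["rotate"]) {
      ang <- stats::runif(1, params$rot_range[1], params$rot_range[2])
      x <- rotate_image(x, ang)
    }
    if (on["bright_contrast"]) {
      fb <- stats::runif(1, params$bc_range[1], params$bc_range[2])
      fc <- stats::runif(1, params$bc_range[1], params$bc_range[2])
      x <- (x * fb - 0.5) * fc + 0.5
    }
    if (on["blur"]) {
      sg <- stats::runif(1, params$blur_sigma[1], params$blur_sigma[2])
      x <- gaussian_blur_sigma(x, sg)
    }
    x <- clip01(x)
    out <- if (inherits(patch, "ipb_patch")) {
      p2 <- patch
      p2$coarse <- x
      if (!is.null(patch$fine)) {
        q <- nrow(x) %/% 4L
        p2$fine <- x[(q + 1L):(3L * q), (q + 1L):(3L * q), drop = FALSE]
      }
      p2
    } else x
    attr(out, "applied") <- on
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
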
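# Geometric image transforms: bilinear resize and rotation.
# Sampling uses pixel-centre alignment; out-of-support samples clamp to
# the nearest edge pixel.

# bilinear sample of matrix x at fractional (r, c) coordinate vectors
bilinear_sample <- function(x, r, c) {
  h <- nrow(x); w <- ncol(x)
  r <- pmin(pmax(r, 1), h); c <- pmin(pmax(c, 1), w)
  r0 <- pmin(floor(r), h - 1L); c0 <- pmin(floor(c), w - 1L)
  if (h == 1L) r0 <- rep(1, length(r))
  if (w == 1L) c0 <- rep(1, length(c))
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  x[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    x[cbind(r1, c0)] * fr * (1 - fc) +
    x[cbind(r0, c1)] * (1 - fr) * fc +
    x[cbind(r1, c1)] * fr * fc
}

#' Bilinear resize
#'
#' @param x Numeric matrix.
#' @param new_h,new_w Target dimensions.
#' @return `new_h x new_w` matrix.
#' @export
bilinear_resize <- function(x, new_h, new_w) {
  assert_image(x)
  sy <- nrow(x) / new_h; sx <- ncol(x) / new_w
  rr <- (seq_len(new_h) - 0.5) * sy + 0.5
  cc <- (seq_len(new_w) - 0.5) * sx + 0.5
  grid_r <- rep(rr, times = new_w)
  grid_c <- rep(cc, each = new_h)
  matrix(bilinear_sample(x, grid_r, grid_c), new_h, new_w)
}

#' Rotate an image about its centre
#'
#' Bilinear interpolation; samples falling outside the image clamp to the
#' nearest edge pixel.  Output has the same dimensions as the input.
#'
#' @param x Numeric matrix.
#' @param angle_deg Rotation angle in degrees (counter-clockwise).
#' @return Rotated matrix.
#' @export
rotate_image <- function(x, angle_deg) {
  assert_image(x)
  th <- angle_deg * pi / 180
  h <- nrow(x); w <- ncol(x)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  rr <- rep(seq_len(h), times = w) - cr
  cw <- rep(seq_len(w), each = h) - cc
  # inverse mapping: rotate destination coords by -theta
  sr <- cos(th) * rr - sin(th) * cw + cr
  sc <- sin(th) * rr + cos(th) * cw + cc
  matrix(bilinear_sample(x, sr, sc), h, w)
}

#' Resize-if-too-small normalisation
#'
#' Images smaller than the patch size cannot be cropped, so they are
#' upscaled (aspect preserved, bilinear) until the minimum side equals
#' `target_min_side`; larger images pass through unchanged.  The long side
#' rounds half-up.
#'
#' @param image Numeric matrix.
#' @param target_min_side Target for the minimum side (default 128).
#' @return Possibly resized matrix.
#' @export
normalize_resize <- function(image, target_min_side = 128L) {
  assert_image(image)
  h <- nrow(image); w <- ncol(image)
  if (min(h, w) >= target_min_side) return(image)
  s <- target_min_side / min(h, w)
  if (h <= w) {
    bilinear_resize(image, target_min_side,
                    as.integer(round_half_up(w * s)))
  } else {
    bilinear_resize(image, as.integer(round_half_up(h * s)),
                    target_min_side)
  }
}
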
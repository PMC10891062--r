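# Low-level image morphology and filtering primitives.
#
# All operators work on plain numeric/logical matrices.  Neighbourhood
# operations are implemented with padded-shift accumulation, which is
# vectorised and fast enough for the image sizes this package targets.

# replicate-pad a matrix by p pixels on every side
pad_replicate <- function(x, p) {
  h <- nrow(x); w <- ncol(x)
  ri <- c(rep(1L, p), seq_len(h), rep(h, p))
  ci <- c(rep(1L, p), seq_len(w), rep(w, p))
  x[ri, ci, drop = FALSE]
}

# zero-pad (logical FALSE-pad) by p pixels
pad_zero <- function(x, p) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(if (is.logical(x)) FALSE else 0, h + 2 * p, w + 2 * p)
  out[p + seq_len(h), p + seq_len(w)] <- x
  out
}

# sum of x over the given (dr, dc) offsets, replicate- or zero-padded
shift_sum <- function(x, offsets, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  p <- max(abs(offsets))
  xp <- if (pad == "replicate") pad_replicate(x, p) else pad_zero(x * 1, p)
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    out <- out + xp[p + dr + seq_len(h), p + dc + seq_len(w)]
  }
  out
}

# (2r+1)^2 box mean with replicate padding, via separable cumsum passes
box_filter <- function(x, r) {
  if (r <= 0) return(x)
  k <- 2L * r + 1L
  xp <- pad_replicate(x, r)
  # rows
  cs <- apply(xp, 2, cumsum)
  rowpart <- (rbind(cs[k:nrow(xp), , drop = FALSE]) -
              rbind(0, cs[seq_len(nrow(xp) - k), , drop = FALSE]))
  # cols
  cs2 <- t(apply(rowpart, 1, cumsum))
  out <- cs2[, k:ncol(xp), drop = FALSE] -
    cbind(0, cs2[, seq_len(ncol(xp) - k), drop = FALSE])
  out / (k * k)
}

# offsets (dr, dc) of a disk structuring element of radius r
disk_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE])
}

#' 3x3 Gaussian blur
#'
#' Separable binomial `(1,2,1)/4` kernel, the standard 3x3 Gaussian
#' approximation; borders are replicate-padded.
#'
#' @param x Numeric matrix.
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur3 <- function(x) {
  assert_image(x)
  xp <- pad_replicate(x, 1L)
  h <- nrow(x); w <- ncol(x)
  sl <- function(dr, dc) xp[1 + dr + seq_len(h), 1 + dc + seq_len(w)]
  k <- c(1, 2, 1) / 4
  out <- matrix(0, h, w)
  for (i in -1:1) for (j in -1:1)
    out <- out + k[i + 2] * k[j + 2] * sl(i, j)
  out
}

#' Local entropy filter
#'
#' Shannon entropy (bits) of the quantised gray-level histogram in a disk
#' neighbourhood, the texture detector used ahead of Otsu thresholding:
#' textured colony area has high local entropy, flat background low.
#'
#' @param x Numeric matrix in `[0,1]`.
#' @param radius Disk radius in pixels (default 3).
#' @param nbins Number of gray-level bins (default 64).
#' @return Matrix of local entropies (bits).
#' @export
entropy_filter <- function(x, radius = 3L, nbins = 64L) {
  assert_image(x)
  q <- pmin(floor(clip01(x) * nbins), nbins - 1)
  off <- disk_offsets(radius)
  nn <- nrow(off)
  ent <- matrix(0, nrow(x), ncol(x))
  for (b in seq_len(nbins) - 1L) {
    ind <- matrix(as.numeric(q == b), nrow(x), ncol(x))
    cnt <- shift_sum(ind, off, pad = "replicate")
    p <- cnt / nn
    nz <- p > 0
    ent[nz] <- ent[nz] - p[nz] * log2(p[nz])
  }
  ent
}

#' Otsu global threshold
#'
#' Maximises between-class variance over a 256-bin histogram of values
#' scaled to `[0,1]`.  A degenerate (single-bin) histogram yields `Inf`
#' so that thresholding produces an empty foreground.
#'
#' @param x Numeric matrix.
#' @param nbins Histogram resolution (default 256).
#' @return Threshold on the scale of `x` (foreground is `x > threshold`),
#'   or `Inf` when the histogram is degenerate (single-valued input).
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  assert_image(x)
  rng <- range(x)
  if (diff(rng) < 1e-12) return(Inf)
  z <- (x - rng[1]) / diff(rng)
  h <- tabulate(pmin(floor(z * nbins), nbins - 1) + 1L, nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(nbins) - 0.5) / nbins)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)
  rng[1] + (k / nbins) * diff(rng)
}

# binary erosion/dilation with a disk structuring element
binary_erode <- function(mask, radius) {
  off <- disk_offsets(radius)
  shift_sum(mask * 1, off, pad = "zero") >= nrow(off)
}

binary_dilate <- function(mask, radius) {
  off <- disk_offsets(radius)
  shift_sum(mask * 1, off, pad = "zero") > 0
}

#' Morphological opening with a disk element
#' @param mask Logical matrix.
#' @param radius Disk radius (default 3).
#' @return Logical matrix.
#' @export
binary_opening <- function(mask, radius = 3L) {
  binary_dilate(binary_erode(mask, radius), radius)
}

#' Label connected components
#'
#' Breadth-first flood fill.  Components are numbered in raster order of
#' their first-encountered pixel, which makes labelling deterministic.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask) || !is.logical(mask))
    invalid_argument("`mask` must be a logical matrix")
  if (!connectivity %in% c(4L, 8L))
    invalid_argument("connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  hp <- h + 2L
  mp <- pad_zero(mask, 1L)
  offs <- if (connectivity == 8L) {
    c(-1L, 1L, -hp, hp, -hp - 1L, -hp + 1L, hp - 1L, hp + 1L)
  } else c(-1L, 1L, -hp, hp)
  lab <- integer(length(mp))
  # raster order over the padded matrix is column-major; convert to find
  # seeds in (row, col) raster order within the unpadded frame
  todo <- which(mp)
  nextlab <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    nextlab <- nextlab + 1L
    lab[s] <- nextlab
    frontier <- s
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, `+`)))
      nb <- nb[mp[nb] & lab[nb] == 0L]
      lab[nb] <- nextlab
      frontier <- nb
    }
  }
  matrix(lab, hp)[1L + seq_len(h), 1L + seq_len(w)]
}

#' Fill holes in a binary mask
#'
#' Background regions (4-connected) not reachable from the image border are
#' converted to foreground.
#'
#' @param mask Logical matrix.
#' @return Logical matrix.
#' @export
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4L)
  h <- nrow(mask); w <- ncol(mask)
  border_labels <- unique(c(bg[1, ], bg[h, ], bg[, 1], bg[, w]))
  border_labels <- border_labels[border_labels != 0L]
  mask | (bg != 0L & !(bg %in% border_labels))
}

#' Remove small connected components
#'
#' Keeps components whose pixel area is at least `min_area` (objects
#' strictly smaller are removed, matching the usual small-object filter).
#'
#' @param mask Logical matrix.
#' @param min_area Minimum area in pixels (default 2000).
#' @param connectivity 8 (default) or 4.
#' @return Logical matrix.
#' @export
remove_small_objects <- function(mask, min_area = 2000L, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}
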
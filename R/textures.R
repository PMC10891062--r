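# Procedural textures for the four colony phenotype classes.
#
# The real classes are distinguished by texture and shape: pluripotent
# "dense" colonies show fine-grained uniform speckle, "spread" progenitors
# show coarse smooth blotches, "differentiated" neurons show dark cell
# bodies with thin axon-like strokes, and "debris" shows high-contrast
# bright-rimmed spheres of dead cells.  The generators below reproduce
# those qualitative signatures so that a single scalar statistic (mean
# local 3x3 variance, `texture_stat`) separates the classes by
# construction; the amplitudes were fixed once so the four statistic
# distributions occupy disjoint bands (see the separability tests).

TEXTURE_MIN_SIDE <- 8L

# mean local variance band centres per class, frozen at the defaults;
# used only for documentation/tests of the separation margin
TEXTURE_STAT_BANDS <- list(
  spread = c(0, 1.2e-3), dense = c(1.6e-3, 3.5e-3),
  diff = c(5e-3, 2.2e-2), debris = c(2.8e-2, 1.2e-1)
)

#' Scalar texture statistic: mean local variance
#'
#' Mean over pixels of the population variance in the 3x3 neighbourhood
#' (replicate-padded at borders).  This is the declared statistic under
#' which the four synthetic classes are separable.
#'
#' @param x Numeric image matrix in `[0,1]`.
#' @return Scalar mean local variance.
#' @export
texture_stat <- function(x) {
  assert_image(x)
  m1 <- box_filter(x, 1L)
  m2 <- box_filter(x * x, 1L)
  mean(pmax(m2 - m1 * m1, 0))
}

#' Generate a class-specific synthetic texture
#'
#' Deterministic for a fixed seed.  Foreground textures are darker and more
#' textured than the bright background used by [gen_scene()], matching
#' phase-contrast appearance.
#'
#' @param class Class label (one of [ipb_classes()]) or integer code 1..4.
#' @param size Integer `(H, W)`, each at least 8.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return `H x W` matrix in `[0,1]`.
#' @export
gen_class_texture <- function(class, size, seed = NULL) {
  if (is.numeric(class)) class <- id_to_class(class)
  if (length(class) != 1 || is.na(match(class, IPB_CLASSES)))
    invalid_argument(paste0("unknown class id: ", paste(class, collapse = ",")))
  size <- as.integer(size)
  if (length(size) != 2 || any(size < TEXTURE_MIN_SIDE))
    invalid_argument("texture size must be at least 8x8")
  gen <- function() {
    h <- size[1]; w <- size[2]; n <- h * w
    x <- switch(class,
      dense = matrix(0.45 + runif(n, -0.09, 0.09), h, w),
      spread = {
        sm <- box_filter(box_filter(matrix(runif(n, -1, 1), h, w), 3L), 3L)
        s <- stats::sd(sm)
        if (s < 1e-12) s <- 1
        clip01(0.55 + sm / s * 0.10)
      },
      diff = {
        # fine cellular speckle everywhere; strokes/blobs ride on top
        x <- matrix(0.62 + runif(n, -0.09, 0.09), h, w)
        # dark round cell bodies
        nb <- max(1L, round(n / 260))
        for (i in seq_len(nb)) {
          x <- stamp_disk(x, runif(1, 1, h), runif(1, 1, w),
                          runif(1, 1.5, 3.5), 0.22)
        }
        # thin elongated axon-like strokes
        ns <- max(2L, round(n / 220))
        for (i in seq_len(ns)) {
          x <- stamp_stroke(x, runif(1, 1, h), runif(1, 1, w),
                            runif(1, 0, pi), runif(1, 8, 22), 0.25)
        }
        x
      },
      debris = {
        x <- matrix(0.55 + runif(n, -0.09, 0.09), h, w)
        nc <- max(2L, round(n / 110))
        for (i in seq_len(nc)) {
          r0 <- runif(1, 1, h); c0 <- runif(1, 1, w)
          rad <- runif(1, 2.5, 5.5)
          x <- stamp_disk(x, r0, c0, rad, 0.95)          # bright rim
          x <- stamp_disk(x, r0, c0, rad - 1.2, 0.25)    # dark core
        }
        x
      }
    )
    clip01(x)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# set pixels within `rad` of (r0, c0) to `value` plus per-pixel jitter
# (cell bodies are never optically flat; keeping texture inside stamped
# features also keeps their local entropy above background)
stamp_disk <- function(x, r0, c0, rad, value, jitter = 0.05) {
  if (rad <= 0) return(x)
  rr <- max(1L, floor(r0 - rad)):min(nrow(x), ceiling(r0 + rad))
  cc <- max(1L, floor(c0 - rad)):min(ncol(x), ceiling(c0 + rad))
  if (!length(rr) || !length(cc)) return(x)
  m <- outer((rr - r0)^2, (cc - c0)^2, `+`) <= rad^2
  sub <- x[rr, cc, drop = FALSE]
  sub[m] <- value + runif(sum(m), -jitter, jitter)
  x[rr, cc] <- sub
  x
}

# draw a 1-px-wide line of given length from (r0,c0) at `angle`
stamp_stroke <- function(x, r0, c0, angle, len, value, jitter = 0.05) {
  t <- seq(0, len, by = 0.5)
  rr <- round(r0 + t * sin(angle)); cc <- round(c0 + t * cos(angle))
  ok <- rr >= 1 & rr <= nrow(x) & cc >= 1 & cc <= ncol(x)
  pix <- unique(cbind(rr[ok], cc[ok]))
  x[pix] <- value + runif(nrow(pix), -jitter, jitter)
  x
}
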
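# Portable graymap (PGM) I/O.
#
# The package stores synthetic fixtures and masks as single-channel PGM:
# "P2" (ASCII) for text-only fixtures checked into the repository, "P5"
# (raw) for bulk run-time output.  Pixels are 8-bit; matrices are [0,1]
# doubles row-major top-to-bottom, matching the raster convention.

#' Write a grayscale image as PGM
#'
#' @param x Numeric matrix in `[0,1]` (rows = image rows).
#' @param path Output file path.
#' @param format `"raw"` (P5, binary) or `"ascii"` (P2, plain text).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(x, path, format = c("raw", "ascii")) {
  assert_image(x)
  format <- match.arg(format)
  px <- as.integer(round(clip01(x) * 255))
  # PGM is row-major: emit row by row (t() flattens column-major)
  pxr <- as.vector(t(matrix(px, nrow(x), ncol(x))))
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(x), nrow(x)), "255"), con)
    writeLines(paste(pxr, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(x), nrow(x)), con, eos = NULL)
    writeBin(as.raw(pxr), con)
  }
  invisible(path)
}

#' Read a PGM image
#'
#' Supports P2 (ASCII) and P5 (raw) 8-bit graymaps.
#'
#' @param path File path.
#' @return Numeric matrix in `[0,1]`.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) stopf("not a P2/P5 PGM file: %s", path)
  # token reader skipping whitespace and '#' comments
  next_token <- function() {
    tok <- character(0)
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1L))
      if (length(ch) == 0 || ch == "") stopf("truncated PGM header: %s", path)
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- rawToChar(readBin(con, "raw", 1L))
          if (ch %in% c("\n", "\r") || ch == "") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok) > 0) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  w <- as.integer(next_token())
  h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  n <- w * h
  if (magic == "P5") {
    px <- as.integer(readBin(con, "raw", n))
  } else {
    txt <- rawToChar(readBin(con, "raw", file.size(path)))
    px <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])
    if (length(px) < n) stopf("truncated P2 payload: %s", path)
    px <- px[seq_len(n)]
  }
  matrix(px / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a binary mask as 0/255 PGM
#'
#' @param mask Logical matrix.
#' @inheritParams write_pgm
#' @return `path`, invisibly.
#' @export
write_mask_pgm <- function(mask, path, format = c("raw", "ascii")) {
  if (!is.matrix(mask) || !is.logical(mask))
    stopf("`mask` must be a logical matrix")
  write_pgm(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path, format)
}
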
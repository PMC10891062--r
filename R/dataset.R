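# Dataset generation and manifest I/O.
#
# A manifest is a data.frame (class `ipb_manifest`) with columns
# image_id, path, label, height, width; labels are the literal strings
# dense/spread/diff/debris/multilabel.  Images are written as single-
# channel PGM.  Image sizes are drawn log-uniformly between the extreme
# sizes observed in real colony crops (55x85 up to 771x1298).

IPB_SIZE_RANGE <- list(min = c(55L, 85L), max = c(771L, 1298L))

new_manifest <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  counts <- table(factor(df$label, levels = c(IPB_CLASSES, IPB_MULTILABEL)))
  structure(df, class = c("ipb_manifest", "data.frame"),
            class_counts = as.list(as.integer(counts)) |>
              stats::setNames(names(counts)))
}

#' Class counts recorded in a manifest
#' @param manifest An `ipb_manifest`.
#' @return Named list of per-class record counts.
#' @export
manifest_counts <- function(manifest) attr(manifest, "class_counts")

#' Generate a synthetic colony image dataset
#'
#' Writes one PGM image per record plus a CSV manifest.  Single-class
#' records contain one colony of the requested class; multi-label records
#' contain colonies of at least two distinct classes and carry the label
#' `multilabel`.  Counts are honoured exactly and generation is
#' deterministic in `seed`.
#'
#' @param class_counts Named integer vector/list over a subset of
#'   [ipb_classes()], e.g. `c(dense = 20, spread = 50)`.
#' @param multilabel_count Number of multi-label composite images.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param size_range List with `min`/`max` `(H, W)` pairs; defaults to the
#'   real dataset extremes 55x85 .. 771x1298.
#' @param format PGM flavour passed to [write_pgm()].
#' @return An `ipb_manifest`; also written as `manifest.csv` in `out_dir`.
#' @export
gen_dataset <- function(class_counts, multilabel_count = 0L, out_dir,
                        seed = 1L, size_range = IPB_SIZE_RANGE,
                        format = "raw") {
  class_counts <- unlist(class_counts)
  if (length(class_counts) && is.null(names(class_counts)))
    invalid_argument("class_counts must be named")
  if (any(class_counts < 0) || multilabel_count < 0)
    invalid_argument("counts must be nonnegative")
  bad <- setdiff(names(class_counts), IPB_CLASSES)
  if (length(bad))
    invalid_argument(paste("unknown class:", paste(bad, collapse = ",")))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory: %s", out_dir)

  labels <- c(rep(names(class_counts), as.integer(class_counts)),
              rep(IPB_MULTILABEL, multilabel_count))
  n <- length(labels)
  if (n == 0L) {
    man <- new_manifest(data.frame(image_id = character(), path = character(),
                                   label = character(), height = integer(),
                                   width = integer()))
    write_manifest(man, file.path(out_dir, "manifest.csv"))
    return(man)
  }
  rows <- with_seed(derive_seed(seed, "dataset"), {
    lapply(seq_len(n), function(i) {
      s <- stats::runif(1)  # shared log-uniform scale for both dimensions
      hw <- round_half_up(size_range$min * (size_range$max /
                                              size_range$min)^s)
      h <- as.integer(hw[1]); w <- as.integer(hw[2])
      lab <- labels[i]
      spec <- if (lab == IPB_MULTILABEL) {
        k <- sample(2:4, 1)
        multilabel_spec(sample(IPB_CLASSES, k), h, w)
      } else single_colony_spec(lab, h, w)
      sc <- gen_scene(spec)
      id <- sprintf("img_%05d", i)
      path <- file.path(out_dir, paste0(id, ".pgm"))
      write_pgm(sc$image, path, format = format)
      data.frame(image_id = id, path = path, label = lab,
                 height = h, width = w, stringsAsFactors = FALSE)
    })
  })
  man <- new_manifest(do.call(rbind, rows))
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  man
}

#' Write a dataset manifest as CSV
#' @param manifest An `ipb_manifest` (or compatible data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(
    as.data.frame(manifest)[, c("image_id", "path", "label",
                                "height", "width")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset manifest CSV
#' @param path Manifest CSV path.
#' @return An `ipb_manifest`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "path", "label", "height", "width")
  if (!all(need %in% names(df)))
    stopf("manifest must have columns %s", paste(need, collapse = ","))
  bad <- setdiff(unique(df$label), c(IPB_CLASSES, IPB_MULTILABEL))
  if (length(bad))
    stopf("manifest contains unknown labels: %s", paste(bad, collapse = ","))
  new_manifest(df)
}
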
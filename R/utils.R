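#' @keywords internal
"_PACKAGE"

# Morphology class vocabulary used across the package.  Integer codes are
# 1-based and stable; the manifest stores the lower-case string labels.
IPB_CLASSES <- c("dense", "spread", "diff", "debris")
IPB_MULTILABEL <- "multilabel"

#' Morphology class labels
#'
#' The four colony phenotype classes recognised by the classifier, in their
#' canonical integer order (1 = dense, 2 = spread, 3 = diff, 4 = debris).
#'
#' @return Character vector of length 4.
#' @export
ipb_classes <- function() IPB_CLASSES

class_to_id <- function(label) {
  id <- match(label, IPB_CLASSES)
  if (anyNA(id)) {
    stop("unknown class label(s): ",
         paste(unique(label[is.na(id)]), collapse = ", "), call. = FALSE)
  }
  id
}

id_to_class <- function(id) IPB_CLASSES[id]

#' Run code with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded generators never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named RNG substream seed from a master seed
#'
#' A single experiment seed fans out into independent per-stage seeds
#' (data / augment / sampling / init / ...) so that toggling one stage's
#' stochasticity does not shift the others.  Result is kept in
#' `[0, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param stream Character tag naming the substream.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 69069 + h * 1013) %% 2147483647)
}

# round-half-up (R's round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

clip01 <- function(x) pmin(pmax(x, 0), 1)  # arg order keeps dim attributes

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_image <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("`%s` must be a 2-D numeric matrix", arg)
  if (!all(is.finite(x))) stopf("`%s` contains non-finite values", arg)
  invisible(x)
}

# condition helpers --------------------------------------------------------

ipb_error <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

invalid_argument <- function(msg) ipb_error(msg, "ipb_invalid_argument")
degenerate_input <- function(msg) ipb_error(msg, "ipb_degenerate_input")
empty_epoch_error <- function(msg) ipb_error(msg, "ipb_empty_epoch")
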
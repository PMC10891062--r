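# Run configuration: a nested list that round-trips losslessly through
# JSON, with defaults carrying the published hyperparameters.

#' Default run configuration
#'
#' @return Nested list with sections `data`, `seg`, `patch`, `augment`,
#'   `model`, `train`, `split`, `seed`, `outdir`.
#' @export
default_config <- function() {
  list(
    data = list(manifest = NULL, synthesize = FALSE,
                class_counts = list(dense = 20, spread = 50, diff = 5,
                                    debris = 15),
                multilabel_count = 5, include_multilabel = TRUE,
                size_range = list(min = c(55, 85), max = c(771, 1298))),
    seg = list(blur_kernel = 3, disk_radius = 3, min_area = 2000,
               entropy_bins = 64),
    patch = list(scale_mode = "dual224_112", size = 224,
                 min_coverage = 0.5, max_trials = 50),
    augment = list(prob = 0.25, rot_range = c(0, 180),
                   bc_range = c(0.8, 1.2), blur_sigma = c(0.3, 1.0)),
    model = list(arch = "dual_stream_vgg", num_classes = 4,
                 in_channels = 1),
    train = list(eta_s = 0.005, eta_t = 0.005, momentum = 0.9,
                 weight_decay = 1e-4, batch_size = 32,
                 pretrain_epochs = 200, ipb_epochs = 200,
                 warmup_epochs = 10, tau = 0.65, lambda = 1.0,
                 balance = TRUE),
    split = list(fractions = c(0.8, 0.1, 0.1), fold = 0),
    seed = 1,
    outdir = "ipb_run")
}

# recursively overlay user values on the defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stopf("unknown config key(s): %s",
          paste0(path, bad, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
                         !is.null(names(defaults[[k]]))) {
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    } else user[[k]]
  }
  defaults
}

validate_config <- function(cfg) {
  tr <- cfg$train
  if (tr$tau <= 0 || tr$tau >= 1) stopf("config error: train.tau must be in (0,1)")
  if (tr$eta_s <= 0 || tr$eta_t <= 0)
    stopf("config error: learning rates must be positive")
  if (abs(sum(cfg$split$fractions) - 1) > 1e-9)
    stopf("config error: split.fractions must sum to 1")
  if (!cfg$patch$scale_mode %in% c("dual224_112", "single128"))
    stopf("config error: unknown patch.scale_mode")
  cfg
}

#' Load a run configuration from JSON
#'
#' Missing keys take defaults; unknown keys are an error naming the
#' offending keys; an empty file yields the all-defaults configuration.
#'
#' @param path JSON file path.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (nchar(trimws(txt)) == 0) list()
          else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  validate_config(merge_config(default_config(), user))
}

#' Save a run configuration as JSON
#' @param cfg Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
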
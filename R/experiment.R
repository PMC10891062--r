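# End-to-end experiment runner: synthesize or load data, split, pre-train
# the teacher, run IPB, evaluate the best student, and write all run
# artifacts (config snapshot, manifests, loss and proportion traces,
# metrics) under one output directory.

#' Run a full IPB experiment from a configuration
#'
#' Executes split -> teacher pre-training -> IPB -> evaluation, writing
#' `config.json`, `manifest.csv`, `trace.csv` (epoch, student loss,
#' teacher loss, selection accuracy), `p_trace.csv` (per-epoch estimated
#' class proportions), `metrics.json` and `metrics.csv` into
#' `cfg$outdir`.  Deterministic: the same configuration and seed
#' reproduce the same artifacts.
#'
#' @param cfg Configuration list, see [default_config()]; stage errors
#'   propagate with the stage name prefixed.
#' @return Invisibly, a list with `state` (`ipb_train_state`), `metrics`
#'   and `outdir`.
#' @export
run_experiment <- function(cfg = default_config()) {
  cfg <- validate_config(merge_config(default_config(), cfg))
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  save_config(cfg, file.path(outdir, "config.json"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage %s failed: %s", name, conditionMessage(e)))
  }

  manifest <- stage("data", {
    if (isTRUE(cfg$data$synthesize) || is.null(cfg$data$manifest)) {
      gen_dataset(cfg$data$class_counts, cfg$data$multilabel_count,
                  out_dir = file.path(outdir, "images"),
                  seed = derive_seed(cfg$seed, "data"),
                  size_range = cfg$data$size_range)
    } else read_manifest(cfg$data$manifest)
  })
  write_manifest(manifest, file.path(outdir, "manifest.csv"))

  split <- stage("split", make_splits(
    manifest, cfg$split$fractions, cfg$split$fold,
    seed = derive_seed(cfg$seed, "split"),
    include_multilabel = cfg$data$include_multilabel))

  seg <- seg_params(cfg$seg$blur_kernel, cfg$seg$disk_radius,
                    cfg$seg$min_area, cfg$seg$entropy_bins)
  mk_task <- function(ids, augment) {
    make_patch_task_from_manifest(
      manifest, ids, seg = seg, scale_mode = cfg$patch$scale_mode,
      patch_size = cfg$patch$size, min_coverage = cfg$patch$min_coverage,
      max_trials = cfg$patch$max_trials, augment = augment,
      augment_prob = cfg$augment$prob)
  }
  tasks <- stage("tasks", list(
    u = mk_task(split$unlabeled, augment = TRUE),
    l = mk_task(split$labeled, augment = TRUE),
    t = mk_task(split$test, augment = FALSE)))

  arch <- arch_config(cfg$model$arch, cfg$model$num_classes,
                      cfg$model$in_channels)
  tcfg <- train_config(cfg$train$eta_s, cfg$train$eta_t,
                       cfg$train$momentum, cfg$train$weight_decay,
                       cfg$train$batch_size, cfg$train$pretrain_epochs,
                       cfg$train$ipb_epochs, cfg$train$warmup_epochs,
                       cfg$train$tau, cfg$train$lambda)

  state <- stage("train", run_ipb(tasks$u, tasks$l, arch, tcfg,
                                  seed = cfg$seed,
                                  balance = isTRUE(cfg$train$balance)))

  metrics <- stage("evaluate", {
    preds <- predict_images(state$best_student, tasks$t)
    labels <- tasks$t$labels
    score(preds$pred, labels, m = arch$num_classes)
  })

  # content hashes of the run inputs, for exact replay verification
  hashes <- as.list(tools::md5sum(c(
    config = file.path(outdir, "config.json"),
    manifest = file.path(outdir, "manifest.csv"))))
  names(hashes) <- c("config.json", "manifest.csv")
  jsonlite::write_json(hashes, file.path(outdir, "inputs_hash.json"),
                       auto_unbox = TRUE)

  utils::write.csv(state$trace, file.path(outdir, "trace.csv"),
                   row.names = FALSE)
  pt <- as.data.frame(state$p_trace)
  names(pt) <- IPB_CLASSES[seq_len(ncol(pt))]
  utils::write.csv(cbind(epoch = seq_len(nrow(pt)), pt),
                   file.path(outdir, "p_trace.csv"), row.names = FALSE)
  mdf <- data.frame(class = IPB_CLASSES[seq_along(metrics$tpr)],
                    tpr = metrics$tpr, f1 = metrics$f1)
  utils::write.csv(mdf, file.path(outdir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(accuracy = metrics$accuracy, macro_tpr = metrics$macro_tpr,
         macro_f1 = metrics$macro_f1, per_class = mdf,
         best_selection_accuracy = state$best_acc),
    file.path(outdir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(list(state = state, metrics = metrics, outdir = outdir))
}
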
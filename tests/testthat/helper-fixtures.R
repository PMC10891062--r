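# Shared fixtures, generated in code and memoised per test run.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# a balanced set of single-class texture images (one list per class code)
class_images <- function(n_per, size = c(32, 32), offset = 0) {
  imgs <- list(); labs <- integer(0)
  for (cl in 1:4) {
    for (i in seq_len(n_per)) {
      imgs[[length(imgs) + 1L]] <-
        gen_class_texture(cl, size, seed = cl * 10000 + i + offset)
      labs <- c(labs, cl)
    }
  }
  list(images = imgs, labels = labs)
}

tiny_task <- function(n_per, augment = TRUE, offset = 0) {
  d <- class_images(n_per, offset = offset)
  make_patch_task(d$images, d$labels, patch_size = 32, augment = augment)
}

# a tiny teacher trained once and reused across test files
trained_tiny_model <- function() {
  memo("tiny_model", {
    task <- tiny_task(16)
    cfg <- train_config(pretrain_epochs = 40, batch_size = 32)
    pretrain_teacher(task, arch_config("tiny_test"), cfg, seed = 7)
  })
}

# random blob masks for connected-component oracle tests
random_blob_mask <- function(seed, h = 40, w = 40, p = 0.35) {
  with_seed(seed, {
    m <- matrix(runif(h * w) < p, h, w)
    # light smoothing so blobs have some structure
    binary_opening(m, 1L)
  })
}

# igraph-based connected components: the independent labelling oracle
igraph_component_count <- function(mask, connectivity = 8L) {
  idx <- which(mask)
  if (length(idx) == 0) return(0L)
  h <- nrow(mask)
  rc <- cbind((idx - 1L) %% h + 1L, (idx - 1L) %/% h + 1L)
  key <- function(r, c) paste(r, c)
  vert <- key(rc[, 1], rc[, 2])
  offs <- if (connectivity == 8L) {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  edges <- character(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- rc[, 1] + offs[k, 1]; c2 <- rc[, 2] + offs[k, 2]
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= ncol(mask)
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (any(ok)) edges <- c(edges, rbind(vert[ok], key(r2[ok], c2[ok])))
  }
  g <- igraph::graph_from_data_frame(
    d = if (length(edges)) as.data.frame(matrix(edges, ncol = 2,
                                                byrow = TRUE))
        else data.frame(from = character(0), to = character(0)),
    directed = FALSE, vertices = data.frame(name = vert))
  igraph::components(g)$no
}

# ---- the scaled-down paired-seed experiment (acceptance criteria 6/7) ----
#
# Stated world: tiny dual-stream networks, separable 4-class synthetic
# textures, unlabeled class counts 30:10:10:1 (minority = the
# differentiated class, mirroring the real dataset), 40 IPB epochs with
# 5 paired seeds; balanced labeled (8/class) and test (24/class) sets;
# 30 teacher pre-training epochs (the depth at which the tiny teacher's
# confidence clears tau); consistency term off (runtime budget).

scaled_world_tasks <- function(seed) {
  counts <- c(dense = 30, spread = 10, diff = 1, debris = 10)
  mkimgs <- function(n, cl, tag) lapply(seq_len(n), function(i)
    gen_class_texture(cl, c(32, 32),
                      seed = derive_seed(seed, paste0(tag, cl, "_", i))))
  u_imgs <- list(); u_labs <- integer(0)
  for (cl in 1:4) {
    n <- counts[[ipb_classes()[cl]]]
    u_imgs <- c(u_imgs, mkimgs(n, cl, "u")); u_labs <- c(u_labs, rep(cl, n))
  }
  l <- list(); l_labs <- integer(0)
  t <- list(); t_labs <- integer(0)
  for (cl in 1:4) {
    l <- c(l, mkimgs(8, cl, "l")); l_labs <- c(l_labs, rep(cl, 8))
    t <- c(t, mkimgs(24, cl, "t")); t_labs <- c(t_labs, rep(cl, 24))
  }
  list(u = make_patch_task(u_imgs, NULL, patch_size = 32), u_labs = u_labs,
       l = make_patch_task(l, l_labs, patch_size = 32),
       t = make_patch_task(t, t_labs, patch_size = 32, augment = FALSE),
       t_labs = t_labs)
}

scaled_world_pair <- function(seed) {
  tk <- scaled_world_tasks(seed)
  arch <- arch_config("tiny_test")
  # consistency term off in the scaled runs (runtime budget)
  cfg <- train_config(pretrain_epochs = 30, ipb_epochs = 40, lambda = 0)
  teacher <- pretrain_teacher(tk$l, arch, cfg, seed = seed)
  st_bal <- run_ipb(tk$u, tk$l, arch, cfg, seed = seed, balance = TRUE,
                    teacher = teacher)
  st_imb <- run_ipb(tk$u, tk$l, arch, cfg, seed = seed, balance = FALSE,
                    teacher = teacher)
  tpr <- function(st) {
    preds <- predict_images(st$best_student, tk$t)
    score(preds$pred, tk$t_labs, 4)$tpr
  }
  true_p <- tabulate(tk$u_labs, 4) / length(tk$u_labs)
  l1 <- rowSums(abs(st_bal$p_trace -
                      matrix(true_p, nrow(st_bal$p_trace), 4, byrow = TRUE)))
  list(tpr_bal = tpr(st_bal), tpr_imb = tpr(st_imb), l1 = l1)
}

scaled_world_results <- function() {
  memo("scaled_world", lapply(1:5, scaled_world_pair))
}
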
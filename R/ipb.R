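# Iterative pseudo-balancing: the student-teacher meta-pseudo-label loop
# with per-epoch class rebalancing.
#
# Each epoch the teacher pseudo-labels one random in-mask patch per
# unlabeled image; labels below the confidence threshold are dropped;
# class proportions p_i are estimated from the kept labels; and |U|
# training draws are taken from a multinomial over kept items with
# per-item weight w(j) = 1 / (m * p_c(j)), so the expected class shares
# of the student's stream are uniform.  The student minimises
# cross-entropy against the hard pseudo-labels (update: theta_S' =
# theta_S - eta_S * grad), and the teacher is then moved along the
# meta-gradient of the updated student's labeled-set loss (theta_T' =
# theta_T - eta_T * grad), optionally plus a confidence-masked
# consistency term on weak/strong augmented views.

#' Training configuration
#'
#' Defaults are the published hyperparameters: SGD with learning rate
#' 0.005, momentum 0.9, weight decay 1e-4, batch size 32, 200 pre-training
#' and 200 IPB epochs with a 10-epoch linear warm-up of the student
#' learning rate, and pseudo-label confidence threshold 0.65.
#'
#' @param eta_s,eta_t Student/teacher learning rates (> 0).
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param batch_size Minibatch size.
#' @param pretrain_epochs Supervised teacher pre-training epochs.
#' @param ipb_epochs IPB training epochs.
#' @param warmup_epochs Linear student-LR ramp length.
#' @param tau Pseudo-label confidence threshold in (0, 1).
#' @param lambda Consistency-loss weight (>= 0; 0 disables the term).
#' @return An object of class `ipb_train_config`.
#' @export
train_config <- function(eta_s = 0.005, eta_t = 0.005, momentum = 0.9,
                         weight_decay = 1e-4, batch_size = 32L,
                         pretrain_epochs = 200L, ipb_epochs = 200L,
                         warmup_epochs = 10L, tau = 0.65, lambda = 1.0) {
  if (tau <= 0 || tau >= 1) invalid_argument("tau must be in (0, 1)")
  if (eta_s <= 0 || eta_t <= 0)
    invalid_argument("learning rates must be positive")
  if (lambda < 0) invalid_argument("lambda must be nonnegative")
  structure(list(eta_s = eta_s, eta_t = eta_t, momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 ipb_epochs = as.integer(ipb_epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 tau = tau, lambda = lambda),
            class = "ipb_train_config")
}

#' Pre-train the teacher network
#'
#' Fully supervised SGD on the small balanced labeled subset: one
#' augmented in-mask patch per image per epoch, cross-entropy loss.
#'
#' @param labeled An `ipb_task` with labels; every class must appear.
#' @param arch An [arch_config()].
#' @param cfg An [train_config()].
#' @param seed Integer seed.
#' @param epochs Override for `cfg$pretrain_epochs`.
#' @return The trained `ipb_model`.
#' @export
pretrain_teacher <- function(labeled, arch, cfg = train_config(), seed = 1L,
                             epochs = NULL) {
  m <- arch$num_classes
  present <- sort(unique(labeled$labels[!is.na(labeled$labels)]))
  if (!identical(present, seq_len(m)))
    invalid_argument("labeled set must contain every class (balanced subset)")
  if (is.null(epochs)) epochs <- cfg$pretrain_epochs
  model <- build_model(arch, seed = derive_seed(seed, "teacher_init"))
  if (epochs == 0L) return(model)
  opt <- sgd_init(model)
  with_seed(derive_seed(seed, "pretrain"), {
    for (e in seq_len(epochs)) {
      ord <- sample.int(labeled$n)
      for (chunk in batch_chunks(ord, cfg$batch_size)) {
        patches <- task_patches(labeled, chunk)
        st <- student_step(model, patches,
                           labeled$labels[chunk], cfg$eta_s, opt,
                           momentum = cfg$momentum,
                           weight_decay = cfg$weight_decay,
                           num_classes = m)
        model <- st$model; opt <- st$state
      }
    }
  })
  model
}

batch_chunks <- function(idx, size) {
  split(idx, ceiling(seq_along(idx) / size))
}

#' Assign pseudo-labels with confidence filtering
#'
#' Teacher soft probabilities, hard labels by argmax (lowest index wins
#' ties), and a kept flag for confidence >= `tau`.
#'
#' @param teacher An `ipb_model`.
#' @param patches List of `ipb_patch` objects (or any batch form accepted
#'   by [forward_probs()]).
#' @param tau Confidence threshold (default 0.65).
#' @return An object of class `ipb_pseudoset`: list with `probs` (n x m),
#'   `hard`, `confidence`, `kept`, `tau`.
#' @export
assign_pseudo_labels <- function(teacher, patches, tau = 0.65) {
  if (length(patches) == 0) invalid_argument("no patches to pseudo-label")
  new_pseudoset(forward_probs(teacher, patches), tau)
}

# pseudo-set from a probability matrix; split out so the threshold and
# tie-break semantics are testable without a model
new_pseudoset <- function(probs, tau) {
  hard <- max.col(probs, ties.method = "first")
  confidence <- probs[cbind(seq_len(nrow(probs)), hard)]
  structure(list(probs = probs, hard = hard, confidence = confidence,
                 kept = confidence >= tau, tau = tau),
            class = "ipb_pseudoset")
}

#' Estimate the pseudo-label class distribution
#'
#' Counts kept pseudo-labels per class; proportions `p_i = n_i / sum(n)`.
#' Sampling weights use floor pseudo-counts (`max(n_i, 1)`) so that a
#' class absent from this epoch's kept set cannot produce an infinite
#' weight: `w_i = 1 / (m * p_floor_i)`.
#'
#' @param ps An `ipb_pseudoset`.
#' @param m Number of classes.
#' @return An `ipb_classdist`: list with `m`, `n`, `p`, `n_floor`,
#'   `p_floor`, `w_class`.
#' @export
estimate_distribution <- function(ps, m = ncol(ps$probs)) {
  kept_hard <- ps$hard[ps$kept]
  if (length(kept_hard) == 0L)
    empty_epoch_error("no pseudo-labels above the confidence threshold")
  n <- tabulate(kept_hard, nbins = m)
  n_floor <- pmax(n, 1L)
  p_floor <- n_floor / sum(n_floor)
  structure(list(m = m, n = n, p = n / sum(n), n_floor = n_floor,
                 p_floor = p_floor, w_class = 1 / (m * p_floor)),
            class = "ipb_classdist")
}

#' Balanced multinomial resampling of pseudo-labeled items
#'
#' Draws `n_draws` kept-item indices with replacement, item `j` with
#' probability proportional to `1 / (m * p_{c(j)})`; the expected class
#' share is `1/m` for every class with kept items.
#'
#' @param ps An `ipb_pseudoset`.
#' @param dist An `ipb_classdist` from [estimate_distribution()].
#' @param n_draws Number of draws (>= 1).
#' @param seed Optional integer seed.
#' @return Integer vector of item indices into the pseudo-set.
#' @export
balanced_resample <- function(ps, dist, n_draws, seed = NULL) {
  if (n_draws < 1) invalid_argument("n_draws must be >= 1")
  kept_idx <- which(ps$kept)
  w <- dist$w_class[ps$hard[kept_idx]]
  draw <- function() {
    kept_idx[sample.int(length(kept_idx), n_draws, replace = TRUE,
                        prob = w)]
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' One student SGD step
#'
#' Cross-entropy between the student's predictions and the (pseudo)
#' labels, followed by an SGD update with momentum and weight decay:
#' `theta' = theta - eta * v` with `v = momentum * v + grad + wd * theta`.
#'
#' @param student An `ipb_model`.
#' @param patches Batch (list of `ipb_patch`, matrices, or arrays).
#' @param labels Integer hard labels, or an `n x m` matrix of soft target
#'   distributions.
#' @param eta_s Learning rate (0 leaves parameters unchanged when the
#'   optimizer state is fresh).
#' @param opt_state Optimizer state from [sgd_init()]; created fresh when
#'   `NULL`.
#' @param momentum,weight_decay SGD parameters.
#' @param num_classes Number of classes (for hard-label one-hot coding).
#' @return List with `model`, `state`, `loss`, `grads` (the gradient at
#'   the pre-update parameters) and `probs`.
#' @export
student_step <- function(student, patches, labels, eta_s,
                         opt_state = NULL, momentum = 0.9,
                         weight_decay = 1e-4,
                         num_classes = student$cfg$num_classes) {
  inputs <- as_model_inputs(student$cfg, patches)
  targets <- if (is.matrix(labels)) labels else one_hot(labels, num_classes)
  fw <- nn_forward(student, inputs, training = TRUE)
  student <- fw$model
  ce <- ce_loss(fw$logits, targets)
  grads <- nn_backward(student, fw$caches, ce$dlogits)
  if (is.null(opt_state)) opt_state <- sgd_init(student)
  up <- sgd_step(student, grads, opt_state, eta_s, momentum, weight_decay)
  list(model = up$model, state = up$state, loss = ce$loss, grads = grads,
       probs = ce$probs)
}

#' Meta scalar h for the teacher update
#'
#' First-order meta-pseudo-label signal: `h = eta_s * <g_l, g_u>`, the
#' inner product of the updated student's labeled-loss gradient with the
#' student's pseudo-batch gradient, scaled by the student step size.  A
#' positive `h` means the pseudo-labeled step helped on labeled data.
#'
#' @param grads_labeled Gradient tree of the updated student's loss on
#'   labeled data.
#' @param grads_pseudo Gradient tree of the student's pseudo-batch loss
#'   at the pre-update parameters.
#' @param eta_s Student learning rate used for the step.
#' @return Scalar `h`.
#' @export
mpl_h <- function(grads_labeled, grads_pseudo, eta_s) {
  eta_s * grads_dot(grads_labeled, grads_pseudo)
}

#' Confidence-masked consistency loss (weak vs strong views)
#'
#' KL divergence from the teacher's (stop-gradient) prediction on a
#' weakly augmented view to its prediction on a strongly augmented view,
#' averaged over items whose weak-view confidence reaches `tau`.
#'
#' @param teacher An `ipb_model`.
#' @param weak,strong Batches of the same items under weak/strong
#'   augmentation.
#' @param tau Confidence mask threshold.
#' @return List with `loss` and `grads` (w.r.t. teacher parameters
#'   through the strong branch; zero tree when no item passes the mask).
#' @export
consistency_loss <- function(teacher, weak, strong, tau = 0.65) {
  # weak branch: training-mode forward (same batch-norm statistics as the
  # strong branch) but no gradient flows through it
  winp <- as_model_inputs(teacher$cfg, weak)
  pw <- softmax_mat(nn_forward(teacher, winp, training = TRUE)$logits)
  keep <- apply(pw, 1, max) >= tau
  inputs <- as_model_inputs(teacher$cfg, strong)
  fw <- nn_forward(teacher, inputs, training = TRUE)
  psoft <- softmax_mat(fw$logits)
  if (!any(keep)) {
    return(list(loss = 0, grads = zero_grads(teacher)))
  }
  nk <- sum(keep)
  kl <- rowSums(pw * (log(pmax(pw, 1e-12)) - log(pmax(psoft, 1e-12))))
  loss <- sum(kl[keep]) / nk
  dlog <- (psoft - pw) * (keep / nk)           # KL grad w.r.t. strong logits
  grads <- nn_backward(teacher, fw$caches, dlog)
  list(loss = loss, grads = grads)
}

zero_grads <- function(model) {
  sgd_init(model)  # same shapes, all zeros (relu entries NULL, harmless)
}

#' One teacher meta-update step
#'
#' Moves the teacher along `h * grad CE(pseudo-labels, teacher probs)`
#' plus `lambda` times the consistency gradient, with SGD momentum and
#' weight decay; `eta_t = 0` with `lambda = 0` leaves the teacher
#' unchanged.  The meta-learning contract requires the student to have
#' been updated first: pass `student_fresh = FALSE` to signal a stale
#' student and get a contract-violation error.
#'
#' @param teacher An `ipb_model`.
#' @param patches Pseudo-labeled batch the student was trained on.
#' @param hard Hard pseudo-labels for that batch.
#' @param h Meta scalar from [mpl_h()].
#' @param eta_t Teacher learning rate.
#' @param opt_state Optimizer state (fresh when `NULL`).
#' @param lambda Consistency weight; when positive, `weak`/`strong` views
#'   must be supplied.
#' @param weak,strong Optional view batches for the consistency term.
#' @param tau Confidence threshold for the consistency mask.
#' @param momentum,weight_decay SGD parameters.
#' @param student_fresh Must be `TRUE`; the ordering guard.
#' @return List with `model`, `state`, `loss_meta`, `loss_consistency`.
#' @export
teacher_step <- function(teacher, patches, hard, h, eta_t,
                         opt_state = NULL, lambda = 0, weak = NULL,
                         strong = NULL, tau = 0.65, momentum = 0.9,
                         weight_decay = 1e-4, student_fresh = TRUE) {
  if (!isTRUE(student_fresh))
    ipb_error("teacher_step called before the student update (stale student)",
              "ipb_contract_violation")
  inputs <- as_model_inputs(teacher$cfg, patches)
  fw <- nn_forward(teacher, inputs, training = TRUE)
  teacher <- fw$model
  ce <- ce_loss(fw$logits, one_hot(hard, teacher$cfg$num_classes))
  grads <- grads_scale(nn_backward(teacher, fw$caches, ce$dlogits), h)
  closs <- 0
  if (lambda > 0) {
    if (is.null(weak) || is.null(strong))
      invalid_argument("lambda > 0 requires weak and strong views")
    cl <- consistency_loss(teacher, weak, strong, tau)
    grads <- grads_add(grads, grads_scale(cl$grads, lambda))
    closs <- cl$loss
  }
  if (is.null(opt_state)) opt_state <- sgd_init(teacher)
  up <- sgd_step(teacher, grads, opt_state, eta_t, momentum, weight_decay)
  list(model = up$model, state = up$state, loss_meta = ce$loss,
       loss_consistency = closs)
}

#' Run iterative pseudo-balancing training
#'
#' The full loop: per epoch, sample one random in-mask patch per
#' unlabeled image, pseudo-label with the teacher, drop labels below
#' `tau`, estimate class proportions, draw `|U|` items from the
#' inverse-proportion multinomial (uniform over kept items when
#' `balance = FALSE`, the plain meta-pseudo-label baseline), and iterate
#' student/teacher steps over minibatches.  The student learning rate
#' ramps linearly over the first `warmup_epochs`.  After each epoch the
#' student is scored on deterministic patches of the labeled set and the
#' best student is retained.  An epoch with no kept pseudo-labels falls
#' back to soft-label training for the student (teacher unchanged) with
#' a warning.
#'
#' @param unlabeled,labeled `ipb_task` objects with disjoint images;
#'   `labeled` must carry labels.
#' @param arch An [arch_config()].
#' @param cfg An [train_config()].
#' @param seed Integer seed; the run is deterministic in (cfg, seed).
#' @param balance Enable pseudo-balancing (default `TRUE`).
#' @param teacher Optional pre-trained teacher; pre-trained here when
#'   `NULL`.
#' @param epochs Override for `cfg$ipb_epochs`.
#' @return An `ipb_train_state`: list with `teacher`, `student`,
#'   `best_student`, `best_acc`, `trace` (per-epoch data.frame with
#'   `epoch`, `loss_s`, `loss_t`, `sel_acc`) and `p_trace` (per-epoch
#'   estimated class proportions, epochs x m).
#' @export
run_ipb <- function(unlabeled, labeled, arch, cfg = train_config(),
                    seed = 1L, balance = TRUE, teacher = NULL,
                    epochs = NULL) {
  m <- arch$num_classes
  if (is.null(epochs)) epochs <- cfg$ipb_epochs
  if (is.null(teacher))
    teacher <- pretrain_teacher(labeled, arch, cfg, seed = seed)
  student <- build_model(arch, seed = derive_seed(seed, "student_init"))
  if (epochs == 0L) {
    return(structure(list(teacher = teacher, student = student,
                          best_student = student, best_acc = NA_real_,
                          trace = data.frame(), p_trace = NULL, cfg = cfg),
                     class = "ipb_train_state"))
  }
  opt_s <- sgd_init(student)
  opt_t <- sgd_init(teacher)
  n_u <- unlabeled$n
  trace <- data.frame(epoch = integer(), loss_s = numeric(),
                      loss_t = numeric(), sel_acc = numeric())
  p_trace <- matrix(NA_real_, epochs, m)
  best_acc <- -Inf; best_student <- student
  eval_patches_l <- task_eval_patches(labeled)

  with_seed(derive_seed(seed, "ipb"), {
    for (e in seq_len(epochs)) {
      lr_s <- cfg$eta_s * min(1, e / max(1L, cfg$warmup_epochs))
      patches_u <- task_patches(unlabeled, seq_len(n_u))
      ps <- assign_pseudo_labels(teacher, patches_u, cfg$tau)
      soft_epoch <- FALSE
      dist <- tryCatch(estimate_distribution(ps, m),
                       ipb_empty_epoch = function(cnd) NULL)
      if (is.null(dist)) {
        warning(sprintf("epoch %d: no confident pseudo-labels; %s", e,
                        "falling back to soft-label batches"),
                call. = FALSE)
        soft_epoch <- TRUE
        idx <- sample.int(n_u, n_u, replace = TRUE)
      } else if (balance) {
        idx <- balanced_resample(ps, dist, n_u)
      } else {
        kept_idx <- which(ps$kept)
        idx <- kept_idx[sample.int(length(kept_idx), n_u, replace = TRUE)]
      }
      if (!soft_epoch) p_trace[e, ] <- dist$p

      losses_s <- c(); losses_t <- c()
      for (chunk in batch_chunks(idx, cfg$batch_size)) {
        pb <- patches_u[chunk]
        targets <- if (soft_epoch) ps$probs[chunk, , drop = FALSE]
                   else ps$hard[chunk]
        st <- student_step(student, pb, targets, lr_s, opt_s,
                           momentum = cfg$momentum,
                           weight_decay = cfg$weight_decay,
                           num_classes = m)
        student <- st$model; opt_s <- st$state
        losses_s <- c(losses_s, st$loss)

        # labeled batch for the meta-update of the teacher
        li <- sample.int(labeled$n, min(cfg$batch_size, labeled$n))
        lp <- task_patches(labeled, li)
        lfw <- nn_forward(student, as_model_inputs(student$cfg, lp),
                          training = TRUE)
        student <- lfw$model
        lce <- ce_loss(lfw$logits, one_hot(labeled$labels[li], m))
        losses_t <- c(losses_t, lce$loss)
        if (!soft_epoch) {
          g_l <- nn_backward(student, lfw$caches, lce$dlogits)
          h <- mpl_h(g_l, st$grads, lr_s)
          views <- NULL
          if (cfg$lambda > 0) {
            weak <- task_patches(unlabeled, chunk, augment = FALSE)
            views <- list(weak = weak, strong = pb)
          }
          tt <- teacher_step(teacher, pb, ps$hard[chunk], h, cfg$eta_t,
                             opt_t, lambda = cfg$lambda,
                             weak = views$weak, strong = views$strong,
                             tau = cfg$tau, momentum = cfg$momentum,
                             weight_decay = cfg$weight_decay)
          teacher <- tt$model; opt_t <- tt$state
        }
      }
      acc <- selection_accuracy(student, eval_patches_l, labeled$labels)
      if (acc > best_acc) { best_acc <- acc; best_student <- student }
      trace <- rbind(trace, data.frame(epoch = e, loss_s = mean(losses_s),
                                       loss_t = mean(losses_t),
                                       sel_acc = acc))
    }
  })
  structure(list(teacher = teacher, student = student,
                 best_student = best_student, best_acc = best_acc,
                 trace = trace, p_trace = p_trace, cfg = cfg),
            class = "ipb_train_state")
}

selection_accuracy <- function(model, eval_patches, labels) {
  probs <- forward_probs(model, eval_patches)
  mean(max.col(probs, ties.method = "first") == labels)
}
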
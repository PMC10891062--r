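# Exact one-step meta-gradient for the teacher update.
#
# With SOFT pseudo-labels the student's loss L_S(theta_S; theta_T) =
# (1/N) sum_j sum_k pT_jk * (-log pS_jk) is differentiable in the teacher
# parameters, and after one plain student step
#   theta_S' = theta_S - eta_S * grad_{theta_S} L_S
# the labeled loss L_l(theta_S') has the exact teacher gradient
#   d L_l / d theta_T
#     = -eta_S * grad_{theta_T} (1/N) sum_jk pT_jk * a_jk,
#   a_jk = < g_l , grad_{theta_S} (-log pS_jk) >,   g_l = grad L_l(theta_S').
# The a_jk are treated as constants of theta_T; backpropagating the
# per-item weights a_j/N through the teacher softmax gives the gradient.
# This is the quantity the practical first-order signal h (see mpl_h)
# approximates; both routes are available, and the exact route is
# validated against finite differences.

#' Exact meta-gradient of the teacher parameters (soft pseudo-labels)
#'
#' Computes the exact gradient of the updated student's labeled-set
#' cross-entropy with respect to the teacher parameters for a single
#' plain (no momentum) student step on soft pseudo-labels.  Cost is one
#' backward pass per (item, class) pair, so use small batches.
#'
#' @param teacher,student `ipb_model` objects.
#' @param pseudo_patches Unlabeled batch (any form accepted by
#'   [forward_probs()]).
#' @param labeled_patches,labeled_labels Labeled batch and hard labels.
#' @param eta_s Student step size.
#' @return List with `grads` (teacher gradient tree), `loss_after`
#'   (labeled loss at the updated student) and `student_updated`.
#' @export
meta_teacher_grad_exact <- function(teacher, student, pseudo_patches,
                                    labeled_patches, labeled_labels,
                                    eta_s) {
  m <- teacher$cfg$num_classes
  inputs_u <- as_model_inputs(teacher$cfg, pseudo_patches)
  tfw <- nn_forward(teacher, inputs_u, training = TRUE)
  pT <- softmax_mat(tfw$logits)
  n <- nrow(pT)

  # student step on soft labels (plain SGD, no momentum/decay: the
  # closed-form chain rule below assumes theta' linear in the gradient)
  sfw <- nn_forward(student, inputs_u, training = TRUE)
  ce <- ce_loss(sfw$logits, pT)
  g_s <- nn_backward(student, sfw$caches, ce$dlogits)
  student2 <- student
  for (nm in names(g_s)) for (p in names(g_s[[nm]]))
    student2$layers[[nm]][[p]] <-
      student2$layers[[nm]][[p]] - eta_s * g_s[[nm]][[p]]

  # labeled gradient at the updated student
  inputs_l <- as_model_inputs(student$cfg, labeled_patches)
  lfw <- nn_forward(student2, inputs_l, training = TRUE)
  lce <- ce_loss(lfw$logits, one_hot(labeled_labels, m))
  g_l <- nn_backward(student2, lfw$caches, lce$dlogits)

  # a_jk = <g_l, grad_{theta_S}(-log pS_jk)> via one backward per (j,k)
  pS <- softmax_mat(sfw$logits)
  A <- matrix(0, n, m)
  for (j in seq_len(n)) {
    for (k in seq_len(m)) {
      dlog <- matrix(0, n, m)
      dlog[j, ] <- pS[j, ]
      dlog[j, k] <- dlog[j, k] - 1
      gjk <- nn_backward(student, sfw$caches, dlog)
      A[j, k] <- grads_dot(g_l, gjk)
    }
  }
  # teacher gradient: -eta_s * d/dtheta_T (1/n) sum_jk pT_jk A_jk;
  # per-item softmax backward with weights A_j / n
  W <- A / n
  dlogits_t <- pT * (W - rowSums(pT * W))
  grads <- grads_scale(nn_backward(teacher, tfw$caches, dlogits_t), -eta_s)
  list(grads = grads, loss_after = lce$loss, student_updated = student2)
}

# labeled loss after a one-step soft-label student update, as a function
# of a perturbed teacher; the finite-difference closure for the test
meta_labeled_loss <- function(teacher, student, pseudo_patches,
                              labeled_patches, labeled_labels, eta_s) {
  m <- teacher$cfg$num_classes
  inputs_u <- as_model_inputs(teacher$cfg, pseudo_patches)
  pT <- softmax_mat(nn_forward(teacher, inputs_u, training = TRUE)$logits)
  sfw <- nn_forward(student, inputs_u, training = TRUE)
  ce <- ce_loss(sfw$logits, pT)
  g_s <- nn_backward(student, sfw$caches, ce$dlogits)
  student2 <- student
  for (nm in names(g_s)) for (p in names(g_s[[nm]]))
    student2$layers[[nm]][[p]] <-
      student2$layers[[nm]][[p]] - eta_s * g_s[[nm]][[p]]
  inputs_l <- as_model_inputs(student$cfg, labeled_patches)
  lfw <- nn_forward(student2, inputs_l, training = TRUE)
  ce_loss(lfw$logits, one_hot(labeled_labels, m))$loss
}

#' One-parameter meta-gradient toy
#'
#' The minimal instance of the teacher update: a scalar teacher
#' `pT1 = sigmoid(theta_T * x_u)` soft-labels one unlabeled point, a
#' scalar student `pS1 = sigmoid(theta_S * x)` takes one plain gradient
#' step on the soft cross-entropy, and the teacher gradient of the
#' updated student's labeled loss is computed with the same per-class
#' chain rule as [meta_teacher_grad_exact()].  `loss_fn` re-runs the
#' whole pipeline for a perturbed teacher parameter, which is the
#' independent finite-difference oracle.
#'
#' @param theta_t,theta_s Scalar teacher/student parameters.
#' @param x_u,x_l Scalar unlabeled/labeled inputs.
#' @param y_l Labeled target in `{0, 1}` (class-1 indicator).
#' @param eta_s Student step size.
#' @return List with `grad` (d labeled-loss / d theta_t), `loss` and
#'   `loss_fn(theta_t)`.
#' @export
toy_meta_gradient <- function(theta_t, theta_s, x_u, x_l, y_l, eta_s) {
  sigmoid <- function(z) 1 / (1 + exp(-z))
  pipeline <- function(tt) {
    pT1 <- sigmoid(tt * x_u)
    pS1 <- sigmoid(theta_s * x_u)
    gs <- x_u * (pS1 - pT1)               # d L_S / d theta_s (soft CE)
    ts2 <- theta_s - eta_s * gs
    q <- sigmoid(ts2 * x_l)
    -(y_l * log(q) + (1 - y_l) * log(1 - q))
  }
  pT1 <- sigmoid(theta_t * x_u)
  pS1 <- sigmoid(theta_s * x_u)
  gs <- x_u * (pS1 - pT1)
  ts2 <- theta_s - eta_s * gs
  q <- sigmoid(ts2 * x_l)
  g_l <- x_l * (q - y_l)                  # d L_l / d theta_s'
  # per-class student gradients of -log pS_k and their projections
  a1 <- g_l * (-x_u * (1 - pS1))
  a2 <- g_l * (x_u * pS1)
  dpT1 <- x_u * pT1 * (1 - pT1)
  grad <- -eta_s * dpT1 * (a1 - a2)
  list(grad = grad, loss = pipeline(theta_t), loss_fn = pipeline)
}
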
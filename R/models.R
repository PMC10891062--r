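# Classifier architectures.
#
# All architectures share one pattern: one or more convolutional streams
# (each conv is 3x3, stride 1 pad 1, or stride 2 pad 1 for downsampling,
# and is followed by batch normalisation and ReLU), global average
# pooling per stream, feature concatenation, batch normalisation of the
# concatenated vector, then a fully connected head with ReLU between
# layers.  Global average pooling makes the patch size configurable,
# which is what lets the tiny test-scale variants train in seconds.

#' Architecture configuration
#'
#' @param arch One of `"dual_stream_vgg"` (two VGG-style streams on the
#'   224/112 multi-scale pair, 512 features per stream), `"compact_hires"`
#'   (a compact high-resolution net: two parallel-resolution branches over
#'   one input, 10 convolutional + 5 fully connected layers),
#'   `"single_128"` (one stream on 128x128 patches), `"tiny_test"`
#'   (dual-stream, 2 convs per stream at width 16, inputs 32/16) or
#'   `"tiny_single"` (one tiny stream).
#' @param num_classes Number of output classes (default 4).
#' @param in_channels Input channels (default 1, grayscale).
#' @return An object of class `ipb_arch`.
#' @export
arch_config <- function(arch = c("dual_stream_vgg", "compact_hires",
                                 "single_128", "tiny_test", "tiny_single"),
                        num_classes = 4L, in_channels = 1L) {
  arch <- match.arg(arch)
  stream <- function(input, out, stride) {
    if (length(out) != length(stride))
      invalid_argument("conv widths and strides must have equal length")
    list(input = input, out = as.integer(out), stride = as.integer(stride))
  }
  spec <- switch(arch,
    dual_stream_vgg = list(
      streams = list(stream(1L, c(64, 64, 128, 128, 256, 256, 512, 512),
                            c(1, 2, 1, 2, 1, 2, 1, 2)),
                     stream(2L, c(64, 64, 128, 128, 256, 256, 512, 512),
                            c(1, 2, 1, 2, 1, 2, 1, 2))),
      head = c(512L, num_classes),
      input_sizes = c(224L, 112L), scale_mode = "dual224_112"),
    compact_hires = list(
      streams = list(stream(1L, c(32, 64, 64, 128, 128), c(1, 2, 1, 2, 1)),
                     stream(1L, c(32, 64, 64, 128, 128), c(2, 1, 2, 1, 1))),
      head = c(256L, 128L, 64L, 32L, num_classes),
      input_sizes = 128L, scale_mode = "single128"),
    single_128 = list(
      streams = list(stream(1L, c(64, 64, 128, 128, 256, 256, 512, 512),
                            c(1, 2, 1, 2, 1, 2, 1, 2))),
      head = c(512L, num_classes),
      input_sizes = 128L, scale_mode = "single128"),
    tiny_test = list(
      streams = list(stream(1L, c(16, 16), c(2, 2)),
                     stream(2L, c(16, 16), c(2, 2))),
      head = c(num_classes),
      input_sizes = c(32L, 16L), scale_mode = "dual224_112"),
    tiny_single = list(
      streams = list(stream(1L, c(16, 16), c(2, 2))),
      head = c(num_classes),
      input_sizes = 32L, scale_mode = "single128"))
  structure(c(list(arch = arch, num_classes = as.integer(num_classes),
                   in_channels = as.integer(in_channels)), spec),
            class = "ipb_arch")
}

#' Build a Kaiming-initialised model
#'
#' Convolution and dense weights draw from `N(0, sqrt(2 / fan_in))`
#' (Kaiming/He initialisation for ReLU networks); biases are zero,
#' batch-norm scales one, shifts zero.  Deterministic in `seed`.
#'
#' @param cfg An [arch_config()] object.
#' @param seed Integer seed.
#' @return An object of class `ipb_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  if (!inherits(cfg, "ipb_arch")) invalid_argument("`cfg` must be ipb_arch")
  with_seed(seed, {
    layers <- list()
    streams <- list()
    for (s in seq_along(cfg$streams)) {
      st <- cfg$streams[[s]]
      cin <- cfg$in_channels
      ids <- character(0)
      for (i in seq_along(st$out)) {
        cout <- st$out[i]
        cid <- sprintf("s%d_conv%d", s, i)
        bid <- sprintf("s%d_bn%d", s, i)
        layers[[cid]] <- list(
          kind = "conv",
          W = array(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                    c(3L, 3L, cin, cout)),
          b = numeric(cout), stride = st$stride[i], pad = 1L)
        layers[[bid]] <- list(kind = "bn", gamma = rep(1, cout),
                              beta = numeric(cout), rm = numeric(cout),
                              rv = rep(1, cout))
        ids <- c(ids, cid, bid, paste0(cid, "_relu"))
        layers[[paste0(cid, "_relu")]] <- list(kind = "relu")
        cin <- cout
      }
      streams[[s]] <- ids
    }
    widths <- vapply(cfg$streams, function(st) st$out[length(st$out)], 0L)
    feat <- sum(widths)
    layers[["head_bn"]] <- list(kind = "bn", gamma = rep(1, feat),
                                beta = numeric(feat), rm = numeric(feat),
                                rv = rep(1, feat))
    head_ids <- "head_bn"
    fin <- feat
    for (i in seq_along(cfg$head)) {
      fout <- cfg$head[i]
      fid <- sprintf("fc%d", i)
      layers[[fid]] <- list(
        kind = "dense",
        W = matrix(stats::rnorm(fin * fout, 0, sqrt(2 / fin)), fin, fout),
        b = numeric(fout))
      head_ids <- c(head_ids, fid)
      if (i < length(cfg$head)) {
        layers[[paste0(fid, "_relu")]] <- list(kind = "relu")
        head_ids <- c(head_ids, paste0(fid, "_relu"))
      }
      fin <- fout
    }
    structure(list(cfg = cfg, layers = layers, streams = streams,
                   head = head_ids, stream_widths = widths),
              class = "ipb_model")
  })
}

#' Count trainable parameters
#' @param model An `ipb_model`.
#' @return Integer parameter count (weights, biases, batch-norm scale and
#'   shift; running statistics excluded).
#' @export
param_count <- function(model) {
  n <- 0L
  for (ly in model$layers) {
    n <- n + switch(ly$kind,
                    conv = length(ly$W) + length(ly$b),
                    dense = length(ly$W) + length(ly$b),
                    bn = length(ly$gamma) + length(ly$beta),
                    relu = 0L)
  }
  n
}

# forward pass; inputs = list of (H,W,C,N) arrays, one per distinct input.
# Returns logits, per-layer caches, and (in training mode) the model with
# updated batch-norm running statistics.
nn_forward <- function(model, inputs, training = FALSE) {
  if (!is.list(inputs)) inputs <- list(inputs)
  caches <- list()
  feats <- list()
  for (s in seq_along(model$streams)) {
    x <- inputs[[model$cfg$streams[[s]]$input]]
    if (is.null(x)) invalid_argument("missing input for stream")
    if (dim(x)[3] != model$cfg$in_channels)
      invalid_argument("input channel count does not match architecture")
    for (id in model$streams[[s]]) {
      ly <- model$layers[[id]]
      if (ly$kind == "conv") {
        cf <- conv_forward(x, ly$W, ly$b, ly$stride, ly$pad)
        x <- cf$out
        caches[[id]] <- cf$cache
      } else if (ly$kind == "bn") {
        d <- dim(x)
        bf <- bn_forward_mat(chan_to_mat(x), ly$gamma, ly$beta, ly$rm,
                             ly$rv, training)
        x <- mat_to_chan(bf$out, d)
        caches[[id]] <- c(bf$cache, list(dims = d))
        if (training) {
          model$layers[[id]]$rm <- bf$rm
          model$layers[[id]]$rv <- bf$rv
        }
      } else { # relu
        caches[[id]] <- list(mask = x > 0)
        x <- x * caches[[id]]$mask
      }
    }
    gp <- gap_forward(x)
    caches[[paste0("gap", s)]] <- gp$cache
    feats[[s]] <- gp$out
  }
  Hc <- do.call(cbind, feats)
  for (id in model$head) {
    ly <- model$layers[[id]]
    if (ly$kind == "bn") {
      bf <- bn_forward_mat(Hc, ly$gamma, ly$beta, ly$rm, ly$rv, training)
      Hc <- bf$out
      caches[[id]] <- bf$cache
      if (training) {
        model$layers[[id]]$rm <- bf$rm
        model$layers[[id]]$rv <- bf$rv
      }
    } else if (ly$kind == "dense") {
      caches[[id]] <- list(x = Hc)
      Hc <- Hc %*% ly$W
      Hc <- Hc + rep(ly$b, each = nrow(Hc))
    } else {
      caches[[id]] <- list(mask = Hc > 0)
      Hc <- Hc * caches[[id]]$mask
    }
  }
  list(logits = Hc, caches = caches, model = model)
}

# backward pass from dlogits; returns per-layer gradient list
nn_backward <- function(model, caches, dlogits) {
  grads <- list()
  g <- dlogits
  for (id in rev(model$head)) {
    ly <- model$layers[[id]]
    if (ly$kind == "dense") {
      grads[[id]] <- list(W = crossprod(caches[[id]]$x, g), b = colSums(g))
      g <- tcrossprod(g, ly$W)
    } else if (ly$kind == "bn") {
      bb <- bn_backward_mat(g, caches[[id]])
      grads[[id]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
      g <- bb$dM
    } else {
      g <- g * caches[[id]]$mask
    }
  }
  # split concatenated features back into streams
  offs <- cumsum(c(0L, model$stream_widths))
  for (s in seq_along(model$streams)) {
    gs <- g[, (offs[s] + 1L):offs[s + 1L], drop = FALSE]
    d <- caches[[paste0("gap", s)]]
    gx <- gap_backward(gs, d)
    for (id in rev(model$streams[[s]])) {
      ly <- model$layers[[id]]
      if (ly$kind == "conv") {
        cb <- conv_backward(gx, ly$W, caches[[id]])
        grads[[id]] <- list(W = cb$dW, b = cb$db)
        gx <- cb$dx
      } else if (ly$kind == "bn") {
        dd <- caches[[id]]$dims
        bb <- bn_backward_mat(chan_to_mat(gx), caches[[id]])
        grads[[id]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
        gx <- mat_to_chan(bb$dM, dd)
      } else {
        gx <- gx * caches[[id]]$mask
      }
    }
  }
  grads
}

#' Class probabilities for a batch
#'
#' Evaluation-mode forward pass (batch-norm running statistics, no
#' augmentation) followed by softmax; deterministic.
#'
#' @param model An `ipb_model`.
#' @param batch List of input arrays `(H, W, C, N)` (one per stream
#'   input), a single array, a list of `ipb_patch` objects, or a list of
#'   plain matrices.
#' @return `N x m` matrix of probabilities; rows sum to 1.
#' @export
forward_probs <- function(model, batch) {
  inputs <- as_model_inputs(model$cfg, batch)
  softmax_mat(nn_forward(model, inputs, training = FALSE)$logits)
}

# coerce the accepted batch forms into the list-of-arrays the model eats
as_model_inputs <- function(cfg, batch) {
  if (is.array(batch) && length(dim(batch)) == 4) return(list(batch))
  if (!is.list(batch)) invalid_argument("unsupported batch type")
  if (length(batch) && inherits(batch[[1]], "ipb_patch")) {
    coarse <- stack_images(lapply(batch, `[[`, "coarse"))
    if (!is.null(batch[[1]]$fine)) {
      return(list(coarse, stack_images(lapply(batch, `[[`, "fine"))))
    }
    return(list(coarse))
  }
  if (length(batch) && is.matrix(batch[[1]]))
    return(list(stack_images(batch)))
  batch  # already a list of arrays
}

#' Stack grayscale matrices into a batch array
#' @param imgs List of equally sized numeric matrices.
#' @return Array with dim `(H, W, 1, N)`.
#' @export
stack_images <- function(imgs) {
  h <- nrow(imgs[[1]]); w <- ncol(imgs[[1]])
  array(unlist(imgs, use.names = FALSE), c(h, w, 1L, length(imgs)))
}

# ---- SGD with momentum and weight decay ---------------------------------

sgd_init <- function(model) {
  v <- list()
  for (nm in names(model$layers)) {
    ly <- model$layers[[nm]]
    v[[nm]] <- switch(ly$kind,
      conv = list(W = array(0, dim(ly$W)), b = numeric(length(ly$b))),
      dense = list(W = matrix(0, nrow(ly$W), ncol(ly$W)),
                   b = numeric(length(ly$b))),
      bn = list(gamma = numeric(length(ly$gamma)),
                beta = numeric(length(ly$beta))),
      relu = NULL)
  }
  v
}

# v <- mom*v + g + wd*p ; p <- p - lr*v   (decay skipped for biases/BN)
sgd_step <- function(model, grads, state, lr, momentum = 0.9,
                     weight_decay = 1e-4) {
  for (nm in names(grads)) {
    for (p in names(grads[[nm]])) {
      g <- grads[[nm]][[p]]
      if (!all(is.finite(g)))
        stopf("non-finite gradient in layer %s/%s", nm, p)
      if (p == "W") g <- g + weight_decay * model$layers[[nm]][[p]]
      vv <- momentum * state[[nm]][[p]] + g
      state[[nm]][[p]] <- vv
      model$layers[[nm]][[p]] <- model$layers[[nm]][[p]] - lr * vv
    }
  }
  list(model = model, state = state)
}
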
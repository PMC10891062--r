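# Minimal CNN engine: forward/backward passes for the layer types the
# classifier architectures need, written with base-R matrix algebra.
#
# Batches are 4-D arrays dim (H, W, C, N); dense activations are N x F
# matrices.  Convolution uses im2col with cached index maps, so the inner
# loop is a single BLAS matmul.  Backward passes return gradients in the
# same shapes as the parameters.

.im2col_cache <- new.env(parent = emptyenv())

# index map for im2col on a (H, W, C) image with given kernel/stride/pad;
# columns are ordered (di fastest, then dj, then channel) to match R's
# flattening of a (k, k, Cin, Cout) weight array
im2col_index <- function(h, w, c, k, stride, pad) {
  key <- paste(h, w, c, k, stride, pad, sep = "_")
  if (!is.null(.im2col_cache[[key]])) return(.im2col_cache[[key]])
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (hp - k) %/% stride + 1L; wo <- (wp - k) %/% stride + 1L
  oi <- rep(seq_len(ho), times = wo)
  oj <- rep(seq_len(wo), each = ho)
  base <- (oi - 1L) * stride + ((oj - 1L) * stride) * hp
  kk <- expand.grid(di = seq_len(k), dj = seq_len(k), ch = seq_len(c))
  off <- kk$di + (kk$dj - 1L) * hp + (kk$ch - 1L) * hp * wp
  idx <- outer(base, off, `+`)          # (ho*wo) x (k*k*c)
  res <- list(idx = as.integer(idx), ho = ho, wo = wo, hp = hp, wp = wp,
              ncols = k * k * c)
  .im2col_cache[[key]] <- res
  res
}

conv_forward <- function(x, W, b, stride = 1L, pad = 1L) {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]; n <- d[4]
  k <- dim(W)[1]; cout <- dim(W)[4]
  ix <- im2col_index(h, w, cin, k, stride, pad)
  xp <- array(0, c(ix$hp, ix$wp, cin, n))
  xp[pad + seq_len(h), pad + seq_len(w), , ] <- x
  dim(xp) <- c(ix$hp * ix$wp * cin, n)
  colsn <- xp[ix$idx, , drop = FALSE]           # (howo*ncols) x n
  dim(colsn) <- c(ix$ho * ix$wo, ix$ncols, n)
  A <- aperm(colsn, c(1, 3, 2))                 # (howo, n, ncols)
  dim(A) <- c(ix$ho * ix$wo * n, ix$ncols)
  Wm <- matrix(W, ix$ncols, cout)
  out <- A %*% Wm
  out <- out + rep(b, each = nrow(out))
  dim(out) <- c(ix$ho, ix$wo, n, cout)
  out <- aperm(out, c(1, 2, 4, 3))              # (ho, wo, cout, n)
  list(out = out, cache = list(A = A, ix = ix, dims = d, k = k,
                               cout = cout, stride = stride, pad = pad))
}

conv_backward <- function(dout, W, cache) {
  ix <- cache$ix; d <- cache$dims
  h <- d[1]; w <- d[2]; cin <- d[3]; n <- d[4]
  cout <- cache$cout; pad <- cache$pad
  G <- aperm(dout, c(1, 2, 4, 3))               # (ho, wo, n, cout)
  dim(G) <- c(ix$ho * ix$wo * n, cout)
  Wm <- matrix(W, ix$ncols, cout)
  dW <- crossprod(cache$A, G)                   # ncols x cout
  db <- colSums(G)
  dA <- tcrossprod(G, Wm)                       # (howo*n) x ncols
  dim(dA) <- c(ix$ho * ix$wo, n, ix$ncols)
  dA <- aperm(dA, c(1, 3, 2))                   # (howo, ncols, n)
  dim(dA) <- c(ix$ho * ix$wo * ix$ncols, n)
  agg <- rowsum(dA, group = ix$idx)             # scatter-add by index
  dxp <- matrix(0, ix$hp * ix$wp * cin, n)
  dxp[as.integer(rownames(agg)), ] <- agg
  dim(dxp) <- c(ix$hp, ix$wp, cin, n)
  dx <- dxp[pad + seq_len(h), pad + seq_len(w), , , drop = FALSE]
  dim(dx) <- d
  list(dx = dx, dW = array(dW, dim(W)), db = db)
}

# batchnorm over a (rows) x C matrix view; conv inputs are reshaped so
# rows = H*W*N, dense inputs so rows = N
bn_forward_mat <- function(M, gamma, beta, rm, rv, training,
                           momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(M)
    va <- colMeans(M^2) - mu^2
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * va
  } else {
    mu <- rm; va <- rv
  }
  istd <- 1 / sqrt(va + eps)
  nr <- nrow(M)
  xhat <- (M - rep(mu, each = nr)) * rep(istd, each = nr)
  out <- xhat * rep(gamma, each = nr) + rep(beta, each = nr)
  list(out = out, cache = list(xhat = xhat, istd = istd, gamma = gamma),
       rm = rm, rv = rv)
}

bn_backward_mat <- function(dout, cache) {
  xhat <- cache$xhat; istd <- cache$istd; gamma <- cache$gamma
  nr <- nrow(dout)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(gamma, each = nr)
  t1 <- dxhat - rep(colSums(dxhat) / nr, each = nr)
  t2 <- xhat * rep(colSums(dxhat * xhat) / nr, each = nr)
  dM <- (t1 - t2) * rep(istd, each = nr)
  list(dM = dM, dgamma = dgamma, dbeta = dbeta)
}

# reshape helpers between (H,W,C,N) arrays and (H*W*N) x C matrices
chan_to_mat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

mat_to_chan <- function(m, d) {
  dim(m) <- c(d[1], d[2], d[4], d[3])
  aperm(m, c(1, 2, 4, 3))
}

gap_forward <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  cm <- colMeans(m)                             # length C*N
  list(out = t(matrix(cm, d[3], d[4])), cache = d)  # N x C
}

gap_backward <- function(dout, d) {
  # dout: N x C -> spread evenly over H*W
  g <- t(dout) / (d[1] * d[2])                  # C x N
  x <- array(rep(as.vector(g), each = d[1] * d[2]), d)
  x
}

softmax_mat <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy against target distribution rows; returns loss and
# dlogits for the mean reduction
ce_loss <- function(logits, targets) {
  p <- softmax_mat(logits)
  n <- nrow(logits)
  loss <- -sum(targets * log(pmax(p, 1e-12))) / n
  list(loss = loss, dlogits = (p - targets) / n, probs = p)
}

one_hot <- function(labels, m) {
  out <- matrix(0, length(labels), m)
  out[cbind(seq_along(labels), labels)] <- 1
  out
}

# ---- gradient-tree utilities --------------------------------------------

grads_dot <- function(g1, g2) {
  s <- 0
  for (nm in names(g1)) {
    for (p in names(g1[[nm]])) {
      s <- s + sum(g1[[nm]][[p]] * g2[[nm]][[p]])
    }
  }
  s
}

grads_scale <- function(g, a) {
  for (nm in names(g)) for (p in names(g[[nm]])) g[[nm]][[p]] <- g[[nm]][[p]] * a
  g
}

grads_add <- function(g1, g2) {
  for (nm in names(g2)) {
    for (p in names(g2[[nm]])) {
      if (is.null(g1[[nm]][[p]])) g1[[nm]][[p]] <- g2[[nm]][[p]]
      else g1[[nm]][[p]] <- g1[[nm]][[p]] + g2[[nm]][[p]]
    }
  }
  g1
}
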
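# Neural-network primitives: valid 2-D convolution (im2col + BLAS GEMM in
# compiled code), strided max pooling, dense layers, and Adam. Gradients
# are hand-derived and verified against finite differences in the test
# suite.

# x: array (H, W, C, B). w_mat: (kh*kw*C, F) with patch entries ordered
# frame-offset fastest, then band offset, then channel. Returns
# list(out = (OH, OW, F, B) [, col]); col is kept for the weight-gradient
# GEMM during training.
conv2d_forward <- function(x, w_mat, bias, kh = 5L, kw = 5L,
                           want_col = TRUE, relu = FALSE) {
  if (!is.matrix(w_mat)) w_mat <- as.matrix(w_mat)
  cpp_conv2d(x, dim(x), w_mat, bias, kh, kw, want_col, relu)
}

conv2d_backward <- function(dout, col, w_mat, kh, kw, in_channels,
                            need_dx = TRUE) {
  od <- dim(dout)
  B <- od[4]
  npos <- od[1] * od[2]
  dmat <- matrix(aperm(dout, c(1, 2, 4, 3)), nrow = npos * B, ncol = od[3])
  dW <- crossprod(col, dmat)
  db <- colSums(dmat)
  dX <- NULL
  if (need_dx) {
    # full correlation of dout with the flipped kernel
    padded <- array(0, dim = c(od[1] + 2 * (kh - 1), od[2] + 2 * (kw - 1),
                               od[3], B))
    padded[kh:(kh + od[1] - 1), kw:(kw + od[2] - 1), , ] <- dout
    w4 <- array(w_mat, dim = c(kh, kw, in_channels, od[3]))
    wrot <- aperm(w4[kh:1, kw:1, , , drop = FALSE], c(1, 2, 4, 3))
    wrot_mat <- matrix(wrot, nrow = kh * kw * od[3], ncol = in_channels)
    dX <- conv2d_forward(padded, wrot_mat, numeric(in_channels), kh, kw,
                         want_col = FALSE)$out
  }
  list(dW = dW, db = db, dX = dX)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Max pooling with receptive field (ph, pw), stride equal to the field
# (non-overlapping); trailing rows/columns that do not fill a full field
# are dropped (floor convention). With want_argmax, returns
# list(out, argmax) for the backward scatter; otherwise the pooled array.
maxpool_forward <- function(x, ph, pw, want_argmax = FALSE, row_offset = 0L,
                            n_rows = -1L) {
  r <- cpp_maxpool(x, dim(x), ph, pw, want_argmax, row_offset, n_rows)
  if (want_argmax) r else r$out
}

maxpool_backward <- function(dout, argmax, in_dim) {
  cpp_maxpool_backward(dout, argmax, as.integer(in_dim))
}

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * as.numeric(g)
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * as.numeric(g)^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    upd <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
    dim(upd) <- dim(params[[nm]])
    params[[nm]] <- upd
  }
  list(params = params, state = state)
}
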
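# Context-adaptive convolutional network for flight-call clip
# classification: a convolutional main branch embedding a 150 ms clip into
# a 64-dimensional code z, an auxiliary branch embedding a 9 x 32 slice of
# long-term quantile statistics into z_aux, and four merge formulations of
# the output layer:
#
#   baseline: y = sigmoid(b + w . z)                   (static dense layer)
#   AW:       y = sigmoid(b + z_aux . z)               (adaptive weights)
#   AT:       y = sigmoid(w_aux . z_aux + w . z)       (adaptive threshold)
#   MoE:      y = sigmoid(b + sum_k g_k sum_m w~(m,k) z~(m,k)),
#             g = softmax(b_aux + w~_aux' z~_aux),
#             reshape n = K * m + k                    (mixture of experts)

CLIP_FRAMES <- 104L

#' Context-adaptive network configuration
#'
#' Defaults reproduce the reference detector: three convolutional layers
#' (24, 24, 48 kernels of size 5x5; strided 4x2 max pooling after the
#' first two, downsampling time 16x in total), a 64-unit dense embedding
#' with L2 penalty 1e-3, and an auxiliary branch of 8 kernels of size 1x32
#' (weight sharing across quantiles only) whose 9 x 8 = 72 activations
#' feed a 64-unit dense layer. Smaller widths can be configured for
#' scaled-down experiments.
#'
#' @param formulation Output-layer merge: `"baseline"`, `"aw"`, `"at"` or
#'   `"moe"`.
#' @param conv_channels Integer vector of three convolutional widths.
#' @param n_hidden Embedding dimension N of both branches.
#' @param aux_kernels Number of 1x32 kernels in the auxiliary branch.
#' @param K Number of experts (MoE); `n_hidden` must be divisible by `K`.
#' @param l2 L2 penalty on the dense embedding weights of the main branch.
#' @param input_frames,input_bands Clip shape (frames x mel bands).
#' @param aux_quantiles,aux_bands Context-slice shape.
#' @return A list of class `canet_config`.
#' @export
canet_config <- function(formulation = c("baseline", "aw", "at", "moe"),
                         conv_channels = c(24, 24, 48), n_hidden = 64,
                         aux_kernels = 8, K = 4, l2 = 1e-3,
                         input_frames = CLIP_FRAMES, input_bands = 128,
                         aux_quantiles = 9, aux_bands = 32) {
  formulation <- match.arg(formulation)
  if (formulation == "moe" && n_hidden %% K != 0) {
    stop("n_hidden must be divisible by K for the mixture of experts")
  }
  structure(list(formulation = formulation,
                 conv_channels = as.integer(conv_channels),
                 n_hidden = as.integer(n_hidden),
                 aux_kernels = as.integer(aux_kernels), K = as.integer(K),
                 l2 = l2, input_frames = as.integer(input_frames),
                 input_bands = as.integer(input_bands),
                 aux_quantiles = as.integer(aux_quantiles),
                 aux_bands = as.integer(aux_bands),
                 pool = c(4L, 2L)),
            class = "canet_config")
}

# Spatial dimensions through the main branch (valid convolutions, floor
# pooling).
canet_shapes <- function(cfg) {
  h <- cfg$input_frames; w <- cfg$input_bands
  h1 <- h - 4L; w1 <- w - 4L
  h1p <- h1 %/% cfg$pool[1]; w1p <- w1 %/% cfg$pool[2]
  h2 <- h1p - 4L; w2 <- w1p - 4L
  h2p <- h2 %/% cfg$pool[1]; w2p <- w2 %/% cfg$pool[2]
  h3 <- h2p - 4L; w3 <- w2p - 4L
  if (h3 < 1L || w3 < 1L) stop("input too small for the architecture")
  list(c1 = c(h1, w1), p1 = c(h1p, w1p), c2 = c(h2, w2), p2 = c(h2p, w2p),
       c3 = c(h3, w3), flat = h3 * w3 * cfg$conv_channels[3])
}

#' Initialize a context-adaptive network
#'
#' Glorot-style uniform initialization of all weights, zero biases,
#' reproducible under the supplied seed.
#'
#' @param config A [canet_config()].
#' @param seed Integer seed for the weight draw.
#' @param frontend Optional frontend description stored with the model: a
#'   list with `representation` (`"logmelspec"` or `"pcen"`), `stft`
#'   (an [stft_config()]) and `pcen` (a [pcen_params()] or `NULL`). A model
#'   is only valid together with its own frontend.
#' @return An object of class `canet_model`.
#' @export
canet_init <- function(config = canet_config(), seed = 1, frontend = NULL) {
  stopifnot(inherits(config, "canet_config"))
  set.seed(seed)
  ch <- config$conv_channels
  N <- config$n_hidden
  sh <- canet_shapes(config)
  p <- list(
    W1 = glorot_uniform(25, 25 * ch[1], c(25, ch[1])),
    b1 = numeric(ch[1]),
    W2 = glorot_uniform(25 * ch[1], 25 * ch[2], c(25 * ch[1], ch[2])),
    b2 = numeric(ch[2]),
    W3 = glorot_uniform(25 * ch[2], 25 * ch[3], c(25 * ch[2], ch[3])),
    b3 = numeric(ch[3]),
    W4 = glorot_uniform(sh$flat, N, c(sh$flat, N)),
    b4 = numeric(N)
  )
  if (config$formulation != "baseline") {
    A <- config$aux_kernels
    p$Wa1 <- glorot_uniform(config$aux_bands, A, c(config$aux_bands, A))
    p$ba1 <- numeric(A)
    p$Wa2 <- glorot_uniform(config$aux_quantiles * A, N,
                            c(config$aux_quantiles * A, N))
    p$ba2 <- numeric(N)
  }
  p <- c(p, switch(config$formulation,
    baseline = list(w = glorot_uniform(N, 1, c(N)), b = 0),
    aw = list(b = 0),
    at = list(w = glorot_uniform(N, 1, c(N)),
              w_aux = glorot_uniform(N, 1, c(N))),
    moe = list(w = glorot_uniform(N, 1, c(N)), b = 0,
               w_aux_m = glorot_uniform(N %/% config$K, config$K,
                                        c(N %/% config$K, config$K)),
               b_aux = numeric(config$K))
  ))
  structure(list(config = config, params = p, frontend = frontend,
                 shapes = sh,
                 norm = list(center = 0, scale = 1, aux_center = 0,
                             aux_scale = 1)),
            class = "canet_model")
}

#' @export
print.canet_model <- function(x, ...) {
  cat(sprintf("<canet_model> %s, conv %s, N=%d%s\n",
              x$config$formulation,
              paste(x$config$conv_channels, collapse = "/"),
              x$config$n_hidden,
              if (!is.null(x$frontend)) paste0(", frontend ",
                                               x$frontend$representation) else ""))
  invisible(x)
}

check_clips <- function(model, clips) {
  if (is.matrix(clips)) clips <- array(clips, dim = c(dim(clips), 1L, 1L))
  d <- dim(clips)
  if (length(d) == 3L) {
    clips <- array(clips, dim = c(d[1], d[2], 1L, d[3]))
    d <- dim(clips)
  }
  if (d[1] != model$config$input_frames || d[2] != model$config$input_bands ||
      d[3] != 1L) {
    stop(sprintf("clip shape must be %d frames x %d bands",
                 model$config$input_frames, model$config$input_bands))
  }
  clips
}

check_slices <- function(model, slices) {
  if (is.matrix(slices)) slices <- array(slices, dim = c(dim(slices), 1L))
  d <- dim(slices)
  if (d[1] != model$config$aux_quantiles || d[2] != model$config$aux_bands) {
    stop(sprintf("context slice must be %d quantiles x %d bands",
                 model$config$aux_quantiles, model$config$aux_bands))
  }
  slices
}

forward_main_internal <- function(model, x) {
  p <- model$params
  cfg <- model$config
  B <- dim(x)[4]
  x <- standardize_input(x, model$norm$center, model$norm$scale)
  c1 <- conv2d_forward(x, p$W1, p$b1)
  a1 <- relu(c1$out)
  p1 <- maxpool_forward(a1, cfg$pool[1], cfg$pool[2], want_argmax = TRUE)
  c2 <- conv2d_forward(p1$out, p$W2, p$b2)
  a2 <- relu(c2$out)
  p2 <- maxpool_forward(a2, cfg$pool[1], cfg$pool[2], want_argmax = TRUE)
  c3 <- conv2d_forward(p2$out, p$W3, p$b3)
  a3 <- relu(c3$out)
  flat <- matrix(a3, nrow = model$shapes$flat, ncol = B)
  zpre <- crossprod(p$W4, flat) + p$b4
  z <- relu(zpre)
  list(z = z, cache = list(x = x, c1 = c1, a1 = a1, p1 = p1, c2 = c2,
                           a2 = a2, p2 = p2, c3 = c3, a3 = a3, flat = flat,
                           zpre = zpre))
}

# Main-branch codes for a dense grid of sliding windows over one
# recording. Because valid convolution is shift-covariant, the first
# convolutional layer is computed once over the whole recording and each
# window's activations are slices of it; the window-aligned 4x2 pooling
# grids fall into `pool[1]` phase classes, each pooled once per block.
# Exactly equivalent to evaluating forward_main window by window
# (verified in the tests), but ~3x cheaper on heavily overlapping grids.
sliding_main_codes <- function(model, values, starts, block = 256L) {
  p <- model$params
  cfg <- model$config
  nf <- cfg$input_frames
  nb <- ncol(values)
  ph <- cfg$pool[1]; pw <- cfg$pool[2]
  n_win <- length(starts)
  z <- matrix(0, cfg$n_hidden, n_win)
  for (b0 in seq(1L, n_win, by = block)) {
    b1 <- min(b0 + block - 1L, n_win)
    s0 <- starts[b0]; s1 <- starts[b1]
    sub <- standardize_input(values[s0:(s1 + nf - 1L), , drop = FALSE],
                             model$norm$center, model$norm$scale)
    x <- array(sub, dim = c(nrow(sub), nb, 1L, 1L))
    a1 <- conv2d_forward(x, p$W1, p$b1, want_col = FALSE, relu = TRUE)$out
    n1 <- dim(a1)[1]
    pooled <- vector("list", ph)
    for (q in seq_len(ph) - 1L) {
      k <- (n1 - q) %/% ph
      if (k < 1L) next
      pooled[[q + 1L]] <- maxpool_forward(a1, ph, pw, row_offset = q,
                                          n_rows = ph * k)
    }
    B <- b1 - b0 + 1L
    wrows <- (nf - 4L) %/% ph
    batch <- array(0, dim = c(wrows, (nb - 4L) %/% pw, cfg$conv_channels[1], B))
    for (j in seq_len(B)) {
      ls <- starts[b0 + j - 1L] - s0 + 1L
      q <- (ls - 1L) %% ph
      j0 <- (ls - 1L - q) %/% ph + 1L
      batch[, , , j] <- pooled[[q + 1L]][j0:(j0 + wrows - 1L), , , 1L]
    }
    a2 <- conv2d_forward(batch, p$W2, p$b2, want_col = FALSE, relu = TRUE)$out
    p2 <- maxpool_forward(a2, ph, pw)
    a3 <- conv2d_forward(p2, p$W3, p$b3, want_col = FALSE, relu = TRUE)$out
    flat <- matrix(a3, nrow = model$shapes$flat, ncol = B)
    z[, b0:b1] <- relu(crossprod(p$W4, flat) + p$b4)
  }
  z
}

# Inference-only main branch: fused ReLU, no column caches. Agrees with
# forward_main_internal exactly (verified in the tests).
forward_main_infer <- function(model, x) {
  p <- model$params
  cfg <- model$config
  B <- dim(x)[4]
  x <- standardize_input(x, model$norm$center, model$norm$scale)
  a1 <- conv2d_forward(x, p$W1, p$b1, want_col = FALSE, relu = TRUE)$out
  p1 <- maxpool_forward(a1, cfg$pool[1], cfg$pool[2])
  a2 <- conv2d_forward(p1, p$W2, p$b2, want_col = FALSE, relu = TRUE)$out
  p2 <- maxpool_forward(a2, cfg$pool[1], cfg$pool[2])
  a3 <- conv2d_forward(p2, p$W3, p$b3, want_col = FALSE, relu = TRUE)$out
  flat <- matrix(a3, nrow = model$shapes$flat, ncol = B)
  relu(crossprod(p$W4, flat) + p$b4)
}

backward_main_internal <- function(model, cache, dz) {
  p <- model$params
  cfg <- model$config
  dzpre <- dz * (cache$zpre > 0)
  g <- list()
  g$W4 <- cache$flat %*% t(dzpre) + 2 * cfg$l2 * p$W4
  g$b4 <- rowSums(dzpre)
  dflat <- p$W4 %*% dzpre
  da3 <- array(dflat, dim = dim(cache$a3))
  dc3 <- da3 * (cache$c3$out > 0)
  b3 <- conv2d_backward(dc3, cache$c3$col, p$W3, 5L, 5L,
                        in_channels = dim(cache$p2$out)[3])
  g$W3 <- b3$dW; g$b3 <- b3$db
  dp2 <- maxpool_backward(b3$dX, cache$p2$argmax, dim(cache$a2))
  dc2 <- dp2 * (cache$c2$out > 0)
  b2 <- conv2d_backward(dc2, cache$c2$col, p$W2, 5L, 5L,
                        in_channels = dim(cache$p1$out)[3])
  g$W2 <- b2$dW; g$b2 <- b2$db
  dp1 <- maxpool_backward(b2$dX, cache$p1$argmax, dim(cache$a1))
  dc1 <- dp1 * (cache$c1$out > 0)
  b1 <- conv2d_backward(dc1, cache$c1$col, p$W1, 5L, 5L, in_channels = 1L,
                        need_dx = FALSE)
  g$W1 <- b1$dW; g$b1 <- b1$db
  g
}

forward_aux_internal <- function(model, slices) {
  p <- model$params
  cfg <- model$config
  B <- dim(slices)[3]
  Q <- cfg$aux_quantiles
  slices <- standardize_input(slices, model$norm$aux_center,
                              model$norm$aux_scale)
  x2 <- matrix(aperm(slices, c(1, 3, 2)), nrow = Q * B, ncol = cfg$aux_bands)
  hpre <- sweep(x2 %*% p$Wa1, 2, p$ba1, `+`)   # (Q*B, A)
  h <- relu(hpre)
  harr <- array(h, dim = c(Q, B, cfg$aux_kernels))
  flat <- matrix(aperm(harr, c(1, 3, 2)), nrow = Q * cfg$aux_kernels, ncol = B)
  zpre <- crossprod(p$Wa2, flat) + p$ba2
  z_aux <- relu(zpre)
  list(z_aux = z_aux,
       cache = list(x2 = x2, hpre = hpre, flat = flat, zpre = zpre, B = B))
}

backward_aux_internal <- function(model, cache, dz_aux) {
  p <- model$params
  cfg <- model$config
  Q <- cfg$aux_quantiles
  B <- cache$B
  dzpre <- dz_aux * (cache$zpre > 0)
  g <- list()
  g$Wa2 <- cache$flat %*% t(dzpre)
  g$ba2 <- rowSums(dzpre)
  dflat <- p$Wa2 %*% dzpre                              # (Q*A, B)
  dh <- matrix(aperm(array(dflat, dim = c(Q, cfg$aux_kernels, B)),
                     c(1, 3, 2)), nrow = Q * B, ncol = cfg$aux_kernels)
  dhpre <- dh * (cache$hpre > 0)
  g$Wa1 <- crossprod(cache$x2, dhpre)
  g$ba1 <- colSums(dhpre)
  g
}

softmax <- function(a) {
  e <- exp(sweep(a, 2, apply(a, 2, max), `-`))
  sweep(e, 2, colSums(e), `/`)
}

# Merge the two branch embeddings into the pre-sigmoid activation u and a
# cache for the backward pass. z, z_aux: (N, B) matrices (z_aux NULL for
# the baseline).
merge_forward <- function(model, z, z_aux) {
  p <- model$params
  cfg <- model$config
  switch(cfg$formulation,
    baseline = list(u = as.numeric(crossprod(z, p$w)) + p$b, cache = NULL),
    aw = list(u = colSums(z_aux * z) + p$b, cache = NULL),
    at = list(u = as.numeric(crossprod(z, p$w)) +
                as.numeric(crossprod(z_aux, p$w_aux)), cache = NULL),
    moe = {
      K <- cfg$K; M <- cfg$n_hidden %/% K
      B <- ncol(z)
      # n = K * m + k  (0-based)  =>  row n+1 maps to (m, k); with k
      # fastest this is exactly a (K, M) reshape of the length-N vector.
      zt <- array(z, dim = c(K, M, B))        # [k, m, b]
      zat <- array(z_aux, dim = c(K, M, B))
      wt <- matrix(p$w, nrow = K)             # [k, m]
      # alpha(k) = b_aux(k) + sum_m w_aux_m(m, k) * z_aux~(m, k)
      wam <- t(p$w_aux_m)                     # [k, m]
      alpha <- apply(zat, 3, function(s) rowSums(wam * s)) + p$b_aux
      alpha <- matrix(alpha, nrow = K)
      gates <- softmax(alpha)
      s_k <- apply(zt, 3, function(s) rowSums(wt * s))
      s_k <- matrix(s_k, nrow = K)
      u <- p$b + colSums(gates * s_k)
      list(u = u, cache = list(zt = zt, zat = zat, wt = wt, wam = wam,
                               gates = gates, s_k = s_k))
    },
    stop("unknown formulation")
  )
}

# du: vector length B of dL/du. Returns grads for merge params and dz,
# dz_aux.
merge_backward <- function(model, z, z_aux, mcache, du) {
  p <- model$params
  cfg <- model$config
  B <- length(du)
  g <- list()
  switch(cfg$formulation,
    baseline = {
      g$w <- as.numeric(z %*% du)
      g$b <- sum(du)
      list(grads = g, dz = outer(p$w, du), dz_aux = NULL)
    },
    aw = {
      g$b <- sum(du)
      list(grads = g, dz = sweep(z_aux, 2, du, `*`),
           dz_aux = sweep(z, 2, du, `*`))
    },
    at = {
      g$w <- as.numeric(z %*% du)
      g$w_aux <- as.numeric(z_aux %*% du)
      list(grads = g, dz = outer(p$w, du), dz_aux = outer(p$w_aux, du))
    },
    moe = {
      K <- cfg$K; M <- cfg$n_hidden %/% K
      gates <- mcache$gates; s_k <- mcache$s_k
      g$b <- sum(du)
      dgates <- sweep(s_k, 2, du, `*`)
      ds_k <- sweep(gates, 2, du, `*`)
      # softmax backward per column
      dalpha <- gates * sweep(dgates, 2, colSums(gates * dgates), `-`)
      g$b_aux <- rowSums(dalpha)
      # w_aux_m grad: sum_b dalpha(k,b) * z_aux~(k,m,b); z_aux feeds only
      # alpha, z feeds only s_k
      zat <- mcache$zat
      dwam <- matrix(0, K, M)
      dzat_alpha <- array(0, dim = dim(zat))
      dzt <- array(0, dim = dim(mcache$zt))
      dw_t <- matrix(0, K, M)
      for (b in seq_len(B)) {
        dwam <- dwam + dalpha[, b] * zat[, , b]
        dzat_alpha[, , b] <- mcache$wam * dalpha[, b]
        dzt[, , b] <- mcache$wt * ds_k[, b]
        dw_t <- dw_t + ds_k[, b] * mcache$zt[, , b]
      }
      g$w_aux_m <- t(dwam)
      g$w <- as.numeric(dw_t)
      list(grads = g,
           dz = matrix(dzt, nrow = cfg$n_hidden, ncol = B),
           dz_aux = matrix(dzat_alpha, nrow = cfg$n_hidden, ncol = B))
    }
  )
}

#' Main-branch embedding of audio clips
#'
#' Runs clips through the convolutional main branch, producing the
#' nonnegative 64-dimensional code `z(t, n)` (or `n_hidden`-dimensional
#' for non-default configurations).
#'
#' @param model A [canet_init()] model.
#' @param clips Array `frames x bands x 1 x B` (or `frames x bands` for a
#'   single clip).
#' @return Matrix `n_hidden x B`.
#' @export
forward_main <- function(model, clips) {
  stopifnot(inherits(model, "canet_model"))
  clips <- check_clips(model, clips)
  forward_main_infer(model, clips)
}

#' Auxiliary-branch embedding of context slices
#'
#' The convolutional stage applies `aux_kernels` kernels of size 1 x 32
#' (sharing weights across quantiles only), yielding 9 x 8 = 72
#' activations under the default configuration, followed by a dense layer
#' onto the embedding dimension.
#'
#' @param model A [canet_init()] model with a non-baseline formulation.
#' @param slices Array `9 x 32 x B` (or a single `9 x 32` matrix).
#' @return Matrix `n_hidden x B` of nonnegative activations.
#' @export
forward_aux <- function(model, slices) {
  stopifnot(inherits(model, "canet_model"))
  if (model$config$formulation == "baseline") {
    stop("baseline models have no auxiliary branch")
  }
  slices <- check_slices(model, slices)
  forward_aux_internal(model, slices)$z_aux
}

#' Merge branch embeddings into an event probability
#'
#' Applies the configured output-layer formulation to precomputed branch
#' codes. Outputs lie strictly in (0, 1).
#'
#' @param model A [canet_init()] model.
#' @param z Main-branch code(s), `n_hidden x B` matrix or length-N vector.
#' @param z_aux Auxiliary code(s), same shape; ignored by the baseline.
#' @return Numeric vector of B probabilities.
#' @export
merge_output <- function(model, z, z_aux = NULL) {
  stopifnot(inherits(model, "canet_model"))
  if (is.vector(z)) z <- matrix(z, ncol = 1)
  if (!is.null(z_aux) && is.vector(z_aux)) z_aux <- matrix(z_aux, ncol = 1)
  if (model$config$formulation != "baseline" && is.null(z_aux)) {
    stop("this formulation requires z_aux")
  }
  stats::plogis(merge_forward(model, z, z_aux)$u)
}

#' Predict event probabilities for clips
#'
#' @param model A [canet_init()] model.
#' @param clips Clip array (`frames x bands x 1 x B`).
#' @param slices Context slices (`9 x 32 x B`), required for
#'   context-adaptive formulations.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
canet_predict <- function(model, clips, slices = NULL) {
  stopifnot(inherits(model, "canet_model"))
  clips <- check_clips(model, clips)
  z <- forward_main_infer(model, clips)
  z_aux <- NULL
  if (model$config$formulation != "baseline") {
    if (is.null(slices)) stop("context slices required for this formulation")
    slices <- check_slices(model, slices)
    z_aux <- forward_aux_internal(model, slices)$z_aux
  }
  stats::plogis(merge_forward(model, z, z_aux)$u)
}

#' Time-varying threshold view of an adaptive-threshold model
#'
#' For the AT formulation, the fixed decision `y(t) > tau` on the merged
#' output is equivalent to comparing the static detector
#' `sigmoid(w . z(t))` against the slowly varying threshold
#' `sigmoid(sigmoid^-1(tau) - w_aux . z_aux(t))` returned here, one value
#' per context frame.
#'
#' @param model An AT-formulation [canet_init()] model.
#' @param context A `context_tensor`, or an array/matrix of context slices
#'   (`9 x 32 x B`).
#' @param tau Fixed threshold in (0, 1).
#' @return Numeric vector of effective thresholds, one per context frame.
#' @export
adaptive_threshold_view <- function(model, context, tau) {
  stopifnot(inherits(model, "canet_model"))
  if (model$config$formulation != "at") stop("model is not an AT model")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    stop("tau must lie strictly in (0, 1)")
  }
  slices <- if (inherits(context, "context_tensor")) {
    aperm(context$values, c(2, 3, 1))
  } else if (is.matrix(context)) {
    array(context, dim = c(dim(context), 1L))
  } else context
  slices <- check_slices(model, slices)
  z_aux <- forward_aux_internal(model, slices)$z_aux
  a <- as.numeric(crossprod(z_aux, model$params$w_aux))
  stats::plogis(stats::qlogis(tau) - a)
}

#' Clip-level classification accuracy
#'
#' Fraction of clips for which the absolute difference between the
#' predicted probability and the binary label is strictly below 0.5.
#'
#' @param y_pred Numeric vector of probabilities.
#' @param y_true Binary labels of the same length.
#' @return Accuracy in `[0, 1]`.
#' @examples
#' classification_accuracy(c(0.9, 0.2, 0.6), c(1, 0, 0))
#' @export
classification_accuracy <- function(y_pred, y_true) {
  if (length(y_pred) != length(y_true)) stop("length mismatch")
  mean(abs(y_pred - y_true) < 0.5)
}

# Full forward + backward pass; returns loss, probabilities and gradients
# for every parameter.
canet_loss_grad <- function(model, clips, slices, y_true) {
  cfg <- model$config
  B <- dim(clips)[4]
  fm <- forward_main_internal(model, clips)
  fa <- NULL
  z_aux <- NULL
  if (cfg$formulation != "baseline") {
    fa <- forward_aux_internal(model, slices)
    z_aux <- fa$z_aux
  }
  mf <- merge_forward(model, fm$z, z_aux)
  y <- stats::plogis(mf$u)
  eps <- 1e-12
  bce <- -mean(y_true * log(y + eps) + (1 - y_true) * log(1 - y + eps))
  loss <- bce + cfg$l2 * sum(model$params$W4^2)
  du <- (y - y_true) / B
  mb <- merge_backward(model, fm$z, z_aux, mf$cache, du)
  grads <- mb$grads
  grads <- c(grads, backward_main_internal(model, fm$cache, mb$dz))
  if (cfg$formulation != "baseline") {
    grads <- c(grads, backward_aux_internal(model, fa$cache, mb$dz_aux))
  }
  list(loss = loss, y = y, grads = grads)
}

# Fixed affine input standardization (fit on training data, stored with
# the model so deployment uses identical statistics).
standardize_input <- function(x, center, scale) {
  if (center == 0 && scale == 1) return(x)
  (x - center) / scale
}

#' Train a context-adaptive network
#'
#' Minimizes binary cross-entropy (plus the L2 penalty on the dense
#' embedding weights) with Adam on mini-batches. Training is deterministic
#' under a fixed seed on a fixed platform. Early stopping monitors
#' validation accuracy with the given patience; the parameters of the best
#' validation epoch are restored.
#'
#' @param model A [canet_init()] model.
#' @param data Training [clip_batch()].
#' @param validation Optional validation [clip_batch()]; its sensors must
#'   not intersect the training sensors (leave-one-sensor-out contract).
#' @param epochs Maximum number of epochs.
#' @param batch_size Mini-batch size; incomplete trailing batches are
#'   dropped within an epoch (each epoch reshuffles, so all clips are
#'   visited across epochs).
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param patience Early-stopping patience in epochs (ignored without
#'   validation data).
#' @param seed Seed controlling shuffling.
#' @param standardize Fit a global affine input standardization (per
#'   branch) on the training data before training and store it with the
#'   model; deployment then reuses the same statistics. Without it,
#'   representations with a large additive offset (logmelspec) start deep
#'   in the saturated regime of the sigmoid head.
#' @param verbose Print per-epoch losses.
#' @return The trained `canet_model`, with a `history` data frame
#'   (`epoch`, `train_loss`, `train_acc`, `val_loss`, `val_acc`) attached.
#' @export
canet_train <- function(model, data, validation = NULL, epochs = 20,
                        batch_size = 32, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, patience = 20, seed = 1,
                        standardize = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "canet_model"), inherits(data, "clip_batch"))
  n <- length(data$labels)
  if (n == 0L) stop("empty training split")
  if (!is.null(validation)) {
    stopifnot(inherits(validation, "clip_batch"))
    if (length(validation$labels) == 0L) stop("empty validation split")
    if (length(intersect(unique(data$sensor_ids),
                         unique(validation$sensor_ids))) > 0) {
      stop("validation sensors intersect training sensors")
    }
  }
  needs_aux <- model$config$formulation != "baseline"
  if (needs_aux && is.null(data$slices)) {
    stop("context slices required for this formulation")
  }
  if (standardize) {
    s_main <- stats::sd(data$clips)
    model$norm$center <- mean(data$clips)
    model$norm$scale <- if (s_main > 0) s_main else 1
    if (needs_aux) {
      s_aux <- stats::sd(data$slices)
      model$norm$aux_center <- mean(data$slices)
      model$norm$aux_scale <- if (s_aux > 0) s_aux else 1
    }
  }
  set.seed(seed)
  state <- adam_state(model$params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric())
  best <- list(acc = -Inf, params = model$params, epoch = 0L)
  wait <- 0L
  bs <- min(batch_size, n)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    n_batches <- max(1L, n %/% bs)
    ep_loss <- 0; ep_correct <- 0; ep_seen <- 0
    for (bi in seq_len(n_batches)) {
      take <- ord[((bi - 1) * bs + 1):(bi * bs)]
      clips <- data$clips[, , , take, drop = FALSE]
      sl <- if (needs_aux) data$slices[, , take, drop = FALSE] else NULL
      lg <- canet_loss_grad(model, clips, sl, data$labels[take])
      step <- adam_step(model$params, lg$grads, state, lr = lr,
                        beta1 = beta1, beta2 = beta2)
      model$params <- step$params
      state <- step$state
      ep_loss <- ep_loss + lg$loss * length(take)
      ep_correct <- ep_correct + sum(abs(lg$y - data$labels[take]) < 0.5)
      ep_seen <- ep_seen + length(take)
    }
    val_loss <- NA_real_; val_acc <- NA_real_
    if (!is.null(validation)) {
      vp <- canet_predict(model, validation$clips,
                          if (needs_aux) validation$slices else NULL)
      eps <- 1e-12
      val_loss <- -mean(validation$labels * log(vp + eps) +
                          (1 - validation$labels) * log(1 - vp + eps))
      val_acc <- classification_accuracy(vp, validation$labels)
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / ep_seen,
                                   train_acc = ep_correct / ep_seen,
                                   val_loss = val_loss, val_acc = val_acc))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_acc %s", ep,
                      ep_loss / ep_seen, ep_correct / ep_seen,
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
    if (!is.null(validation)) {
      if (val_acc > best$acc + 1e-12) {
        best <- list(acc = val_acc, params = model$params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }
  if (!is.null(validation) && is.finite(best$acc)) model$params <- best$params
  model$history <- hist
  model
}

#' Bundle clips, labels and aligned context slices for training
#'
#' @param clips Array `frames x bands x 1 x B` (a bare
#'   `frames x bands x B` array is promoted).
#' @param labels Binary vector of length B.
#' @param slices Optional context-slice array `9 x 32 x B`, one slice per
#'   clip (the slice active at the clip's center time).
#' @param sensor_ids Character vector of length B.
#' @return An object of class `clip_batch`.
#' @export
clip_batch <- function(clips, labels, slices = NULL, sensor_ids = NULL) {
  d <- dim(clips)
  if (length(d) == 3L) clips <- array(clips, dim = c(d[1], d[2], 1L, d[3]))
  d <- dim(clips)
  B <- d[4]
  if (length(labels) != B) stop("labels length must match clip count")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  if (!is.null(slices) && dim(slices)[3] != B) {
    stop("slices count must match clip count")
  }
  if (is.null(sensor_ids)) sensor_ids <- rep("unknown", B)
  structure(list(clips = clips, labels = as.numeric(labels), slices = slices,
                 sensor_ids = as.character(sensor_ids)),
            class = "clip_batch")
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive holding the parameters, the
#' merge configuration and the frontend settings; a model is only valid
#' together with its own frontend.
#'
#' @param model A `canet_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_model`: `path` invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "canet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "canet_model")) stop("not a canet_model checkpoint")
  m
}
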
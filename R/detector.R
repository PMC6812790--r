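# Sliding-window detection in continuous audio: run the trained clip
# classifier over 150 ms windows hopped by 50 ms to obtain the event
# detection function (EDF) at 20 frames per second, then extract
# thresholded local peaks.

EDF_WINDOW_S <- 0.150
EDF_HOP_S <- 0.050

#' Extract fixed-length clip features around given center times
#'
#' Slices 104-frame (150 ms) windows out of a time-frequency matrix,
#' centered on the requested times; clips reaching past the matrix edges
#' are zero-padded symmetrically.
#'
#' @param m A [tf_matrix()].
#' @param times Center times in seconds.
#' @param n_frames Clip length in frames.
#' @return Array `n_frames x bands x 1 x length(times)`.
#' @export
clip_features <- function(m, times, n_frames = CLIP_FRAMES) {
  stopifnot(inherits(m, "tf_matrix"))
  T <- nrow(m$values)
  nb <- ncol(m$values)
  half <- n_frames %/% 2
  out <- array(0, dim = c(n_frames, nb, 1L, length(times)))
  fr <- m$frame_rate
  for (i in seq_along(times)) {
    cidx <- round((times[i] - m$frame_times[1]) * fr) + 1
    lo <- cidx - half + 1L
    hi <- lo + n_frames - 1L
    src <- max(1L, lo):min(T, hi)
    if (length(src) < 1L || src[1] > T || src[length(src)] < 1L) next
    dst <- src - lo + 1L
    out[dst, , 1L, i] <- m$values[src, , drop = FALSE]
  }
  out
}

# Context slices aligned to clip center times: the most recent context
# frame at or before each time.
clip_slices <- function(ct, times) {
  stopifnot(inherits(ct, "context_tensor"))
  idx <- pmax(1L, findInterval(times, ct$frame_times))
  q <- dim(ct$values)[2]; f <- dim(ct$values)[3]
  out <- array(0, dim = c(q, f, length(times)))
  for (i in seq_along(times)) out[, , i] <- ct$values[idx[i], , ]
  out
}

#' Event detection function from precomputed features
#'
#' Slides the classifier over a time-frequency matrix: one output per
#' 50 ms hop, each evaluated on the 150 ms window starting at that hop and
#' stamped with the window-center time. Windows lie fully inside the
#' matrix (no padding), so a recording of duration `D` yields
#' `floor((D_frames - 104) / (0.05 * frame_rate)) + 1` frames.
#'
#' @param m A [tf_matrix()] in the representation the model was trained
#'   with.
#' @param model A [canet_init()] model.
#' @param context A `context_tensor` computed from the same recording;
#'   required for context-adaptive formulations, ignored by the baseline.
#' @param batch_size Windows per forward pass.
#' @return An object of class `edf`: list with `values` (probabilities),
#'   `times` (window centers, s), `frame_hop` (0.05 s).
#' @export
edf_from_features <- function(m, model, context = NULL, batch_size = 64) {
  stopifnot(inherits(m, "tf_matrix"), inherits(model, "canet_model"))
  if (!is.null(model$frontend) &&
      m$representation != model$frontend$representation) {
    stop(sprintf("model expects %s features, got %s",
                 model$frontend$representation, m$representation))
  }
  T <- nrow(m$values)
  n_frames <- model$config$input_frames
  if (T < n_frames) stop("recording shorter than one 150 ms analysis window")
  fr <- m$frame_rate
  hop_frames <- EDF_HOP_S * fr
  starts <- 1L + floor((seq_len(ceiling(T / hop_frames)) - 1L) * hop_frames)
  starts <- starts[starts + n_frames - 1L <= T]
  n_win <- length(starts)
  times <- (seq_len(n_win) - 1L) * EDF_HOP_S + EDF_WINDOW_S / 2
  needs_aux <- model$config$formulation != "baseline"
  if (needs_aux && is.null(context)) {
    stop("context tensor required for a context-adaptive model")
  }
  z <- sliding_main_codes(model, m$values, starts, block = batch_size)
  z_aux <- NULL
  if (needs_aux) {
    # the context tensor varies at ~8 frames/hour: embed each unique
    # context frame once and broadcast
    ci <- pmax(1L, findInterval(times, context$frame_times))
    uci <- unique(ci)
    q <- dim(context$values)[2]; f <- dim(context$values)[3]
    sl <- array(0, dim = c(q, f, length(uci)))
    for (i in seq_along(uci)) sl[, , i] <- context$values[uci[i], , ]
    za_u <- forward_aux_internal(model, sl)$z_aux
    z_aux <- za_u[, match(ci, uci), drop = FALSE]
  }
  y <- stats::plogis(merge_forward(model, z, z_aux)$u)
  structure(list(values = y, times = times, frame_hop = EDF_HOP_S,
                 start_time = times[1]),
            class = "edf")
}

#' Event detection function of a continuous recording
#'
#' Computes the model's own time-frequency representation (the frontend
#' stored in the checkpoint), the long-term context tensor if the model is
#' context-adaptive, and the sliding-window EDF.
#'
#' @param w A [waveform()].
#' @param model A [canet_init()] model carrying a `frontend` description.
#' @param context Optional precomputed `context_tensor`; computed from the
#'   recording when omitted.
#' @param context_window,context_period Context settings used when the
#'   tensor must be computed (seconds).
#' @return An `edf` object (see [edf_from_features()]).
#' @export
compute_edf <- function(w, model, context = NULL, context_window = 1800,
                        context_period = 450) {
  stopifnot(inherits(w, "waveform"), inherits(model, "canet_model"))
  if (duration(w) < EDF_WINDOW_S) stop("recording shorter than 150 ms")
  fe <- model$frontend
  if (is.null(fe)) fe <- list(representation = "logmelspec",
                              stft = stft_config(), pcen = NULL)
  mel <- melspectrogram(w, fe$stft %||% stft_config())
  rep <- switch(fe$representation,
    logmelspec = logmelspec(mel),
    pcen = pcen(mel, fe$pcen %||% pcen_params("outdoor")),
    stop("unknown frontend representation")
  )
  if (model$config$formulation != "baseline" && is.null(context)) {
    context <- summary_statistics(rep, window_span = context_window,
                                  frame_period = context_period)
  }
  edf_from_features(rep, model, context)
}

#' @export
print.edf <- function(x, ...) {
  cat(sprintf("<edf> %d frames @ 20 frames/s, values in [%.3f, %.3f]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Extract thresholded peaks from an event detection function
#'
#' A peak is a strict-left / weak-right local maximum
#' (`y(t-1) < y(t) >= y(t+1)`) exceeding the threshold; edge frames and
#' flat stretches yield no peaks. With a positive `min_spacing`, peaks are
#' suppressed greedily in descending score order (ties broken by earlier
#' time): any remaining peak closer than the spacing to an already kept
#' peak is dropped. With zero spacing adjacent peaks can be as close as
#' two hops (100 ms).
#'
#' @param edf An `edf` object.
#' @param tau Detection threshold in (0, 1).
#' @param min_spacing Minimum spacing between kept peaks in milliseconds
#'   (0 disables suppression; 150 reproduces the baseline constraint).
#' @return An [event_list()] with peak times and scores.
#' @export
pick_peaks <- function(edf, tau, min_spacing = 0) {
  stopifnot(inherits(edf, "edf"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    stop("tau must lie strictly in (0, 1)")
  }
  y <- edf$values
  n <- length(y)
  if (n < 3L) return(event_list())
  i <- 2:(n - 1)
  is_peak <- (y[i - 1] < y[i]) & (y[i] >= y[i + 1]) & (y[i] > tau)
  idx <- i[is_peak]
  if (length(idx) == 0L) return(event_list())
  t <- edf$times[idx]
  s <- y[idx]
  if (min_spacing > 0) {
    spacing <- min_spacing / 1000
    ord <- order(-s, t)
    keep_t <- numeric(0)
    keep <- logical(length(idx))
    for (j in ord) {
      if (length(keep_t) == 0L || all(abs(t[j] - keep_t) >= spacing)) {
        keep[j] <- TRUE
        keep_t <- c(keep_t, t[j])
      }
    }
    t <- t[keep]; s <- s[keep]
  }
  o <- order(t)
  event_list(t[o], s[o])
}

#' Export detected events as audio clips
#'
#' Writes one 150 ms WAV clip per detected event, named by its timestamp.
#'
#' @param w The recording [waveform()].
#' @param events An [event_list()].
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
export_event_clips <- function(w, events, dir) {
  stopifnot(inherits(w, "waveform"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  half <- round(EDF_WINDOW_S / 2 * w$sample_rate)
  paths <- character(0)
  for (t in events$time_s) {
    c0 <- round(t * w$sample_rate)
    lo <- max(1, c0 - half); hi <- min(length(w$samples), c0 + half)
    clip <- waveform(w$samples[lo:hi], w$sample_rate, w$sensor_id, w$split)
    p <- file.path(dir, sprintf("event_%09.3fs.wav", t))
    write_wav(clip, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
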
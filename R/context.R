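# Long-term context features: quantile summary statistics of the
# time-frequency background over trailing windows, and band SPL trend
# diagnostics.

#' Quantile levels of the context tensor
#'
#' Nine long-term order statistics — the median, quartiles, deciles,
#' percentiles and permilles — as probability levels.
#' @return Numeric vector of 9 probabilities.
#' @export
context_quantile_levels <- function() {
  c(0.001, 0.01, 0.10, 0.25, 0.50, 0.75, 0.90, 0.99, 0.999)
}

#' Long-term quantile summary statistics
#'
#' Computes the context tensor `mu(t, q, f)`: for each context frame, the
#' nine order statistics of all time-frequency magnitudes in the trailing
#' window of span `window_span`, per reduced frequency band. Bands are
#' reduced 128 -> 32 by non-overlapping average pooling of 4 adjacent mel
#' bands. Windows are trailing (causal), so the features are computable in
#' streaming deployment; the first frames use whatever audio is available
#' and a window longer than the recording is truncated with a warning.
#'
#' @param m A [tf_matrix()] (any representation; use the same
#'   representation the detector was trained with).
#' @param window_span Window span `T_CA` in seconds (default 1800 s).
#' @param frame_period Context sampling period in seconds (default 450 s,
#'   i.e. 8 frames per hour).
#' @param band_pool Number of adjacent mel bands averaged per reduced band.
#' @return An object of class `context_tensor`: list with `values` (array
#'   frames x 9 quantiles x reduced bands), `frame_times`,
#'   `quantile_levels`, `band_centers`, `frame_period`, `window_span`.
#' @examples
#' w <- waveform(rnorm(22050) * 0.01, 22050)
#' ct <- summary_statistics(logmelspec(melspectrogram(w)),
#'                          window_span = 1, frame_period = 0.5)
#' dim(ct$values)
#' @export
summary_statistics <- function(m, window_span = 1800, frame_period = 450,
                               band_pool = 4) {
  stopifnot(inherits(m, "tf_matrix"))
  if (frame_period <= 0) stop("frame_period must be positive")
  if (window_span <= 0) stop("window_span must be positive")
  n_bands <- ncol(m$values)
  if (n_bands %% band_pool != 0) stop("band count not divisible by band_pool")
  dur <- nrow(m$values) / m$frame_rate
  if (nrow(m$values) < 1L) stop("empty time-frequency matrix")
  if (window_span > dur) {
    warning("window span exceeds recording duration; truncating to available data")
  }
  # reduced bands: average pooling of adjacent mel bands
  n_red <- n_bands %/% band_pool
  grp <- rep(seq_len(n_red), each = band_pool)
  red <- t(rowsum(t(m$values), grp) / band_pool)  # frames x n_red
  red_centers <- as.numeric(rowsum(m$band_centers, grp) / band_pool)

  n_frames <- max(1L, floor(dur / frame_period))
  times <- seq_len(n_frames) * frame_period
  times[n_frames] <- min(times[n_frames], dur)
  if (n_frames == 1L) times <- dur
  q_levels <- context_quantile_levels()
  vals <- array(NA_real_, dim = c(n_frames, length(q_levels), n_red))
  for (i in seq_len(n_frames)) {
    t_hi <- times[i]
    t_lo <- max(0, t_hi - window_span)
    rows <- which(m$frame_times >= t_lo - 1e-9 & m$frame_times <= t_hi + 1e-9)
    if (length(rows) == 0L) rows <- seq_len(nrow(red))
    sub <- red[rows, , drop = FALSE]
    vals[i, , ] <- apply(sub, 2, stats::quantile, probs = q_levels,
                         names = FALSE, type = 7)
  }
  structure(list(values = vals, frame_times = times,
                 quantile_levels = q_levels, band_centers = red_centers,
                 frame_period = frame_period, window_span = window_span),
            class = "context_tensor")
}

#' @export
print.context_tensor <- function(x, ...) {
  cat(sprintf("<context_tensor> %d frames x %d quantiles x %d bands (period %g s, span %g s)\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$frame_period, x$window_span))
  invisible(x)
}

#' Context slice active at a given time
#'
#' Returns the most recent context frame at or before `time`; times before
#' the first context frame fall back to the first frame.
#'
#' @param ct A `context_tensor`.
#' @param time Time in seconds.
#' @return 9 x 32 matrix (quantiles x bands).
#' @export
context_slice_at <- function(ct, time) {
  stopifnot(inherits(ct, "context_tensor"))
  i <- findInterval(time, ct$frame_times)
  i <- max(1L, i)
  matrix(ct$values[i, , ], nrow = dim(ct$values)[2])
}

#' Median band sound pressure level trend
#'
#' Per temporal segment, `10 * log10` of the median in-band mel energy,
#' referenced to digital full scale. Mirrors the classic diagnostic of
#' insect-band noise decaying over a night of recording.
#'
#' @param m A [tf_matrix()] with `representation = "melspec"`.
#' @param band_lo,band_hi Band limits in Hz.
#' @param segment Segment duration in seconds (default 1800 s).
#' @return Data frame with `segment_start`, `segment_mid` (s), and
#'   `spl_db` (dB re full scale).
#' @export
band_spl_trend <- function(m, band_lo = 2000, band_hi = 2500, segment = 1800) {
  stopifnot(inherits(m, "tf_matrix"))
  if (m$representation != "melspec") stop("input must be a melspec tf_matrix")
  if (band_lo >= band_hi) stop("band_lo must be below band_hi")
  cols <- which(m$band_centers >= band_lo & m$band_centers <= band_hi)
  if (length(cols) == 0L) stop("empty band selection")
  seg_idx <- floor(m$frame_times / segment)
  segs <- sort(unique(seg_idx))
  spl <- vapply(segs, function(s) {
    rows <- which(seg_idx == s)
    e <- rowMeans(m$values[rows, cols, drop = FALSE])
    10 * log10(stats::median(e) / FULL_SCALE^2)
  }, numeric(1))
  data.frame(segment_start = segs * segment,
             segment_mid = segs * segment + segment / 2,
             spl_db = spl)
}

#' Estimate a linear background decay from an SPL trend
#'
#' First-to-last segment difference rescaled by `S / (S - 1)` (the segment
#' medians sit at segment centers, which span only `(S - 1) / S` of the
#' recording), so a linear ramp in dB is recovered without bias.
#'
#' @param trend Output of [band_spl_trend()].
#' @return Estimated total level change in dB over the recording (negative
#'   for a decay).
#' @export
estimate_decay_db <- function(trend) {
  s <- nrow(trend)
  if (s < 2L) stop("need at least two segments")
  (trend$spl_db[s] - trend$spl_db[1]) * s / (s - 1)
}
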
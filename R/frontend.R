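# Time-frequency frontend: mel spectrogram, log compression, and
# per-channel energy normalization (PCEN).
#
# The decoding convention follows field recorders with 32-bit converters:
# unit-range float samples are rescaled to the full-scale integer range
# [-2^31, 2^31) before the STFT, so that the PCEN constants epsilon and
# delta keep their published meaning.

FULL_SCALE <- 2^31
LOG_FLOOR <- 1e-10

#' STFT configuration
#'
#' Defaults match the detection frontend used throughout the package:
#' 12 ms analysis window, 1.5 ms hop, zero-padded FFT, 128 mel bands
#' spanning the flight-call range from 2 kHz up to the Nyquist frequency.
#'
#' @param window_length STFT window length in samples (Hann window).
#' @param hop_length Hop between frames in samples.
#' @param n_fft FFT length (window is zero-padded to this length).
#' @param n_mels Number of mel bands.
#' @param fmin,fmax Mel filterbank edges in Hz. `fmax = NULL` means Nyquist.
#' @return A list of class `stft_config`.
#' @export
stft_config <- function(window_length = 256, hop_length = 32, n_fft = 1024,
                        n_mels = 128, fmin = 2000, fmax = NULL) {
  stopifnot(window_length > 0, hop_length > 0, n_fft >= window_length,
            n_mels > 0, fmin >= 0)
  structure(list(window_length = window_length, hop_length = hop_length,
                 n_fft = n_fft, n_mels = n_mels, fmin = fmin, fmax = fmax),
            class = "stft_config")
}

#' Construct a time-frequency matrix
#'
#' Container for the matrix `E(t, f)` of mel-frequency magnitudes (or a
#' compressed transform thereof), indexed by frame (rows) and band
#' (columns).
#'
#' @param values Matrix, frames x bands.
#' @param frame_rate Frames per second.
#' @param band_centers Band center frequencies in Hz, strictly increasing.
#' @param representation One of `"melspec"`, `"logmelspec"`, `"pcen"`.
#' @param frame_times Optional vector of frame center times (s).
#' @param pcen_params The [pcen_params()] used, when `representation`
#'   is `"pcen"`.
#' @return An object of class `tf_matrix`.
#' @export
tf_matrix <- function(values, frame_rate, band_centers,
                      representation = c("melspec", "logmelspec", "pcen"),
                      frame_times = NULL, pcen_params = NULL) {
  representation <- match.arg(representation)
  values <- as.matrix(values)
  if (ncol(values) != length(band_centers)) {
    stop("band_centers length must match the number of columns")
  }
  if (any(diff(band_centers) <= 0)) stop("band_centers must be strictly increasing")
  if (representation %in% c("melspec", "pcen") && any(values < -1e-9)) {
    # pcen can dip microscopically below zero through floating error only
    if (representation == "melspec") stop("melspec values must be nonnegative")
  }
  if (is.null(frame_times)) {
    frame_times <- (seq_len(nrow(values)) - 1) / frame_rate
  }
  structure(list(values = values, frame_rate = frame_rate,
                 band_centers = band_centers, representation = representation,
                 frame_times = frame_times, pcen_params = pcen_params),
            class = "tf_matrix")
}

#' @export
print.tf_matrix <- function(x, ...) {
  cat(sprintf("<tf_matrix:%s> %d frames x %d bands @ %.2f frames/s\n",
              x$representation, nrow(x$values), ncol(x$values), x$frame_rate))
  invisible(x)
}

# Slaney-style mel scale (linear below 1 kHz, log above).
hz_to_mel <- function(f) {
  f_sp <- 200 / 3
  min_log_hz <- 1000
  logstep <- log(6.4) / 27
  ifelse(f < min_log_hz, f / f_sp, min_log_hz / f_sp + log(f / min_log_hz) / logstep)
}

mel_to_hz <- function(m) {
  f_sp <- 200 / 3
  min_log_mel <- 1000 / f_sp
  logstep <- log(6.4) / 27
  ifelse(m < min_log_mel, m * f_sp, 1000 * exp(logstep * (m - min_log_mel)))
}

#' Mel filterbank matrix
#'
#' Triangular, area-normalized (Slaney-style) filters on FFT bin center
#' frequencies. Rows are mel bands, columns FFT bins.
#'
#' @param sample_rate Audio sample rate in Hz.
#' @param n_fft FFT length.
#' @param n_mels Number of bands.
#' @param fmin,fmax Band edges in Hz (`fmax = NULL` for Nyquist).
#' @return `n_mels` x `(n_fft/2 + 1)` matrix with attribute
#'   `"band_centers"`.
#' @export
mel_filterbank <- function(sample_rate, n_fft = 1024, n_mels = 128,
                           fmin = 2000, fmax = NULL) {
  if (is.null(fmax)) fmax <- sample_rate / 2
  stopifnot(fmin < fmax, fmax <= sample_rate / 2 + 1e-9)
  fft_freqs <- seq(0, sample_rate / 2, length.out = n_fft %/% 2 + 1)
  mel_pts <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2))
  fb <- matrix(0, n_mels, length(fft_freqs))
  for (i in seq_len(n_mels)) {
    lo <- mel_pts[i]; ce <- mel_pts[i + 1]; hi <- mel_pts[i + 2]
    up <- (fft_freqs - lo) / (ce - lo)
    down <- (hi - fft_freqs) / (hi - ce)
    tri <- pmax(0, pmin(up, down))
    fb[i, ] <- tri * 2 / (hi - lo)  # area normalization
  }
  attr(fb, "band_centers") <- mel_pts[2:(n_mels + 1)]
  fb
}

# Power STFT without padding: frames lie fully inside the signal; frame
# time is the window-center time. Computed in chunks to bound memory;
# pairs of real frames share one complex FFT (conjugate-symmetry split).
# Returns bins x frames.
power_stft <- function(x, sample_rate, cfg) {
  wl <- cfg$window_length
  hop <- as.integer(cfg$hop_length)
  nfft <- cfg$n_fft
  n <- length(x)
  if (n < wl) stop("input too short: need at least one analysis window")
  n_frames <- (n - wl) %/% hop + 1
  win <- hann_window(wl)
  n_bins <- nfft %/% 2 + 1
  out <- matrix(0, n_bins, n_frames)
  chunk <- 8192L
  for (f0 in seq(1L, n_frames, by = chunk)) {
    f1 <- min(f0 + chunk - 1L, n_frames)
    nc <- f1 - f0 + 1L
    z <- cpp_pack_frames(x, f0, nc, hop, win, nfft)
    p <- cpp_split_power(stats::mvfft(z), n_bins)
    out[, f0:f1] <- p[, seq_len(nc), drop = FALSE]
  }
  out
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)

#' Mel-frequency spectrogram
#'
#' Squared-modulus STFT mapped through a mel filterbank. The waveform is
#' resampled to 22,050 Hz if needed and rescaled to the full-scale 32-bit
#' integer range before analysis, so downstream PCEN constants keep their
#' published meaning. No frame padding is applied: all frames lie fully
#' inside the signal and carry window-center times, which avoids edge
#' energy that adaptive gain control would otherwise amplify.
#'
#' @param w A [waveform()].
#' @param config An [stft_config()].
#' @return A [tf_matrix()] with `representation = "melspec"`,
#'   `frame_rate = sample_rate / hop_length`.
#' @examples
#' w <- waveform(sin(2 * pi * 5000 * seq(0, 0.2, by = 1 / 22050)), 22050)
#' m <- melspectrogram(w)
#' dim(m$values)
#' @export
melspectrogram <- function(w, config = stft_config()) {
  stopifnot(inherits(w, "waveform"), inherits(config, "stft_config"))
  if (!all(is.finite(w$samples))) stop("non-finite samples")
  w <- resample_waveform(w, 22050)
  x <- w$samples * FULL_SCALE
  spec <- power_stft(x, w$sample_rate, config)   # bins x frames
  fb <- mel_filterbank(w$sample_rate, config$n_fft, config$n_mels,
                       config$fmin, config$fmax)
  # the filterbank is sparse (a few dozen bins per triangle)
  vals <- t(as.matrix(Matrix::Matrix(fb, sparse = TRUE) %*% spec))
  frame_rate <- w$sample_rate / config$hop_length
  t0 <- (config$window_length / 2 - 0.5) / w$sample_rate
  times <- t0 + (seq_len(nrow(vals)) - 1) / frame_rate
  tf_matrix(vals, frame_rate, attr(fb, "band_centers"), "melspec",
            frame_times = times)
}

#' Logarithmic compression of a mel spectrogram
#'
#' Elementwise `log(eps + E)` with a small floor that keeps zero energies
#' finite. This is the static dynamic-range compression that PCEN is
#' compared against.
#'
#' @param m A [tf_matrix()] with `representation = "melspec"`.
#' @param eps Log floor (default `1e-10`).
#' @return A [tf_matrix()] with `representation = "logmelspec"`.
#' @export
logmelspec <- function(m, eps = LOG_FLOOR) {
  stopifnot(inherits(m, "tf_matrix"))
  if (m$representation != "melspec") stop("input must be a melspec tf_matrix")
  if (any(m$values < 0)) stop("negative input values")
  out <- m
  out$values <- log(eps + m$values)
  out$representation <- "logmelspec"
  out
}

#' PCEN parameter set
#'
#' Per-channel energy normalization combines per-band automatic gain
#' control (division by a low-pass-smoothed energy raised to `alpha`) with
#' root dynamic-range compression (`delta`, `r`). The `"indoor"` preset is
#' the original far-field speech recommendation; the `"outdoor"` preset is
#' tuned for bioacoustic event detection (faster smoother, weaker gain
#' normalization, stronger compression).
#'
#' @param preset `"outdoor"`, `"indoor"` or `"custom"`.
#' @param eps AGC stabilizer (positive).
#' @param alpha Gain-normalization exponent in (0, 1].
#' @param delta Compression bias (positive).
#' @param r Compression root exponent in (0, 1].
#' @param t_pcen Smoother support in seconds.
#' @return A list of class `pcen_params`.
#' @examples
#' pcen_params("outdoor")
#' @export
pcen_params <- function(preset = c("outdoor", "indoor", "custom"),
                        eps = NULL, alpha = NULL, delta = NULL, r = NULL,
                        t_pcen = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    outdoor = list(eps = 1e-6, alpha = 0.8, delta = 10, r = 1 / 4, t_pcen = 0.060),
    indoor = list(eps = 1e-6, alpha = 0.98, delta = 2, r = 1 / 2, t_pcen = 0.400),
    custom = list(eps = 1e-6, alpha = 0.8, delta = 10, r = 1 / 4, t_pcen = 0.060)
  )
  p <- list(
    eps = if (is.null(eps)) def$eps else eps,
    alpha = if (is.null(alpha)) def$alpha else alpha,
    delta = if (is.null(delta)) def$delta else delta,
    r = if (is.null(r)) def$r else r,
    t_pcen = if (is.null(t_pcen)) def$t_pcen else t_pcen,
    preset_name = preset
  )
  if (p$eps <= 0 || p$delta <= 0 || p$t_pcen <= 0) stop("eps, delta, t_pcen must be positive")
  if (p$alpha <= 0 || p$alpha > 1) stop("alpha must lie in (0, 1]")
  if (p$r <= 0 || p$r > 1) stop("r must lie in (0, 1]")
  structure(p, class = "pcen_params")
}

# Smoother coefficient from a support expressed in frames: the standard
# convention relating the -3 dB support T of a first-order IIR to its
# feed-forward gain s.
pcen_smoother_coef <- function(t_frames) {
  (sqrt(1 + 4 * t_frames^2) - 1) / (2 * t_frames^2)
}

#' Per-channel energy normalization
#'
#' Applies, per mel band, a causal first-order IIR smoother `M(t, f)`
#' (initialized at the first frame to suppress the onset transient)
#' followed by adaptive gain control and root compression:
#' `PCEN = (E / (eps + M)^alpha + delta)^r - delta^r`.
#'
#' With `alpha = 1` and vanishing `eps`, constant inputs of any positive
#' level map to the same steady-state output: the gain-invariance property
#' that suppresses slowly varying background noise.
#'
#' @param m A [tf_matrix()] with `representation = "melspec"`.
#' @param params A [pcen_params()].
#' @return A [tf_matrix()] with `representation = "pcen"`.
#' @examples
#' w <- waveform(rnorm(22050) * 0.01, 22050)
#' p <- pcen(melspectrogram(w), pcen_params("outdoor"))
#' @export
pcen <- function(m, params = pcen_params("outdoor")) {
  stopifnot(inherits(m, "tf_matrix"))
  if (m$representation != "melspec") stop("input must be a melspec tf_matrix")
  if (!inherits(params, "pcen_params")) stop("params must be pcen_params")
  if (params$delta <= 0 || params$r <= 0) stop("delta and r must be positive")
  E <- m$values
  t_frames <- params$t_pcen * m$frame_rate
  s <- pcen_smoother_coef(t_frames)
  # M(1) = E(1); M(t) = (1-s) M(t-1) + s E(t)
  u <- E * s
  u[1, ] <- E[1, ]
  M <- apply_recursive_smoother(u, 1 - s)
  out <- m
  out$values <- (E / (params$eps + M)^params$alpha + params$delta)^params$r -
    params$delta^params$r
  out$representation <- "pcen"
  out$pcen_params <- params
  out
}

# y[t] = u[t] + a * y[t-1], columnwise
apply_recursive_smoother <- function(u, a) {
  if (nrow(u) == 1L) return(u)
  y <- stats::filter(u, filter = a, method = "recursive")
  matrix(as.numeric(y), nrow = nrow(u))
}

#' Distribution diagnostics of time-frequency magnitudes
#'
#' Globally standardizes all matrix values to zero mean and unit variance,
#' then reports skewness, excess kurtosis, and a fixed-bin histogram. Used
#' to quantify how close a representation's background statistics are to a
#' Gaussian: PCEN with outdoor parameters typically yields much smaller
#' |skewness| than log compression.
#'
#' @param m A [tf_matrix()].
#' @param breaks Histogram bin edges applied to the standardized values;
#'   values outside the range are clamped to the outer bins.
#' @return List with `skewness`, `kurtosis` (excess), `histogram`
#'   (counts), `breaks`.
#' @export
magnitude_distribution <- function(m, breaks = seq(-6, 6, by = 0.25)) {
  stopifnot(inherits(m, "tf_matrix"))
  v <- as.numeric(m$values)
  if (length(v) == 0L) stop("empty matrix")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("degenerate distribution: zero variance")
  z <- (v - mean(v)) / s
  zc <- pmax(pmin(z, max(breaks) - 1e-12), min(breaks))
  counts <- tabulate(findInterval(zc, breaks), nbins = length(breaks) - 1L)
  list(skewness = e1071::skewness(z, type = 1),
       kurtosis = e1071::kurtosis(z, type = 1),
       histogram = counts, breaks = breaks)
}
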
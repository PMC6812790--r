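#' Construct a waveform object
#'
#' A `waveform` holds decoded monaural audio as unit-range floating-point
#' samples, together with its sample rate and provenance (sensor id and
#' dataset split). All frontend functions in this package expect a
#' `waveform`.
#'
#' @param samples Numeric vector of audio samples, nominally in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (positive scalar).
#' @param sensor_id Identifier of the recording unit (string).
#' @param split Dataset split this recording belongs to: `"train"`,
#'   `"validation"` or `"test"`.
#' @return An object of class `waveform`: a list with fields `samples`,
#'   `sample_rate`, `sensor_id`, `split`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 1, by = 1 / 22050)), 22050)
#' duration(w)
#' @export
waveform <- function(samples, sample_rate, sensor_id = "unknown",
                     split = c("train", "validation", "test")) {
  split <- match.arg(split)
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("samples must be a non-empty numeric vector")
  }
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar")
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         sensor_id = as.character(sensor_id), split = split),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %.3f s @ %g Hz, sensor '%s' (%s)\n",
              duration(x), x$sample_rate, x$sensor_id, x$split))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w A [waveform()].
#' @return Duration in seconds.
#' @export
duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$sample_rate
}

#' Resample a waveform to a target rate
#'
#' Polyphase resampling via [signal::resample()] with a rational
#' approximation of the rate ratio. Returns the input untouched when the
#' rates already agree.
#'
#' @param w A [waveform()].
#' @param rate Target sample rate in Hz.
#' @return A [waveform()] at `rate` Hz.
#' @export
resample_waveform <- function(w, rate = 22050) {
  stopifnot(inherits(w, "waveform"))
  if (w$sample_rate == rate) return(w)
  g <- gcd_int(round(rate), round(w$sample_rate))
  p <- round(rate) / g
  q <- round(w$sample_rate) / g
  y <- signal::resample(w$samples, p = p, q = q)
  waveform(y, rate, w$sensor_id, w$split)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Read a WAV file as a waveform
#'
#' Minimal RIFF/WAVE reader supporting 16-bit PCM and 32-bit IEEE float
#' encodings. Stereo input is averaged to mono with a warning; any sample
#' rate other than `rate` is resampled.
#'
#' @param path Path to a `.wav` file.
#' @param rate Target sample rate (Hz); the decoded audio is resampled to
#'   this rate. Use `NULL` to keep the file's native rate.
#' @param sensor_id,split Provenance attached to the returned waveform.
#' @return A [waveform()].
#' @export
read_wav <- function(path, rate = 22050, sensor_id = "unknown", split = "train") {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        n_channels = readBin(fmt_raw[3:4], "integer", 1, size = 2,
                             endian = "little", signed = FALSE),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, size = 4,
                              endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, size = 2,
                       endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("corrupt WAV file: ", path)
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                 endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) / 4, size = 4,
                 endian = "little")
  } else {
    stop("unsupported WAV encoding (need PCM16 or float32): ", path)
  }
  if (fmt$n_channels > 1L) {
    warning("averaging ", fmt$n_channels, " channels to mono")
    x <- rowMeans(matrix(x, ncol = fmt$n_channels, byrow = TRUE))
  }
  w <- waveform(x, fmt$sample_rate, sensor_id, split)
  if (!is.null(rate)) w <- resample_waveform(w, rate)
  w
}

#' Write a waveform to a 16-bit PCM WAV file
#'
#' @param w A [waveform()]; samples are clipped to `[-1, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmax(pmin(w$samples, 1), -1)
  # scale matches the reader (x = pcm / 32768), clamped at the int16 rail
  pcm <- as.integer(pmin(round(x * 32768), 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
  writeBin(as.integer(round(w$sample_rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(w$sample_rate) * 2), con, size = 4, endian = "little")
  writeBin(as.integer(2), con, size = 2, endian = "little")   # block align
  writeBin(as.integer(16), con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
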
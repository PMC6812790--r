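# Training-clip augmentation: geometrical effects (pitch shift, time
# stretch, via a phase vocoder) and adaptive cross-sensor background
# noise addition. Exactly one effect per augmented clip.

# Phase vocoder time stretch: output duration = input duration / rate.
# Hann analysis/synthesis windows, 75% synthesis overlap, weighted
# overlap-add with squared-window normalization. For rate = 1 this is an
# identity up to resynthesis error.
phase_vocoder_stretch <- function(x, rate, n_fft = 512, syn_hop = 128) {
  if (rate <= 0) stop("rate must be positive")
  if (rate == 1) return(x)
  ana_hop <- syn_hop * rate
  n <- length(x)
  win <- hann_window(n_fft)
  n_frames <- max(2L, floor((n - n_fft) / ana_hop) + 1L)
  omega <- 2 * pi * (seq_len(n_fft) - 1) / n_fft
  out_len <- (n_frames - 1L) * syn_hop + n_fft
  y <- numeric(out_len)
  norm <- numeric(out_len)
  prev_phase <- NULL
  acc_phase <- NULL
  for (i in seq_len(n_frames)) {
    s0 <- floor((i - 1) * ana_hop) + 1
    frame <- x[s0:(s0 + n_fft - 1)]
    spec <- stats::fft(frame * win)
    mag <- Mod(spec)
    phase <- Arg(spec)
    if (is.null(prev_phase)) {
      acc_phase <- phase
    } else {
      dphi <- phase - prev_phase - omega * ana_hop
      dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
      true_freq <- omega + dphi / ana_hop
      acc_phase <- acc_phase + true_freq * syn_hop
    }
    prev_phase <- phase
    resyn <- Re(stats::fft(mag * exp(1i * acc_phase), inverse = TRUE)) / n_fft
    t0 <- (i - 1L) * syn_hop
    idx <- (t0 + 1):(t0 + n_fft)
    y[idx] <- y[idx] + resyn * win
    norm[idx] <- norm[idx] + win^2
  }
  y <- y / pmax(norm, 1e-8)
  target <- max(1L, round(n / rate))
  if (length(y) >= target) y[seq_len(target)] else c(y, numeric(target - length(y)))
}

# Linear-interpolation resampling by a frequency factor (length / factor).
resample_by_factor <- function(x, factor) {
  n_out <- max(2L, round(length(x) / factor))
  stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = n_out))$y
}

#' Time-stretch a waveform
#'
#' Phase-vocoder time stretching: pitch is preserved while the duration is
#' divided by `rate` (`rate > 1` speeds up).
#'
#' @param w A [waveform()].
#' @param rate Stretch factor (positive).
#' @return A [waveform()] of duration `duration(w) / rate`.
#' @export
time_stretch <- function(w, rate) {
  stopifnot(inherits(w, "waveform"))
  if (rate <= 0) stop("rate must be positive")
  waveform(phase_vocoder_stretch(w$samples, rate), w$sample_rate,
           w$sensor_id, w$split)
}

#' Pitch-shift a waveform
#'
#' Shifts pitch by a number of semitones while preserving duration
#' (resampling followed by phase-vocoder stretching).
#'
#' @param w A [waveform()].
#' @param semitones Shift in semitones (positive raises pitch).
#' @return A [waveform()] of (almost exactly) the input duration.
#' @export
pitch_shift <- function(w, semitones) {
  stopifnot(inherits(w, "waveform"))
  if (semitones == 0) return(w)
  factor <- 2^(semitones / 12)
  fast <- resample_by_factor(w$samples, factor)        # shorter & higher
  y <- phase_vocoder_stretch(fast, 1 / factor)         # restore duration
  n <- length(w$samples)
  if (length(y) >= n) y <- y[seq_len(n)] else y <- c(y, numeric(n - length(y)))
  waveform(y, w$sample_rate, w$sensor_id, w$split)
}

fix_length <- function(x, n) {
  if (length(x) == n) return(x)
  if (length(x) > n) {
    lo <- (length(x) - n) %/% 2 + 1
    x[lo:(lo + n - 1)]
  } else {
    pad <- n - length(x)
    c(numeric(pad %/% 2), x, numeric(pad - pad %/% 2))
  }
}

#' Augmentation specification
#'
#' Exactly one digital audio effect per augmented clip: a pitch shift, a
#' time stretch, or the addition of background noise from a sensor in the
#' same dataset split.
#'
#' @param kind `"pitch_shift"`, `"time_stretch"` or `"add_noise"`.
#' @param shift Pitch shift in semitones (pitch_shift only).
#' @param rate Stretch factor (time_stretch only).
#' @param noise_sensor Source sensor of the background noise (add_noise).
#' @param snr_db Signal-to-noise ratio of the mix in dB (add_noise);
#'   `Inf` leaves the clip untouched.
#' @return A list of class `augmentation_spec`.
#' @export
augmentation_spec <- function(kind = c("pitch_shift", "time_stretch", "add_noise"),
                              shift = NULL, rate = NULL, noise_sensor = NULL,
                              snr_db = NULL) {
  kind <- match.arg(kind)
  if (kind == "time_stretch" && (is.null(rate) || rate <= 0)) {
    stop("rate must be positive")
  }
  structure(list(kind = kind, shift = shift, rate = rate,
                 noise_sensor = noise_sensor, snr_db = snr_db),
            class = "augmentation_spec")
}

#' Apply one augmentation to a clip
#'
#' Pitch shifts preserve duration; time stretches change the amount of
#' material by `1 / rate` and the result is center-cropped or zero-padded
#' back to the clip length; noise addition mixes a background excerpt at
#' the specified SNR. The noise source and the clip must belong to the
#' same dataset split — anything else would leak information across the
#' leave-one-sensor-out folds.
#'
#' @param clip A [waveform()] training/validation clip.
#' @param spec An [augmentation_spec()].
#' @param noise A [waveform()] background excerpt (required for
#'   `add_noise`), at least as long as the clip.
#' @return The augmented [waveform()], same length as `clip`.
#' @export
augment <- function(clip, spec, noise = NULL) {
  stopifnot(inherits(clip, "waveform"), inherits(spec, "augmentation_spec"))
  n <- length(clip$samples)
  out <- switch(spec$kind,
    pitch_shift = pitch_shift(clip, spec$shift),
    time_stretch = {
      y <- time_stretch(clip, spec$rate)
      waveform(fix_length(y$samples, n), clip$sample_rate, clip$sensor_id,
               clip$split)
    },
    add_noise = {
      if (is.null(noise)) stop("add_noise requires a noise excerpt")
      if (!identical(noise$split, clip$split)) {
        stop("augmentation leaks across splits: clip and noise must share a split")
      }
      if (is.infinite(spec$snr_db)) {
        clip
      } else {
        nz <- fix_length(noise$samples, n)
        p_sig <- mean(clip$samples^2)
        p_nz <- mean(nz^2)
        if (p_nz == 0) stop("silent noise excerpt")
        gain <- sqrt(p_sig / (p_nz * 10^(spec$snr_db / 10)))
        waveform(clip$samples + gain * nz, clip$sample_rate,
                 clip$sensor_id, clip$split)
      }
    }
  )
  out
}

#' Build a randomized augmentation plan for a clip manifest
#'
#' Geometrical data augmentation (GDA) draws 4 pitch shifts (uniform in
#' +/- 1 semitone) and 4 time stretches (log-uniform rate in 0.9–1.1) per
#' clip. Adaptive data augmentation (ADA) additionally draws 4 background
#' noise mixes (SNR uniform in -6 to +6 dB) from every training sensor —
#' 20 variants per clip with 3 training sensors. ADA is refused for
#' context-adaptive model configurations: mixing extraneous noise into the
#' clip without recomputing the 30-minute auxiliary features would
#' deliberately desynchronize the two branches.
#'
#' @param manifest Data frame with at least `sensor_id` and `split`
#'   columns, one row per clip.
#' @param mode `"GDA"` or `"GDA+ADA"`.
#' @param seed Integer seed; identical seeds give identical plans.
#' @param model_config Optional [canet_config()]; an error is raised when
#'   ADA is requested for a non-baseline formulation.
#' @param n_pitch,n_stretch,n_noise Variants per category (defaults 4).
#' @return Data frame of specs: `clip_index`, `kind`, `shift`, `rate`,
#'   `noise_sensor`, `snr_db`.
#' @export
make_augmentation_plan <- function(manifest, mode = c("GDA", "GDA+ADA"),
                                   seed = 1, model_config = NULL,
                                   n_pitch = 4, n_stretch = 4, n_noise = 4) {
  mode <- match.arg(mode)
  stopifnot(all(c("sensor_id", "split") %in% names(manifest)))
  if (mode == "GDA+ADA" && !is.null(model_config) &&
      model_config$formulation != "baseline") {
    stop("adaptive data augmentation cannot be combined with context adaptation")
  }
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    for (j in seq_len(n_pitch)) {
      rows[[length(rows) + 1L]] <- data.frame(
        clip_index = i, kind = "pitch_shift",
        shift = stats::runif(1, -1, 1), rate = NA_real_,
        noise_sensor = NA_character_, snr_db = NA_real_)
    }
    for (j in seq_len(n_stretch)) {
      rows[[length(rows) + 1L]] <- data.frame(
        clip_index = i, kind = "time_stretch", shift = NA_real_,
        rate = exp(stats::runif(1, log(0.9), log(1.1))),
        noise_sensor = NA_character_, snr_db = NA_real_)
    }
    if (mode == "GDA+ADA") {
      same_split <- manifest$split == manifest$split[i]
      sensors <- sort(unique(manifest$sensor_id[same_split]))
      for (sn in sensors) {
        for (j in seq_len(n_noise)) {
          rows[[length(rows) + 1L]] <- data.frame(
            clip_index = i, kind = "add_noise", shift = NA_real_,
            rate = NA_real_, noise_sensor = sn,
            snr_db = stats::runif(1, -6, 6))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Serialize an augmentation plan to JSON
#'
#' @param plan Output of [make_augmentation_plan()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_augmentation_plan <- function(plan, path) {
  jsonlite::write_json(plan, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
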
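# Shared fixtures: tiny model configurations and hand-built containers.

tiny_config <- function(formulation = "baseline", n_hidden = 8, K = 4) {
  canet_config(formulation, conv_channels = c(3, 3, 4), n_hidden = n_hidden,
               aux_kernels = 2, K = K)
}

small_config <- function(formulation = "baseline") {
  canet_config(formulation, conv_channels = c(8, 8, 16), n_hidden = 32)
}

# Wrap a raw probability series as an EDF (20 frames/s convention).
make_edf <- function(values) {
  structure(list(values = values,
                 times = (seq_along(values) - 1) * 0.05 + 0.075,
                 frame_hop = 0.05, start_time = 0.075),
            class = "edf")
}

const_tfm <- function(value, frames = 50, bands = 4, frame_rate = 100,
                      representation = "melspec") {
  tf_matrix(matrix(value, frames, bands), frame_rate, seq_len(bands) * 100,
            representation)
}

# Exhaustive maximum matching by recursion over reference events: the
# independent oracle for the bipartite matcher.
oracle_max_matching <- function(ref, est, tolerance = 0.5) {
  nr <- length(ref); ne <- length(est)
  best <- 0L
  recurse <- function(i, used) {
    if (i > nr) return(0L)
    most <- recurse(i + 1L, used)  # leave ref i unmatched
    for (j in seq_len(ne)) {
      if (!used[j] && abs(ref[i] - est[j]) <= tolerance) {
        used[j] <- TRUE
        most <- max(most, 1L + recurse(i + 1L, used))
        used[j] <- FALSE
      }
    }
    most
  }
  recurse(1L, logical(ne))
}

sine_wave <- function(freq, dur = 1, sr = 22050, amp = 0.5) {
  waveform(amp * sin(2 * pi * freq * (seq_len(round(dur * sr)) - 1) / sr), sr)
}

# Independent greedy oracle for 1-D matching with a uniform tolerance:
# sweeping both sorted lists and pairing the earliest mutually compatible
# events is maximum-cardinality for interval bipartite graphs.
oracle_greedy_matching <- function(ref, est, tolerance = 0.5) {
  i <- 1L; j <- 1L; tp <- 0L
  while (i <= length(ref) && j <= length(est)) {
    if (abs(ref[i] - est[j]) <= tolerance) {
      tp <- tp + 1L; i <- i + 1L; j <- j + 1L
    } else if (ref[i] < est[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  tp
}
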
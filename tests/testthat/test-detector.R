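test_that("the EDF grid covers windows fully inside the recording", {
  set.seed(14)
  w <- waveform(rnorm(22050 * 5) * 0.05, 22050)
  mdl <- canet_init(tiny_config(), seed = 1,
                    frontend = list(representation = "logmelspec",
                                    stft = stft_config(), pcen = NULL))
  e <- compute_edf(w, mdl)
  m <- melspectrogram(w)
  # brute-force oracle: count hops whose 104-frame window fits
  fr <- m$frame_rate
  n_expected <- 0L
  i <- 1L
  repeat {
    start <- 1L + floor((i - 1L) * 0.05 * fr)
    if (start + 103L > nrow(m$values)) break
    n_expected <- n_expected + 1L
    i <- i + 1L
  }
  expect_equal(length(e$values), n_expected)
  expect_equal(e$times[1], 0.075)
  expect_equal(diff(e$times)[1], 0.05)
  expect_true(all(e$values > 0 & e$values < 1))
  expect_error(compute_edf(waveform(rnorm(1000), 22050), mdl), "150 ms")
})

test_that("EDF of a recording equals concatenated EDFs of aligned halves", {
  # halves of 9.6 s = 211,680 samples: a multiple of both the 32-sample
  # STFT hop and the 50 ms EDF hop, so frame grids align exactly
  set.seed(15)
  half <- 211680L
  x <- rnorm(2 * half) * 0.05
  mdl <- canet_init(tiny_config(), seed = 2,
                    frontend = list(representation = "logmelspec",
                                    stft = stft_config(), pcen = NULL))
  e_full <- compute_edf(waveform(x, 22050), mdl)
  e1 <- compute_edf(waveform(x[1:half], 22050), mdl)
  e2 <- compute_edf(waveform(x[(half + 1):(2 * half)], 22050), mdl)
  n_half <- 192L  # 9.6 s / 50 ms hops per half
  expect_equal(e_full$values[seq_along(e1$values)], e1$values,
               tolerance = 1e-12)
  away <- (n_half + 4):(n_half + length(e2$values))  # past the seam
  expect_equal(e_full$values[away],
               e2$values[away - n_half], tolerance = 1e-12)
})

test_that("pick_peaks extracts strict-left/weak-right maxima above threshold", {
  e <- make_edf(c(0, 0.9, 0))
  p <- pick_peaks(e, 0.5)
  expect_equal(nrow(p), 1)
  expect_equal(p$score, 0.9)
  expect_equal(p$time_s, e$times[2])
  expect_equal(nrow(pick_peaks(make_edf(rep(0.8, 10)), 0.5)), 0)  # plateau
  expect_equal(nrow(pick_peaks(make_edf(c(0.9, 0.1, 0.1)), 0.5)), 0)  # edge
  expect_error(pick_peaks(e, 1.5), "tau")
  expect_error(pick_peaks(e, 0), "tau")
})

test_that("greedy spacing suppression keeps the highest peak of a crowd", {
  e <- make_edf(c(0, 0.8, 0, 0.9, 0, 0.7, 0))
  expect_equal(pick_peaks(e, 0.5, 0)$score, c(0.8, 0.9, 0.7))
  # all three peaks sit 100 ms apart, so 150 ms spacing keeps only the top
  kept <- pick_peaks(e, 0.5, 150)
  expect_equal(kept$score, 0.9)
  # brute-force check of the greedy rule: every suppressed peak is within
  # the spacing of a kept, higher-scoring peak
  e2 <- make_edf(c(0, 0.8, 0, 0.9, 0, 0, 0, 0.7, 0))
  kept2 <- pick_peaks(e2, 0.5, 150)
  all_p <- pick_peaks(e2, 0.5, 0)
  for (i in seq_len(nrow(all_p))) {
    if (all_p$time_s[i] %in% kept2$time_s) next
    better <- kept2[kept2$score >= all_p$score[i], ]
    expect_true(any(abs(better$time_s - all_p$time_s[i]) < 0.150))
  }
  expect_equal(kept2$score, c(0.9, 0.7))  # 0.7 is 200 ms from 0.9
})

test_that("raising the threshold never adds events", {
  set.seed(16)
  e <- make_edf(stats::plogis(rnorm(300)))
  taus <- seq(0.1, 0.9, by = 0.1)
  counts <- vapply(taus, function(t) nrow(pick_peaks(e, t)), integer(1))
  expect_true(all(diff(counts) <= 0))
  for (t in c(0.3, 0.6)) {
    p <- pick_peaks(e, t)
    expect_true(all(p$score > t))
  }
})

test_that("zero-spacing mode admits peaks two hops apart", {
  e <- make_edf(rep(c(0.1, 0.9), 10))
  p <- pick_peaks(e, 0.5, 0)
  expect_equal(min(diff(p$time_s)), 0.1)  # 100 ms = two 50 ms hops
})

test_that("clip features are centered and zero-padded at the edges", {
  m <- tf_matrix(matrix(seq_len(500), 500, 4), 100, seq_len(4) * 100,
                 "melspec")
  cl <- clip_features(m, c(2.5), n_frames = 104)
  expect_equal(dim(cl), c(104, 4, 1, 1))
  expect_true(all(cl[, 1, 1, 1] > 0))  # fully interior
  edge <- clip_features(m, c(0.1), n_frames = 104)
  expect_true(any(edge[, 1, 1, 1] == 0))  # padded before the start
  center_val <- cl[52, 1, 1, 1]
  expect_equal(center_val, 250, tolerance = 2)  # frame nearest 2.5 s
})
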
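test_that("a zero event rate yields background-only audio", {
  spec <- night_spec(duration = 10, n_sensors = 2, rate_start = 0,
                     rate_end = 0, seed = 31)
  nt <- synthesize_night(spec, 1)
  expect_equal(nrow(nt$events), 0)
  expect_equal(length(nt$waveform$samples), 10 * 22050)
})

test_that("synthesis is bitwise reproducible per (spec, sensor)", {
  spec <- night_spec(duration = 8, seed = 32)
  a <- synthesize_night(spec, 2)
  b <- synthesize_night(spec, 2)
  expect_identical(a$waveform$samples, b$waveform$samples)
  expect_identical(a$events, b$events)
  c <- synthesize_night(spec, 3)
  expect_false(identical(a$waveform$samples, c$waveform$samples))
})

test_that("arrivals follow the programmed nondecreasing rate ramp", {
  # lambda rises linearly 19x, making the last-third mean 4x the first
  spec <- night_spec(duration = 30, n_sensors = 1, rate_start = 6,
                     rate_end = 114, level_offsets_db = 0, seed = 33)
  first <- 0; last <- 0
  for (k in 1:20) {
    sp <- night_spec(duration = 30, n_sensors = 1, rate_start = 6,
                     rate_end = 114, level_offsets_db = 0, seed = 33 + k)
    ev <- synthesize_night(sp, 1)$events$time_s
    first <- first + sum(ev < 10)
    last <- last + sum(ev >= 20)
  }
  # expected counts from the integral of the linear rate over 20 nights
  e_first <- 20 * (6 + (114 - 6) / 6) / 60 * 10
  e_last <- 20 * (6 + 5 * (114 - 6) / 6) / 60 * 10
  expect_lt(abs(first - e_first), 4 * sqrt(e_first))
  expect_lt(abs(last - e_last), 4 * sqrt(e_last))
  expect_gt(last / first, 2.5)  # ~4x in expectation
})

test_that("clip datasets are balanced with clean negatives", {
  spec <- night_spec(duration = 60, n_sensors = 1, rate_start = 80,
                     rate_end = 80, level_offsets_db = 0, seed = 34)
  nt <- synthesize_night(spec, 1)
  expect_gte(nrow(nt$events), 64)
  manifest <- make_clip_dataset(list(nt), n_per_class = 64, seed = 35)
  expect_equal(nrow(manifest), 128)
  expect_equal(sum(manifest$label), 64)
  pos <- manifest[manifest$label == 1, ]
  expect_true(all(pos$time_s %in% nt$events$time_s))  # centered on events
  neg <- manifest[manifest$label == 0, ]
  for (t in neg$time_s) {
    expect_gte(min(abs(t - nt$events$time_s)), 0.5)
  }
})

test_that("negatives are refused when the background is saturated", {
  spec <- night_spec(duration = 2, n_sensors = 1, rate_start = 2000,
                     rate_end = 2000, level_offsets_db = 0, seed = 36)
  nt <- suppressWarnings(synthesize_night(spec, 1))
  expect_error(
    suppressWarnings(make_clip_dataset(list(nt), n_per_class = 5, seed = 1)),
    "not enough")
})

test_that("the programmed level decay and sensor offsets are measurable", {
  # tone-free background isolates the broadband level programming
  spec <- night_spec(duration = 60, n_sensors = 2, decay_db = 10,
                     rate_start = 0, rate_end = 0,
                     level_offsets_db = c(0, 6), tone_amp = 0, seed = 37)
  m1 <- melspectrogram(synthesize_night(spec, 1)$waveform)
  m2 <- melspectrogram(synthesize_night(spec, 2)$waveform)
  tr1 <- band_spl_trend(m1, 2000, 6000, segment = 5)
  tr2 <- band_spl_trend(m2, 2000, 6000, segment = 5)
  expect_equal(estimate_decay_db(tr1), -10, tolerance = 1)
  expect_equal(mean(tr2$spl_db - tr1$spl_db), 6, tolerance = 1)
})

test_that("event band labels match the rendered spectral content", {
  spec <- night_spec(duration = 20, n_sensors = 1, rate_start = 30,
                     rate_end = 30, level_offsets_db = 0,
                     noise_sigma = 1e-4, tone_amp = 0, seed = 38)
  nt <- synthesize_night(spec, 1)
  m <- melspectrogram(nt$waveform)
  for (i in seq_len(nrow(nt$events))) {
    cl <- clip_features(m, nt$events$time_s[i])[, , 1, 1]
    prof <- colSums(cl)
    centroid <- sum(prof * m$band_centers) / sum(prof)
    if (nt$events$band_label[i] == "low") {
      expect_lt(centroid, 5000)
    } else {
      expect_gt(centroid, 5000)
    }
  }
})
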
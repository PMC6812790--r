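test_that("a zero-semitone pitch shift is the identity", {
  w <- sine_wave(3000, dur = 0.15)
  out <- augment(w, augmentation_spec("pitch_shift", shift = 0))
  rel_rms <- sqrt(mean((out$samples - w$samples)^2) / mean(w$samples^2))
  expect_lt(rel_rms, 1e-3)
})

test_that("pitch shifting moves the dominant frequency and keeps duration", {
  w <- sine_wave(2000, dur = 0.3)
  up <- pitch_shift(w, 12)  # one octave
  expect_equal(length(up$samples), length(w$samples))
  spec <- Mod(stats::fft(up$samples * flightcall:::hann_window(
    length(up$samples))))
  n <- length(spec)
  f_peak <- (which.max(spec[1:(n / 2)]) - 1) * 22050 / n
  expect_equal(f_peak, 4000, tolerance = 100)
})

test_that("time stretching follows the length arithmetic before re-padding", {
  w <- sine_wave(3000, dur = 0.15)  # 3307 samples
  st <- time_stretch(w, 2.0)
  expect_equal(length(st$samples), round(length(w$samples) / 2))
  out <- augment(w, augmentation_spec("time_stretch", rate = 2.0))
  expect_equal(length(out$samples), length(w$samples))  # re-padded to 150 ms
  # half the padded clip is the stretched material, the rest zeros
  expect_equal(sum(out$samples != 0), length(st$samples), tolerance = 50)
  expect_error(augmentation_spec("time_stretch", rate = -1), "positive")
})

test_that("noise addition respects SNR and split purity", {
  set.seed(21)
  clip <- waveform(rnorm(3307) * 0.1, 22050, "a", "train")
  noise <- waveform(rnorm(5000) * 0.2, 22050, "b", "train")
  inf_mix <- augment(clip, augmentation_spec("add_noise", noise_sensor = "b",
                                             snr_db = Inf), noise)
  expect_identical(inf_mix$samples, clip$samples)
  mix0 <- augment(clip, augmentation_spec("add_noise", noise_sensor = "b",
                                          snr_db = 0), noise)
  added <- mix0$samples - clip$samples
  snr_obs <- 10 * log10(mean(clip$samples^2) / mean(added^2))
  expect_equal(snr_obs, 0, tolerance = 0.2)
  noise_val <- waveform(rnorm(5000), 22050, "b", "validation")
  expect_error(augment(clip, augmentation_spec("add_noise", snr_db = 0),
                       noise_val), "leaks across splits")
})

test_that("augmentation plans have the published shape: 4 + 4 + 4 x sensors", {
  manifest <- data.frame(sensor_id = rep(c("u1", "u2", "u3"), length.out = 10),
                         split = "train")
  plan <- make_augmentation_plan(manifest, "GDA+ADA", seed = 5)
  expect_equal(nrow(plan), 10 * (4 + 4 + 4 * 3))  # 200 specs
  expect_equal(nrow(make_augmentation_plan(manifest, "GDA", seed = 5)), 80)
  gda <- make_augmentation_plan(manifest, "GDA", seed = 5)
  expect_false(any(gda$kind == "add_noise"))
  plan2 <- make_augmentation_plan(manifest, "GDA+ADA", seed = 5)
  expect_identical(plan, plan2)  # same seed, same plan
  # parameter ranges
  expect_true(all(abs(plan$shift[plan$kind == "pitch_shift"]) <= 1))
  expect_true(all(plan$rate[plan$kind == "time_stretch"] >= 0.9 &
                    plan$rate[plan$kind == "time_stretch"] <= 1.1))
  expect_true(all(abs(plan$snr_db[plan$kind == "add_noise"]) <= 6))
})

test_that("ADA is refused for context-adaptive configurations", {
  manifest <- data.frame(sensor_id = "u1", split = "train")
  expect_error(
    make_augmentation_plan(manifest, "GDA+ADA",
                           model_config = canet_config("at")),
    "cannot be combined")
  # but allowed for the baseline
  p <- make_augmentation_plan(manifest, "GDA+ADA",
                              model_config = canet_config("baseline"))
  expect_true(any(p$kind == "add_noise"))
})

test_that("plans never pair clips and noise across splits", {
  manifest <- data.frame(
    sensor_id = c("u1", "u2", "u3", "u4"),
    split = c("train", "train", "validation", "validation"))
  plan <- make_augmentation_plan(manifest, "GDA+ADA", seed = 6)
  noise_rows <- plan[plan$kind == "add_noise", ]
  for (i in seq_len(nrow(noise_rows))) {
    clip_split <- manifest$split[noise_rows$clip_index[i]]
    noise_split <- manifest$split[manifest$sensor_id ==
                                    noise_rows$noise_sensor[i]][1]
    expect_identical(clip_split, noise_split)
  }
})
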
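# Preprocessing chain: filtering, re-referencing, down-sampling,
# epoching, baseline correction, and energy preservation through the
# whole chain.

fs <- 512
tt <- (0:(fs * 4 - 1)) / fs

test_that("band-pass filter removes DC, keeps the passband, kills the stopband", {
  # DC on a 20-s record: the 0.5 Hz high-pass leaves only edge transients
  dc <- raw_from_matrix(matrix(5, 1, fs * 20), fs)
  out <- bandpass_filter(dc, 0.5, 40)
  expect_lt(abs(mean(out$samples)), 0.05)
  mid <- out$samples[1, (5 * fs):(15 * fs)]
  expect_lt(max(abs(mid)), 0.01)

  tone10 <- raw_from_matrix(matrix(sin(2 * pi * 10 * tt), 1), fs)
  out10 <- bandpass_filter(tone10, 0.5, 40)
  expect_gt(fft_amplitude(out10$samples[1, ], fs, 10), 0.95)   # < 5% loss

  tone100 <- raw_from_matrix(matrix(sin(2 * pi * 100 * tt), 1), fs)
  out100 <- bandpass_filter(tone100, 0.5, 40)
  expect_lt(fft_amplitude(out100$samples[1, ], fs, 100), 0.10) # > 90% attenuation

  expect_error(bandpass_filter(tone10, 40, 0.5), class = "eegdwt_bad_band")
  expect_error(bandpass_filter(tone10, 0.5, 300), class = "eegdwt_bad_band")
})

test_that("average re-reference zeroes the cross-channel mean and keeps differences", {
  v <- sin(2 * pi * 7 * tt)
  sym <- raw_from_matrix(rbind(v, -v), fs)
  out <- rereference_average(sym)
  expect_equal(out$samples, sym$samples)

  same <- raw_from_matrix(rbind(v, v, v), fs)
  expect_true(all(abs(rereference_average(same)$samples) < 1e-12))

  set.seed(3)
  X <- matrix(rnorm(16 * 1000), 16, 1000)
  out16 <- rereference_average(raw_from_matrix(X, fs))
  expect_lt(max(abs(colMeans(out16$samples))), 1e-10)

  expect_error(rereference_average(raw_from_matrix(matrix(v, 1), fs)),
               class = "eegdwt_single_channel")
})

test_that("down-sampling decimates, rescales events, and anti-aliases", {
  ev <- data.frame(onset_sample = c(0L, 512L), condition = c("rest", "picking"),
                   trial_index = c(NA, 1L), string_id = c(NA, 3L),
                   duration_s = c(1, 1))
  r <- raw_from_matrix(matrix(sin(2 * pi * 10 * tt), 1), fs, events = ev)
  d <- downsample(r, 64)
  expect_equal(ncol(d$samples), length(tt) / 8)
  expect_equal(d$fs, 64)
  expect_equal(d$events$onset_sample, c(0L, 64L))
  expect_gt(fft_amplitude(d$samples[1, ], 64, 10), 0.95)

  r40 <- raw_from_matrix(matrix(sin(2 * pi * 40 * tt), 1), fs)
  d40 <- downsample(r40, 64)
  # 40 Hz is above the new Nyquist (32 Hz): total residual power < 1% of input
  expect_lt(sqrt(mean(d40$samples^2)) / sqrt(0.5), 0.10)

  expect_error(downsample(raw_from_matrix(matrix(v <- rnorm(300), 1), 96), 64),
               class = "eegdwt_bad_ratio")
})

test_that("epoch extraction yields one epoch per task event plus segmented rest", {
  cfg <- fast_config(seed = 9)
  rec <- generate_participant_recording(cfg, 1)
  ep <- preprocess_recording(rec)
  info <- ep$info
  expect_equal(dim(ep$data)[3], 64)
  expect_equal(ep$fs, 64)
  expect_equal(sum(info$condition == "picking"), 12)
  expect_equal(sum(info$condition == "coordination"), 12)
  expect_equal(sum(info$condition == "rest"), floor(cfg$rest_duration / 1))
  expect_equal(nrow(info), dim(ep$data)[1])
  # rest epochs carry a counter, task epochs a trial index
  expect_true(all(!is.na(info$rest_epoch[info$condition == "rest"])))
  expect_true(all(!is.na(info$trial_index[info$condition != "rest"])))
})

test_that("a 2-minute rest block yields 120 rest epochs", {
  cfg <- sim_config(n_participants = 1, channels = frontal_electrodes(),
                    fs_raw = 128, trial_duration = 1, rest_duration = 120,
                    inter_trial_gap = 0.25, seed = 2)
  rec <- generate_participant_recording(cfg, 1)
  ep <- preprocess_recording(rec)
  expect_equal(sum(ep$info$condition == "rest"), 120)
})

test_that("an event whose window exceeds the record is dropped with a warning", {
  n <- 64 * 3
  ev <- data.frame(onset_sample = c(0L, 64L, n - 1L),
                   condition = c("picking", "picking", "picking"),
                   trial_index = 1:3, string_id = 1:3, duration_s = 1)
  # last event starts at the final sample: window truncated
  ev$duration_s[3] <- 1 / 64
  r <- raw_from_matrix(matrix(rnorm(2 * n), 2), 64, labels = c("Fp1", "Fp2"),
                       events = ev)
  expect_warning(ep <- extract_epochs(r), "dropped 1")
  expect_equal(dim(ep$data)[1], 2)  # epochs out = events in minus drops
})

test_that("baseline correction zeroes every epoch-channel mean", {
  cfg <- tiny_config(seed = 13)
  rec <- generate_participant_recording(cfg, 1)
  ep <- baseline_correct(extract_epochs(downsample(rec, 64)))
  means <- apply(ep$data, c(1, 2), mean)
  scale <- max(abs(ep$data))
  expect_lt(max(abs(means)), 1e-9 * scale)

  # constant epoch -> all zeros; zero-mean epoch -> unchanged
  const <- ep; const$data[] <- 7
  expect_true(all(baseline_correct(const)$data == 0))
  sine <- ep
  sine$data[] <- rep(sin(2 * pi * 8 * (0:63) / 64 + 0.3) -
                       mean(sin(2 * pi * 8 * (0:63) / 64 + 0.3)),
                     each = prod(dim(ep$data)[1:2]))
  expect_equal(baseline_correct(sine)$data, sine$data, tolerance = 1e-12)
})

test_that("in-band tone energy survives the full preprocessing chain within 10%", {
  # pure in-band tones embedded in a long record; compare epoch energy
  # after the chain with the ideal 1-s tone energy at 64 Hz
  for (f in c(6, 10, 20)) {
    n <- fs * 6
    sig <- sin(2 * pi * f * (0:(n - 1)) / fs)
    ev <- data.frame(onset_sample = c(0L, 2L * fs, 4L * fs),
                     condition = "picking", trial_index = 1:3,
                     string_id = 1:3, duration_s = 1)
    raw <- raw_from_matrix(rbind(sig, -sig), fs, labels = c("F3", "F4"),
                           events = ev)
    ep <- preprocess_recording(raw)
    e_out <- sum(ep$data[2, 1, ]^2)
    e_ideal <- sum(sin(2 * pi * f * (0:63) / 64)^2)
    expect_lt(abs(e_out - e_ideal) / e_ideal, 0.10)
  }
})
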
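test_that("band-pass preserves the passband and rejects the stopband", {
  # a 0.1 Hz high-pass has seconds of memory, so the contract is measured on
  # a long tone, away from the pad-influenced edges
  rec <- tone_recording(c(10, 50), duration_s = 60)
  out <- bandpass_filter(rec, 0.1, 30)
  amp10 <- tone_amplitude(out$data[1, ], trim = 0.3)
  amp50 <- tone_amplitude(out$data[2, ], trim = 0.3)
  expect_gt(amp10, 0.95); expect_lt(amp10, 1.05)
  expect_lt(amp50, 0.1)
})

test_that("high-pass rejects DC and validates cutoffs", {
  rec <- eeg_recording(matrix(5, 2, 2000), fs = 250)
  out <- bandpass_filter(rec, 0.1, NULL)
  expect_lt(abs(mean(out$data)), 0.05 * 5)
  expect_error(bandpass_filter(tone_recording(10), 130, NULL), "Nyquist")
  expect_error(bandpass_filter(tone_recording(10), 30, 10), "inverted")
})

test_that("line-noise removal is a narrow spectral notch", {
  rec <- tone_recording(c(50, 10))
  out <- remove_line_noise(rec)
  p50_before <- band_power(rec$data[1, ], 250, 49, 51)
  p50_after <- band_power(out$data[1, ], 250, 49, 51)
  expect_lt(p50_after / p50_before, 10^(-20 / 10))  # >= 20 dB down
  expect_lt(abs(tone_amplitude(out$data[2, ]) - 1), 0.05)
  # null input stays null
  zero <- eeg_recording(matrix(0, 1, 1000), fs = 250)
  expect_lt(max(abs(remove_line_noise(zero)$data)), 1e-9)
  expect_error(remove_line_noise(rec, c(55, 45)), "increasing")
})

test_that("notch leaves broadband power outside the band nearly unchanged", {
  set.seed(31)
  rec <- eeg_recording(matrix(rnorm(3e4), 1), fs = 250)
  out <- remove_line_noise(rec)
  # compare power below 40 Hz (clear of the transition bands)
  before <- band_power(rec$data[1, ], 250, 1, 40)
  after <- band_power(out$data[1, ], 250, 1, 40)
  expect_lt(abs(after / before - 1), 0.05)
})

test_that("scalp selection by projected radius keeps 137 of 256 channels", {
  m <- synthetic_geodesic_montage()
  rec <- eeg_recording(matrix(rnorm(256 * 100), 256), fs = 250,
                       channel_names = m$name, montage = m)
  sel <- select_scalp_channels(rec)
  expect_identical(n_channels(sel), 137L)
  expect_identical(sel$channel_names, sel$montage$name)
  expect_identical(n_channels(select_scalp_channels(rec, Inf)), 256L)
  expect_error(select_scalp_channels(rec, -1), "no channels")
  bare <- eeg_recording(matrix(rnorm(200), 2), fs = 250)
  expect_error(select_scalp_channels(bare), "montage")
})

test_that("decimation halves the sample count and keeps sub-Nyquist tones", {
  rec <- eeg_recording(matrix(rnorm(2 * 1000), 2), fs = 250)
  out <- resample_recording(rec, 125)
  expect_identical(ncol(out$data), 500L)
  expect_identical(out$fs, 125)
  tone <- tone_recording(20, duration_s = 8)
  down <- resample_recording(tone, 125)
  expect_lt(abs(tone_amplitude(down$data[1, ]) - 1), 0.05)
  expect_identical(resample_recording(rec, 250), rec)
  expect_error(resample_recording(rec, 500), "upsampling")
  expect_error(resample_recording(rec, 100), "divide")
})

test_that("common-average reference zeroes the channel mean and is idempotent", {
  set.seed(8)
  rec <- eeg_recording(matrix(rnorm(5 * 300), 5), fs = 250)
  out <- rereference_to_mean(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-9 * sd(rec$data))
  expect_equal(rereference_to_mean(out)$data, out$data)
  # an already mean-zero pair is unchanged
  v <- rnorm(100)
  pair <- eeg_recording(rbind(v, -v), fs = 250, channel_names = c("a", "b"))
  expect_equal(rereference_to_mean(pair)$data, pair$data, ignore_attr = TRUE)
  single <- eeg_recording(matrix(rnorm(100), 1), fs = 250)
  expect_error(rereference_to_mean(single), "2 channels")
})

test_that("artifact rejection masks exactly the windows a pulse overlaps", {
  set.seed(12)
  rec <- eeg_recording(matrix(rnorm(2 * 2500), 2), fs = 250)
  clean <- reject_artifact_segments(rec, 500, 200)
  expect_false(any(clean$mask))
  # inject a 1000 uV square pulse spanning samples 301..340 on channel 2
  rec$data[2, 301:340] <- 1000
  rej <- reject_artifact_segments(rec, 500, 200)  # 50-sample windows
  masked_windows <- unique((which(rej$mask) - 1) %/% 50) + 1
  expect_equal(masked_windows, 7)  # samples 301..350 only
  expect_true(all(rej$windows$channel == "ch2"))
  expect_error(reject_artifact_segments(rec, 0, 200), "unusable")
  expect_error(reject_artifact_segments(rec, 500, 0), "positive")
})

test_that("epoching yields the documented window arithmetic and alignment", {
  set.seed(3)
  rec <- eeg_recording(matrix(rnorm(2 * 5000), 2), fs = 250)
  onsets <- seq(2000, 11000, by = 1000)  # 10 interior onsets (ms)
  sch <- data.frame(onset_ms = onsets, condition = "x")
  ep <- epoch_recording(rec, sch)
  expect_identical(dim(ep$data), c(10L, 2L, 300L))
  expect_true(0 %in% ep$times_ms)
  # an onset at the recording start loses its pre-stimulus window
  sch2 <- rbind(data.frame(onset_ms = 0, condition = "x"), sch)
  expect_identical(dim(epoch_recording(rec, sch2)$data)[1], 10L)
  # impulse alignment: the epoch value at t = 0 is the impulse
  rec2 <- eeg_recording(matrix(0, 1, 1000), fs = 250)
  rec2$data[1, 501] <- 7  # sample 501 = 2000 ms
  ep2 <- epoch_recording(rec2, data.frame(onset_ms = 2000, condition = "x"))
  expect_equal(ep2$data[1, 1, which(ep2$times_ms == 0)], 7)
  expect_error(epoch_recording(rec, sch[0, ]), "empty")
})

test_that("baseline correction zeroes the pre-stimulus mean, shift-invariantly", {
  ep <- template_epochs(5, noise_sd = 3, seed = 10)
  bc <- baseline_correct(ep)
  idx <- bc$times_ms >= -200 & bc$times_ms < 0
  bl_means <- apply(bc$data[, , idx, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl_means)), 1e-9 * sd(ep$data))
  shifted <- ep; shifted$data <- shifted$data + 42
  expect_equal(baseline_correct(shifted)$data, bc$data)
  expect_error(baseline_correct(ep, c(0, 0)), "increasing")
})

test_that("channel selection commutes with filtering and resampling", {
  m <- scalp_montage_137()[1:8, ]
  m$radius <- c(rep(0.3, 5), rep(0.6, 3))
  set.seed(77)
  rec <- eeg_recording(matrix(rnorm(8 * 2000), 8), fs = 250,
                       channel_names = m$name, montage = m)
  a <- select_scalp_channels(resample_recording(bandpass_filter(rec, 1, 40), 125))
  b <- resample_recording(bandpass_filter(select_scalp_channels(rec), 1, 40), 125)
  expect_equal(a$data, b$data, tolerance = 1e-6)
  expect_identical(a$channel_names, b$channel_names)
})

test_that("pipelines are deterministic data transforms", {
  rr <- small_render(n_channels = 16, n_cascades = 40, duration_s = 30, seed = 55)
  rec <- rr$recording
  a <- classification_preprocess(rec)
  b <- classification_preprocess(rec)
  expect_identical(a$data, b$data)
  expect_identical(a$fs, 125)
  expect_true(all(is.finite(a$data)))
})
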
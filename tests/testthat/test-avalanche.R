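test_that("z-scoring standardizes channels under the population convention", {
  set.seed(21)
  rec <- eeg_recording(matrix(rnorm(3 * 500, mean = 4, sd = 7), 3), fs = 250)
  z <- zscore_channels(rec)
  expect_lt(max(abs(rowMeans(z$data))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(z$data^2)) - 1)), 1e-9)
  # affine transforms leave z-scores unchanged
  rec2 <- rec; rec2$data[2, ] <- 3 * rec2$data[2, ] - 11
  expect_equal(zscore_channels(rec2)$data[2, ], z$data[2, ])
  # two-sample hand case: (0, 2) -> (-1, +1)
  tiny <- eeg_recording(matrix(c(0, 2), 1), fs = 250)
  expect_equal(as.numeric(zscore_channels(tiny)$data), c(-1, 1))
  flat <- eeg_recording(matrix(c(rnorm(100), rep(1, 100)), 2, byrow = TRUE),
                        fs = 250, channel_names = c("ok", "flat"))
  expect_error(zscore_channels(flat), "flat")
})

test_that("event extraction returns one event per excursion at its extremum", {
  zero <- eeg_recording(matrix(0.1 * sin(2 * pi * 5 * (0:999) / 250), 1), fs = 250)
  z <- zscore_channels(zero)  # a sine never exceeds sqrt(2) SD
  expect_identical(sum(lengths(extract_events(z, 2.7))), 0L)
  # triangular pulse peaking at sample 100
  set.seed(5)
  x <- rnorm(1000, sd = 0.01)
  x[95:105] <- 4 * (1 - abs(-5:5) / 6)
  rec <- eeg_recording(matrix(x / sqrt(mean((x - mean(x))^2)), 1), fs = 250)
  ev <- extract_events(rec, 2.7)
  expect_identical(as.integer(ev[[1]]), 100L)
})

test_that("suprathreshold fraction of Gaussian noise matches the 2.7 SD tail", {
  set.seed(99)
  n <- 1e6
  rec <- eeg_recording(matrix(rnorm(n), 1), fs = 250)
  z <- zscore_channels(rec)
  frac <- mean(abs(z$data) > 2.7)
  p <- 2 * (1 - pnorm(2.7))
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("event binning conserves counts and the 24 ms = 3 sample rule", {
  ev <- structure(list(a = c(1L, 2L, 3L)), n_samples = 9L, fs = 125)
  raster <- bin_events(ev, bin_width_ms = 24)
  expect_identical(raster$samples_per_bin, 3L)
  expect_equal(raster$counts[1, ], c(3, 0, 0), ignore_attr = TRUE)
  expect_identical(raster$total_events, 3L)
  empty <- structure(list(a = integer(0)), n_samples = 9L, fs = 125)
  expect_true(all(bin_events(empty, bin_width_ms = 24)$counts == 0))
  expect_error(bin_events(ev, bin_width_ms = 2), "whole number")
  # trailing partial bin is dropped
  ev2 <- structure(list(a = c(1L, 8L)), n_samples = 8L, fs = 125)
  r2 <- bin_events(ev2, bin_width_ms = 24)
  expect_identical(ncol(r2$counts), 2L)
  expect_identical(r2$total_events, 1L)
})

test_that("avalanche segmentation follows the hand-enumerated runs", {
  mk_raster <- function(totals) {
    structure(list(counts = matrix(totals, 1), bin_width_ms = 24,
                   samples_per_bin = 3L, n_samples_source = length(totals) * 3L,
                   total_events = sum(totals)), class = "event_raster")
  }
  av <- segment_avalanches(mk_raster(c(0, 2, 0, 1, 3, 0, 4)))
  expect_identical(length(av), 2L)
  expect_equal(vapply(av, `[[`, numeric(1), "size"), c(2, 4))
  expect_equal(av[[2]]$per_bin_counts, c(1, 3))
  av_keep <- segment_avalanches(mk_raster(c(0, 2, 0, 1, 3, 0, 4)), "keep")
  expect_identical(length(av_keep), 3L)
  expect_identical(length(segment_avalanches(mk_raster(rep(0, 5)))), 0L)
  one <- segment_avalanches(mk_raster(c(0, 5, 0)))
  expect_identical(length(one), 1L)
  expect_equal(one[[1]]$size, 5)
  expect_equal(one[[1]]$duration, 1L)
})

test_that("interior avalanche sizes conserve interior binned events", {
  rr <- small_render(n_channels = 32, n_cascades = 60, duration_s = 40, seed = 61)
  z <- zscore_channels(rr$recording)
  raster <- bin_events(extract_events(z, 2.7), bin_width_ms = 24)
  av <- segment_avalanches(raster)
  totals <- colSums(raster$counts)
  occ <- rle(totals > 0)
  ends <- cumsum(occ$lengths); starts <- ends - occ$lengths + 1
  interior <- sum(unlist(lapply(which(occ$values), function(k) {
    if (starts[k] == 1 || ends[k] == length(totals)) 0 else
      sum(totals[starts[k]:ends[k]])
  })))
  expect_equal(sum(vapply(av, `[[`, numeric(1), "size")), interior)
})

test_that("the MLE exponent matches the brute-force grid oracle", {
  for (true_a in c(-1.3, -1.8, -2.5)) {
    x <- rpowerlaw_discrete(5000, true_a, seed = round(-100 * true_a))
    mle <- fit_size_exponent(x)
    oracle <- grid_search_exponent(x)
    expect_lt(abs(mle - oracle), 2e-3)
  }
  expect_error(fit_size_exponent(rep(1, 200)), "degenerate")
  expect_error(fit_size_exponent(1:50), "at least 100")
})

test_that("branching estimation follows the second/first-bin ratio definition", {
  expect_equal(estimate_branching(list(c(1, 2), 1)), 1.0)
  expect_equal(estimate_branching(list(3, 1, 5)), 0)  # duration-1 only
  expect_error(estimate_branching(list()), "empty")
  # unbiased for the Poisson branching generator
  cs <- simulate_branching_cascades(8, 0.9, 20000, seed = 14, make_rasters = FALSE)
  expect_lt(abs(estimate_branching(cs) - 0.9), 0.03)
})

test_that("the bin-width sweep emits one deterministic row per multiplier", {
  rr <- small_render(n_channels = 32, n_cascades = 60, duration_s = 40, seed = 71)
  rec <- rr$recording
  tab <- sweep_bin_widths(rec, detection_config(base_dt_ms = 4))
  expect_identical(nrow(tab), 10L)
  expect_equal(tab$bin_width_ms, 4 * (1:10))
  expect_identical(sweep_bin_widths(rec, detection_config(base_dt_ms = 4)), tab)
  # merging: coarser bins reduce the avalanche count, up to single-cascade
  # fluctuations where successive bin widths do not nest
  expect_true(all(diff(tab$n_avalanches) <= 1))
  expect_lte(tab$n_avalanches[3], tab$n_avalanches[1])
  expect_lt(tab$n_avalanches[10], tab$n_avalanches[1])
})

test_that("feature extraction recovers critical dynamics from rendered signal", {
  rr <- small_render(n_channels = 64, sigma = 1, n_cascades = 200,
                     duration_s = 90, seed = 81)
  feats <- compute_features(rr$recording,
                            detection_config(base_dt_ms = 8, dt_multiplier = 3))
  expect_gt(feats$sigma, 0.9); expect_lt(feats$sigma, 1.1)
  expect_gt(feats$alpha, -1.7); expect_lt(feats$alpha, -1.35)
  feats2 <- compute_features(rr$recording,
                             detection_config(base_dt_ms = 8, dt_multiplier = 3))
  expect_identical(feats, feats2)
  # an event-free recording has no avalanches to fit
  sine <- tone_recording(c(7, 9), duration_s = 8)
  expect_error(compute_features(sine), "no avalanches")
  ag <- aggregate_features(list(feats, feats2))
  expect_equal(ag$alpha_mean, feats$alpha)
  expect_identical(ag$n_recordings, 2L)
})
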
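test_that("pure Gaussian background crosses 2.7 SD at the analytic rate", {
  rr <- render_resting_recording(NULL, fs = 250, duration_s = 50,
                                 n_channels = 16,
                                 noise_model = resting_noise_model(
                                   pink = FALSE, line_hz = NULL, osc_amp_sd = 0),
                                 seed = 30)
  expect_null(rr$truth)
  z <- zscore_channels(rr$recording)
  frac <- mean(abs(z$data) > 2.7)
  p <- 2 * (1 - pnorm(2.7))
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / length(z$data)))
})

test_that("rendering is bit-deterministic and respects capacity limits", {
  cs <- simulate_branching_cascades(16, 0.8, 30, seed = 31, max_duration = 15)
  a <- render_resting_recording(cs, duration_s = 20, seed = 32)
  b <- render_resting_recording(cs, duration_s = 20, seed = 32)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth, b$truth)
  expect_error(render_resting_recording(cs, duration_s = 1, seed = 32),
               "duration too short")
  no_raster <- simulate_branching_cascades(16, 0.8, 30, seed = 31,
                                           make_rasters = FALSE)
  expect_error(render_resting_recording(no_raster, duration_s = 20), "rasters")
})

test_that("default amplitudes keep injected events recoverable at the detector", {
  cs <- simulate_branching_cascades(32, 0.9, 80, seed = 33, max_duration = 15)
  rr <- render_resting_recording(cs, duration_s = 40, seed = 34)
  z <- zscore_channels(rr$recording)
  raster <- bin_events(extract_events(z, 2.7), bin_width_ms = 24)
  det <- which(raster$counts > 0, arr.ind = TRUE)
  det_keys <- paste(rownames(raster$counts)[det[, 1]], det[, 2])
  truth_keys <- paste(rr$truth$channel, rr$truth$bin)
  expect_gte(mean(truth_keys %in% det_keys), 0.95)
})

test_that("ERP trial synthesis is linear in the template", {
  tpl <- default_erp_template("face_recognition", electrodes = c("E98", "E99"))
  noiseless <- synthesize_erp_trials(tpl, 3, noise_sd_uv = 0)
  for (i in 1:3)
    expect_equal(noiseless$data[i, , ], unclass(tpl), ignore_attr = TRUE)
  doubled <- synthesize_erp_trials(tpl, 3, noise_sd_uv = 0, amplitude_scale = 2)
  expect_equal(apply(doubled$data, c(2, 3), mean), 2 * unclass(tpl),
               ignore_attr = TRUE)
  shifted <- synthesize_erp_trials(tpl, 1, noise_sd_uv = 0, latency_shift_ms = 40)
  k <- round(40 * 250 / 1000)
  expect_equal(shifted$data[1, 1, (k + 1):300], tpl[1, 1:(300 - k)],
               ignore_attr = TRUE)
  bare <- matrix(rnorm(300), 1)  # no fs/tmin attributes: grid unknown
  expect_error(synthesize_erp_trials(bare, 3), "grid mismatch")
})

test_that("trial-average error shrinks like one over sqrt(n)", {
  tpl <- default_erp_template("digit_span", electrodes = "E98")
  rmse_at <- function(n) {
    ep <- synthesize_erp_trials(tpl, n, noise_sd_uv = 10, seed = 40 + n)
    sqrt(mean((apply(ep$data, c(2, 3), mean) - tpl)^2))
  }
  r <- vapply(c(25, 100, 400), rmse_at, numeric(1))
  expect_lt(abs(r[1] / r[2] - 2), 0.8)  # sqrt(100/25) = 2
  expect_lt(abs(r[2] / r[3] - 2), 0.8)  # sqrt(400/100) = 2
})

test_that("the default study design is three cohorts of forty", {
  specs <- default_cohort_specs()
  expect_identical(vapply(specs, `[[`, character(1), "label"), c(A = "A", B = "B", C = "C"))
  expect_identical(sum(vapply(specs, `[[`, integer(1), "n_subjects")), 120L)
  # amplitude ordering B > A > C
  amp <- vapply(specs, `[[`, numeric(1), "erp_amplitude_scale")
  expect_true(amp["B"] > amp["A"] && amp["A"] > amp["C"])
  # branching offset between the post-infection cohorts and controls
  expect_equal(specs$C$branching_parameter - specs$A$branching_parameter, 0.15)
  expect_error(cohort_spec("D"), "arg")
})

test_that("cohort dataset generation is balanced, seeded and subject-distinct", {
  specs <- default_cohort_specs(n_subjects = 2)
  ds <- build_cohort_dataset(specs, seed = 50, n_channels = 12,
                             resting_duration_s = 15, n_cascades = 25,
                             trials_per_paradigm = 4, max_duration = 10)
  expect_identical(nrow(ds$subjects), 6L)
  expect_equal(as.integer(table(ds$subjects$cohort)), c(2L, 2L, 2L))
  expect_setequal(names(ds$resting), ds$subjects$subject_id)
  expect_setequal(names(ds$epochs), ds$subjects$subject_id)
  expect_setequal(names(ds$epochs[["A01"]]),
                  c("face_recognition", "digit_span", "task_switching"))
  # distinct subjects get distinct signals; same build is reproducible
  expect_false(identical(ds$resting[["A01"]]$recording$data,
                         ds$resting[["A02"]]$recording$data))
  ds2 <- build_cohort_dataset(specs, seed = 50, n_channels = 12,
                              resting_duration_s = 15, n_cascades = 25,
                              trials_per_paradigm = 4, max_duration = 10)
  expect_identical(ds$resting[["B01"]]$recording$data,
                   ds2$resting[["B01"]]$recording$data)
  expect_error(build_cohort_dataset(list(), seed = 1), "empty cohort")
})

test_that("feature-level cohort simulation yields one row per subject", {
  specs <- default_cohort_specs(n_subjects = 3)
  feats <- simulate_cohort_features(specs, n_cascades = 300, seed = 60)
  expect_identical(nrow(feats), 9L)
  expect_true(all(c("subject_id", "cohort", "alpha", "sigma") %in% names(feats)))
  expect_true(all(feats$sigma >= 0))
  expect_true(all(feats$alpha < 0))
})
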
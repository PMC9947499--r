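# Programmatic fixtures shared across test files.

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# a recording holding one or more pure tones (channels x samples)
tone_recording <- function(freqs, fs = 250, duration_s = 8, amplitude = 1) {
  tt <- (seq_len(fs * duration_s) - 1) / fs
  data <- t(vapply(freqs, function(f) amplitude * sin(2 * pi * f * tt),
                   numeric(length(tt))))
  eeg_recording(data, fs = fs)
}

scalp_montage_137 <- function() {
  m <- synthetic_geodesic_montage()
  m[m$radius <= 0.5, , drop = FALSE]
}

# small rendered resting-state fixture reused by the avalanche-level tests
small_render <- function(n_channels = 64, sigma = 1, n_cascades = 150,
                         duration_s = 80, seed = 101) {
  cs <- simulate_branching_cascades(n_channels, sigma, n_cascades,
                                    seed = seed, max_duration = 20)
  render_resting_recording(cs, fs = 250, duration_s = duration_s,
                           seed = seed + 1)
}

# epochs whose trials equal a known template plus white noise
template_epochs <- function(n_trials, noise_sd = 0, scale = 1, shift_ms = 0,
                            seed = 1, subject_id = "S1", cohort = "A") {
  tpl <- default_erp_template("digit_span", electrodes = c("E98", "E99"),
                              fs = 250)
  synthesize_erp_trials(tpl, n_trials, amplitude_scale = scale,
                        latency_shift_ms = shift_ms, noise_sd_uv = noise_sd,
                        subject_id = subject_id, seed = seed) |>
    (\(e) { e$cohort <- cohort; e })()
}
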
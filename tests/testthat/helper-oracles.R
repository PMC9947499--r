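# Independent oracles used to cross-check the package's estimators.

# Brute-force grid search for the discrete power-law exponent: evaluates the
# zeta-normalised log-likelihood on a fixed grid, no numerical optimizer.
grid_search_exponent <- function(sizes, x_min = 1, grid = seq(1, 4, by = 1e-3)) {
  sizes <- sizes[sizes >= x_min]
  sl <- sum(log(sizes))
  n <- length(sizes)
  ll <- vapply(grid, function(a) {
    z <- if (x_min == 1) pracma::zeta(a) else
      pracma::zeta(a) - sum(seq_len(x_min - 1)^(-a))
    -n * log(z) - a * sl
  }, numeric(1))
  -grid[which.max(ll)]
}

# amplitude of a sinusoid estimated from the interior of a filtered signal
# (edges excluded to keep filter transients out of the measurement)
tone_amplitude <- function(x, trim = 0.1) {
  n <- length(x)
  core <- x[ceiling(n * trim):floor(n * (1 - trim))]
  sd(core) * sqrt(2)
}

# band power from the periodogram, for spectral filter contracts
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= lo & f <= hi & f <= fs / 2
  sum(p[sel])
}
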
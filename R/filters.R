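# Butterworth low/high-pass design in second-order sections (biquads) with
# zero-phase (forward-backward) application. Transfer-function-form filtfilt
# is numerically unusable for near-DC cutoffs (a 0.1 Hz high-pass at 250 Hz
# puts all poles within 1e-3 of z = 1 and the expanded polynomial
# coefficients lose the passband); factoring into biquads is the standard
# remedy and keeps the response accurate at W down to ~1e-5.

butter_sos <- function(order, W, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1, W > 0, W < 1)
  w <- tan(pi * W / 2)  # bilinear prewarp (fs = 2 convention)
  k <- seq_len(order)
  p0 <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit Butterworth poles
  p <- if (type == "low") w * p0 else w / p0  # s -> s/w or s -> w/s
  zp <- (1 + p) / (1 - p)  # bilinear transform of each pole
  # pair conjugate poles into biquads (odd order: one real pole section)
  used <- rep(FALSE, order)
  sos <- list()
  for (i in seq_len(order)) {
    if (used[i]) next
    if (abs(Im(zp[i])) < 1e-12) {
      used[i] <- TRUE
      a <- c(1, -Re(zp[i]), 0)
      b <- if (type == "low") c(1, 1, 0) else c(1, -1, 0)
    } else {
      j <- which(!used & abs(zp - Conj(zp[i])) < 1e-9)[1]
      used[c(i, j)] <- TRUE
      a <- c(1, -2 * Re(zp[i]), Mod(zp[i])^2)
      b <- if (type == "low") c(1, 2, 1) else c(1, -2, 1)
    }
    # unit gain at DC (low-pass) or Nyquist (high-pass)
    zref <- if (type == "low") 1 else -1
    g <- sum(a * c(1, zref, zref^2)) / sum(b * c(1, zref, zref^2))
    sos[[length(sos) + 1L]] <- list(b = b * g, a = a)
  }
  sos
}

# One biquad with steady-state initial conditions for the constant part of
# the input: the response to the signal mean and start value is taken
# analytically (H(1) * const) and only the zero-start, zero-mean residual
# passes through the zero-state recursion. Without this, a near-DC high-pass
# section starts with an uncharged DC-rejection state and rings for
# thousands of samples.
biquad_apply <- function(x, b, a) {
  n <- length(x)
  const <- mean(x)
  r <- x - const
  h1 <- sum(b) / sum(a)
  v <- b[1] * r + b[2] * c(0, r[-n]) + b[3] * c(0, 0, r[seq_len(max(0, n - 2))])
  as.numeric(stats::filter(v, -a[2:3], method = "recursive")) + h1 * const
}

sos_apply <- function(x, sos) {
  for (s in sos) x <- biquad_apply(x, s$b, s$a)
  x
}

# zero-phase application with reflection padding against edge transients;
# padding is widened to three times the slowest section's time constant so
# start-up ringing of near-DC sections decays inside the pad
sos_filtfilt <- function(x, sos, pad) {
  n <- length(x)
  rmax <- max(vapply(sos, function(s)
    max(Mod(polyroot(rev(s$a[s$a != 0 | seq_along(s$a) == 1])))), numeric(1)))
  tau <- if (rmax < 1) ceiling(-10 / log(rmax)) else n
  pad <- max(1L, min(as.integer(max(pad, tau)), n - 1L))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- sos_apply(xp, sos)
  y <- rev(sos_apply(rev(y), sos))
  y[(pad + 1):(pad + n)]
}
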
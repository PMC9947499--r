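#' Simulate branching-process cascades
#'
#' Generates neuronal-avalanche-like cascades from a Galton-Watson branching
#' process with Poisson offspring: one seed event starts each cascade on a
#' uniformly random channel, and every event in bin t spawns
#' `Poisson(sigma)` events in bin t+1, each placed on a uniformly random
#' channel. A cascade ends when a bin is empty or when `max_duration` bins
#' are reached (capped cascades are flagged: supercritical runs would
#' otherwise not terminate). The offspring mean equals the branching
#' parameter sigma, and at sigma = 1 the cascade-size distribution follows
#' the critical-branching power law with density exponent -3/2.
#'
#' Per-bin event totals are always stored; channel-by-bin rasters are built
#' only when `make_rasters = TRUE`, because supercritical parameter-recovery
#' runs generate event counts that are cheap to store as totals but
#' infeasible to place channel-by-channel.
#'
#' @param n_channels number of channels events are placed on (>= 1).
#' @param sigma offspring mean (branching parameter), >= 0.
#' @param n_avalanches number of cascades to simulate.
#' @param seed integer seed or `NULL`.
#' @param max_duration duration cap in bins (default 100).
#' @param make_rasters build channel x bin count matrices per cascade.
#' @param max_raster_events guard: error if rasters would hold more than this
#'   many events in total.
#' @return an object of class `cascade_set`: list with `bin_totals` (list of
#'   per-bin event totals per cascade), `sizes`, `durations`, `capped`
#'   (logical), `rasters` (list of matrices or `NULL`), `sigma_true`,
#'   `n_channels`, `seed`.
#' @export
simulate_branching_cascades <- function(n_channels, sigma, n_avalanches, seed = NULL,
                                        max_duration = 100, make_rasters = TRUE,
                                        max_raster_events = 2e7) {
  if (!is.numeric(n_channels) || n_channels < 1)
    stop("`n_channels` must be >= 1", call. = FALSE)
  stop_if_not_scalar_number(sigma, "sigma", min = 0)
  stop_if_not_scalar_number(n_avalanches, "n_avalanches", min = 1)
  stop_if_not_scalar_number(max_duration, "max_duration", min = 1)
  n_channels <- as.integer(n_channels)
  n <- as.integer(n_avalanches)

  with_seed(seed, {
    # vectorized over cascades: only per-bin totals evolve
    ids <- vector("list", max_duration)
    cnts <- vector("list", max_duration)
    alive_id <- seq_len(n)
    cur <- rep(1, n)
    t <- 1L
    repeat {
      ids[[t]] <- alive_id
      cnts[[t]] <- cur
      if (t == max_duration || length(alive_id) == 0L) break
      nxt <- stats::rpois(length(cur), sigma * cur)
      keep <- nxt > 0
      alive_id <- alive_id[keep]
      cur <- nxt[keep]
      if (length(alive_id) == 0L) break
      t <- t + 1L
    }
    capped <- rep(FALSE, n)
    if (t == max_duration && length(alive_id) > 0L) {
      nxt <- stats::rpois(length(cur), sigma * cur)
      capped[alive_id[nxt > 0]] <- TRUE
    }
    all_ids <- unlist(ids[seq_len(t)], use.names = FALSE)
    all_cnt <- unlist(cnts[seq_len(t)], use.names = FALSE)
    ord <- order(all_ids)
    bin_totals <- split(all_cnt[ord], all_ids[ord])
    names(bin_totals) <- NULL

    sizes <- vapply(bin_totals, sum, numeric(1))
    durations <- lengths(bin_totals)

    rasters <- NULL
    if (make_rasters) {
      if (sum(sizes) > max_raster_events)
        stop("rasters would hold ", format(sum(sizes), big.mark = ","),
             " events; rerun with make_rasters = FALSE or fewer/shorter cascades",
             call. = FALSE)
      rasters <- lapply(bin_totals, function(tot) {
        m <- matrix(0L, nrow = n_channels, ncol = length(tot))
        for (b in seq_along(tot)) {
          m[, b] <- stats::rmultinom(1, tot[b], rep(1, n_channels))
        }
        m
      })
    }
    structure(list(bin_totals = bin_totals, sizes = sizes, durations = durations,
                   capped = capped, rasters = rasters, sigma_true = sigma,
                   n_channels = n_channels, seed = seed),
              class = "cascade_set")
  })
}

#' @export
print.cascade_set <- function(x, ...) {
  cat(sprintf("<cascade_set> %d cascades on %d channels (sigma_true = %g)\n",
              length(x$bin_totals), x$n_channels, x$sigma_true))
  cat(sprintf("  mean size %.2f, mean duration %.2f, %d capped, rasters: %s\n",
              mean(x$sizes), mean(x$durations), sum(x$capped),
              if (is.null(x$rasters)) "no" else "yes"))
  invisible(x)
}

#' Sample from a discrete power law
#'
#' Draws sizes from the zeta (discrete power-law) distribution
#' P(s) proportional to s^exponent for s >= x_min, by Devroye's rejection
#' method for the Zipf distribution. Used for exponent-recovery experiments
#' against the maximum-likelihood fitter.
#'
#' @param n number of draws.
#' @param exponent power-law exponent with the negative sign convention
#'   (e.g. -1.5336); must be < -1.
#' @param x_min minimum size (support is `x_min, x_min+1, ...`).
#' @param seed integer seed or `NULL`.
#' @return integer-valued numeric vector of length `n`.
#' @export
rpowerlaw_discrete <- function(n, exponent, x_min = 1, seed = NULL) {
  a <- -exponent
  if (!is.numeric(a) || a <= 1)
    stop("`exponent` must be < -1 for a normalizable discrete power law", call. = FALSE)
  stop_if_not_scalar_number(x_min, "x_min", min = 1)
  with_seed(seed, {
    out <- numeric(0)
    b <- 2^(a - 1)
    while (length(out) < n) {
      m <- max(2L * (n - length(out)), 1000L)
      u <- stats::runif(m); v <- stats::runif(m)
      x <- floor(u^(-1 / (a - 1)))
      tq <- (1 + 1 / x)^(a - 1)
      acc <- v * x * (tq - 1) / (b - 1) <= tq / b
      draws <- x[acc]
      if (x_min > 1) draws <- draws[draws >= x_min]  # condition on the tail
      out <- c(out, draws)
    }
    out[seq_len(n)]
  })
}
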
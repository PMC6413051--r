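# Shared fixture builders. Everything is generated in code at test time.

# A boot_signal whose gyro channels are arbitrary functions of time and
# whose acc channels are zero (plus az = 1 g so the record is physical).
make_boot <- function(t, gx = 0, gy = 0, gz = 0, side = "left", rate = NULL) {
  n <- length(t)
  expand <- function(v) if (length(v) == 1L) rep(v, n) else v
  boot_signal(t, expand(gx), expand(gy), expand(gz),
              rep(0, n), rep(0, n), rep(1, n), side = side, rate = rate)
}

# A simulated session resampled onto the shared 50 Hz analysis grid.
session_50 <- function(...) {
  ses <- simulate_session(synth_config(...))
  g <- common_grid(ses$left, ses$right, 50)
  list(left = g$left, right = g$right, truth = ses$truth)
}

# Peak roll rate (deg/s) of the default simulator settings, for scaling
# noise levels as a fraction of signal amplitude.
peak_roll_rate <- function(turn_duration = 1.45, roll_amplitude = 30) {
  roll_amplitude * pi / turn_duration
}

# Brute-force one-to-one event matching oracle: over all injective
# assignments of detected events to reference events within max_lag,
# maximise the number of pairs, then minimise the total absolute lag.
# Exponential; only for tiny inputs.
match_oracle <- function(detected, reference, max_lag) {
  nd <- length(detected); nr <- length(reference)
  best <- list(npairs = -1, cost = Inf, pairs = NULL)
  recurse <- function(i, used_r, pairs, cost) {
    if (i > nd) {
      np <- nrow(pairs)
      if (np > best$npairs ||
          (np == best$npairs && cost < best$cost)) {
        best <<- list(npairs = np, cost = cost, pairs = pairs)
      }
      return(invisible())
    }
    recurse(i + 1L, used_r, pairs, cost)  # leave detected i unmatched
    for (j in seq_len(nr)) {
      lag <- abs(detected[i] - reference[j])
      if (!used_r[j] && lag <= max_lag) {
        used_r[j] <- TRUE
        recurse(i + 1L, used_r,
                rbind(pairs, data.frame(d = i, r = j)), cost + lag)
        used_r[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nr), data.frame(d = integer(), r = integer()), 0)
  best
}

# Brute-force in-window extremum scan: argmax (or argmin) over the samples
# strictly inside the window, used as the oracle the detector must agree
# with.
window_scan_oracle <- function(x, lo, hi, want = "max") {
  inside <- seq(lo + 1L, hi - 1L)
  if (want == "max") inside[which.max(x[inside])] else inside[which.min(x[inside])]
}
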
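#' Construct a boot IMU signal
#'
#' A `boot_signal` is one boot's uniformly sampled (or raw, pre-resampling)
#' 6-axis IMU record: three angular-velocity channels in degrees/s and three
#' acceleration channels in g, on a common time base in seconds.
#'
#' Axis convention (fixed at ingestion, no autodetection): `x` is the boot
#' vertical axis pointing superiorly, `y` the lateral axis pointing left, and
#' `z` the roll (anterior-posterior) axis pointing posteriorly. Rotation about
#' `z` is edging/lean, which is why `gz` carries the turn signal.
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing.
#' @param gx,gy,gz angular velocity about x/y/z in degrees/s.
#' @param ax,ay,az acceleration along x/y/z in g.
#' @param side `"left"` or `"right"`.
#' @param rate nominal sampling rate in Hz. If `NULL`, estimated as the
#'   reciprocal median time step.
#' @return An object of class `boot_signal`: a data frame with columns
#'   `t, gx, gy, gz, ax, ay, az` and attributes `side` and `rate`.
#' @examples
#' t <- seq(0, 1, by = 1 / 64)
#' s <- boot_signal(t, sin(t), cos(t), 2 * t, 0 * t, 0 * t, 1 + 0 * t,
#'                  side = "left")
#' signal_rate(s)
#' @export
boot_signal <- function(t, gx, gy, gz, ax, ay, az, side = c("left", "right"),
                        rate = NULL) {
  side <- match.arg(side)
  t <- as.numeric(t)
  n <- length(t)
  chans <- list(gx = gx, gy = gy, gz = gz, ax = ax, ay = ay, az = az)
  for (nm in names(chans)) {
    if (length(chans[[nm]]) != n) {
      stop("channel '", nm, "' has length ", length(chans[[nm]]),
           ", expected ", n, " (length of t)", call. = FALSE)
    }
  }
  if (n >= 2 && any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (is.null(rate)) {
    if (n < 2) stop("cannot infer rate from fewer than 2 samples", call. = FALSE)
    rate <- 1 / median(diff(t))
  }
  out <- data.frame(t = t, gx = as.numeric(gx), gy = as.numeric(gy),
                    gz = as.numeric(gz), ax = as.numeric(ax),
                    ay = as.numeric(ay), az = as.numeric(az))
  attr(out, "side") <- side
  attr(out, "rate") <- rate
  class(out) <- c("boot_signal", "data.frame")
  out
}

#' @rdname boot_signal
#' @param x a `boot_signal`.
#' @export
signal_rate <- function(x) attr(x, "rate")

#' @rdname boot_signal
#' @export
signal_side <- function(x) attr(x, "side")

#' @export
print.boot_signal <- function(x, ...) {
  cat(sprintf("<boot_signal> side=%s  n=%d  rate=%.6g Hz  span=[%.3f, %.3f] s\n",
              signal_side(x), nrow(x), signal_rate(x), x$t[1], x$t[nrow(x)]))
  invisible(x)
}

#' Check that a boot signal sits on a uniform grid
#'
#' @param x a `boot_signal`.
#' @param tol maximum allowed deviation of successive time deltas from
#'   `1/rate`, in seconds.
#' @return `TRUE`/`FALSE`.
#' @export
is_uniform <- function(x, tol = 1e-9) {
  dt <- diff(x$t)
  length(dt) == 0L || max(abs(dt - 1 / signal_rate(x))) < tol
}

#' Resample a boot signal with a shape-preserving spline
#'
#' Interpolates every channel onto a uniform grid running from the first to
#' the last original timestamp at `target_rate`, using monotone piecewise
#' cubic (shape-preserving) interpolation. By construction the interpolant
#' never overshoots the local data extrema between knots, so resampling
#' cannot manufacture spurious peaks.
#'
#' @param signal a [boot_signal()].
#' @param target_rate output rate in Hz (must be > 0).
#' @return A `boot_signal` on a uniform grid at `target_rate`.
#' @examples
#' t <- seq(0, 2, by = 1 / 64)
#' s <- boot_signal(t, sin(2 * pi * t), 0 * t, cos(2 * pi * t),
#'                  0 * t, 0 * t, 1 + 0 * t, side = "left")
#' r <- resample_boot(s, 50)
#' signal_rate(r)
#' @export
resample_boot <- function(signal, target_rate) {
  stopifnot(inherits(signal, "boot_signal"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0) {
    stop("target_rate must be a single positive number", call. = FALSE)
  }
  if (nrow(signal) < 4L) {
    stop("resampling needs at least 4 samples", call. = FALSE)
  }
  t0 <- signal$t[1]
  t1 <- signal$t[nrow(signal)]
  tt <- t0 + seq(0, floor((t1 - t0) * target_rate)) / target_rate
  ch <- lapply(c("gx", "gy", "gz", "ax", "ay", "az"), function(nm) {
    pracma::pchip(signal$t, signal[[nm]], tt)
  })
  boot_signal(tt, ch[[1]], ch[[2]], ch[[3]], ch[[4]], ch[[5]], ch[[6]],
              side = signal_side(signal), rate = target_rate)
}

#' Per-sample resultant (Euclidean norm) of one sensor's three axes
#'
#' @param signal a [boot_signal()].
#' @param sensor `"gyro"` or `"acc"`.
#' @return Numeric vector, `sqrt(x^2 + y^2 + z^2)` per sample; non-negative.
#' @examples
#' t <- 0:9 / 10
#' s <- boot_signal(t, rep(3, 10), rep(4, 10), rep(0, 10),
#'                  rep(0, 10), rep(0, 10), rep(1, 10), side = "left")
#' resultant(s, "gyro")[1]  # 5
#' @export
resultant <- function(signal, sensor = c("gyro", "acc")) {
  stopifnot(inherits(signal, "boot_signal"))
  sensor <- match.arg(sensor)
  if (sensor == "gyro") {
    sqrt(signal$gx^2 + signal$gy^2 + signal$gz^2)
  } else {
    sqrt(signal$ax^2 + signal$ay^2 + signal$az^2)
  }
}

#' Per-sample mean of a left and a right boot channel
#'
#' Both series must already share a time base (resample first); this is a
#' plain arithmetic mean, used by the averaged-boot signal variants.
#'
#' @param left_channel,right_channel numeric vectors of equal length.
#' @return Numeric vector of the same length.
#' @export
average_boots <- function(left_channel, right_channel) {
  if (length(left_channel) != length(right_channel)) {
    stop("left and right channels differ in length (",
         length(left_channel), " vs ", length(right_channel),
         "); resample to a shared grid first", call. = FALSE)
  }
  (left_channel + right_channel) / 2
}

#' Put two boot records onto one shared uniform grid
#'
#' Crops a left and a right boot record to their common time span and
#' interpolates every channel of both onto one uniform grid (anchored at
#' the later of the two start times) with shape-preserving splines. The
#' averaged-boot signal variants require exactly this: a sample-by-sample
#' correspondence between boots.
#'
#' @param left,right [boot_signal()]s with overlapping time spans.
#' @param rate target rate in Hz.
#' @return `list(left = , right = )` of `boot_signal`s with identical `t`.
#' @export
common_grid <- function(left, right, rate) {
  t0 <- max(left$t[1], right$t[1])
  t1 <- min(left$t[nrow(left)], right$t[nrow(right)])
  if (t1 <= t0) stop("boot records do not overlap in time", call. = FALSE)
  tt <- t0 + seq(0, floor((t1 - t0) * rate)) / rate
  onto <- function(s) {
    ch <- lapply(c("gx", "gy", "gz", "ax", "ay", "az"), function(nm) {
      pracma::pchip(s$t, s[[nm]], tt)
    })
    boot_signal(tt, ch[[1]], ch[[2]], ch[[3]], ch[[4]], ch[[5]], ch[[6]],
                side = signal_side(s), rate = rate)
  }
  list(left = onto(left), right = onto(right))
}
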
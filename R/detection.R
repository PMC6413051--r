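#' Detection configuration
#'
#' Bundles the tunable parameters of the turn-switch detectors and the
#' generic variant-screening search.
#'
#' @param variant a [variant_spec()]; defaults to the recommended averaged
#'   gyroscope z-axis at 3 Hz.
#' @param strong_cutoff_hz cutoff of the strong low-pass used only to delimit
#'   one search window per half-cycle: 0.5 Hz for signed-axis signals, 1 Hz
#'   for resultants. `NULL` picks the default for the variant's axis.
#' @param cutoff_hz analysis cutoff in Hz, or `NA`/`0` for no filtering
#'   (overrides `variant$cutoff_hz` if given).
#' @param min_peak_prominence minimum prominence (signal units) a candidate
#'   in-window extremum must have; 0 disables the gate. The screening
#'   pipeline uses 5% of the channel interquartile range for noisy data.
#' @param min_peak_separation minimum time between retained events in
#'   seconds; when two events fall closer, the less prominent one is dropped.
#'   Default 0.4 s, below the shortest half-turn of the 0.90 s preset.
#' @param filter_design passed to [lowpass_zero_lag()].
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(variant = variant_spec(),
                             strong_cutoff_hz = NULL,
                             cutoff_hz = NULL,
                             min_peak_prominence = 0,
                             min_peak_separation = 0.4,
                             filter_design = "order2_filtfilt") {
  if (!is.null(cutoff_hz)) variant$cutoff_hz <- cutoff_hz
  if (is.null(strong_cutoff_hz)) {
    strong_cutoff_hz <- if (identical(variant$axis, "resultant")) 1 else 0.5
  }
  co <- variant$cutoff_hz
  if (!is.na(co) && co > 0 && strong_cutoff_hz >= co) {
    stop("strong_cutoff_hz must be below the analysis cutoff", call. = FALSE)
  }
  if (min_peak_separation < 0) {
    stop("min_peak_separation must be >= 0", call. = FALSE)
  }
  structure(list(variant = variant,
                 strong_cutoff_hz = strong_cutoff_hz,
                 cutoff_hz = variant$cutoff_hz,
                 min_peak_prominence = min_peak_prominence,
                 min_peak_separation = min_peak_separation,
                 filter_design = filter_design),
            class = "detection_config")
}

#' Signal-variant specification
#'
#' Addresses one member of the screening grid: sensor (gyroscope or
#' accelerometer) x axis (x, y, z or resultant) x source (left boot, right
#' boot or the two-boot average) x analysis cutoff (3, 6, 9, 12 Hz or none).
#' The full cross-product has 120 members.
#'
#' @param sensor `"gyro"` or `"acc"`.
#' @param axis `"x"`, `"y"`, `"z"` or `"resultant"`.
#' @param source `"left"`, `"right"` or `"average"`.
#' @param cutoff_hz 3, 6, 9, 12, or `NA` (equivalently `0`) for no filter.
#' @return A list of class `variant_spec`.
#' @examples
#' variant_spec("gyro", "z", "average", 3)
#' parse_variant("gyro:z:average:3")
#' @export
variant_spec <- function(sensor = c("gyro", "acc"),
                         axis = c("z", "x", "y", "resultant"),
                         source = c("average", "left", "right"),
                         cutoff_hz = 3) {
  sensor <- match.arg(sensor)
  axis <- match.arg(axis)
  source <- match.arg(source)
  if (length(cutoff_hz) != 1L) stop("cutoff_hz must be scalar", call. = FALSE)
  if (!is.na(cutoff_hz) && cutoff_hz == 0) cutoff_hz <- NA_real_
  if (!is.na(cutoff_hz) && !cutoff_hz %in% c(3, 6, 9, 12)) {
    stop("cutoff_hz must be one of 3, 6, 9, 12 or none (NA/0)", call. = FALSE)
  }
  structure(list(sensor = sensor, axis = axis, source = source,
                 cutoff_hz = as.numeric(cutoff_hz)),
            class = "variant_spec")
}

#' @rdname variant_spec
#' @param x a variant string `"sensor:axis:source:cutoff"` with `0` meaning
#'   no filter, e.g. `"gyro:z:average:3"`.
#' @export
parse_variant <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 4L) {
    stop("variant string must be 'sensor:axis:source:cutoff', got '", x, "'",
         call. = FALSE)
  }
  variant_spec(parts[1], parts[2], parts[3], suppressWarnings(as.numeric(parts[4])))
}

#' @rdname variant_spec
#' @param v a `variant_spec`.
#' @export
format_variant <- function(v) {
  co <- if (is.na(v$cutoff_hz)) 0 else v$cutoff_hz
  paste(v$sensor, v$axis, v$source, co, sep = ":")
}

#' @rdname variant_spec
#' @return `variant_grid()`: a data frame enumerating all 120 variants.
#' @export
variant_grid <- function() {
  g <- expand.grid(sensor = c("gyro", "acc"),
                   axis = c("x", "y", "z", "resultant"),
                   source = c("left", "right", "average"),
                   cutoff_hz = c(NA, 3, 6, 9, 12),
                   stringsAsFactors = FALSE)
  g[order(g$sensor, g$axis, g$source, g$cutoff_hz, na.last = FALSE), ,
    drop = FALSE]
}

#' Ordered turn-switch events
#'
#' @param times event times in seconds, strictly increasing.
#' @param direction per-event labels: `"left_to_right"`, `"right_to_left"`
#'   or `"unsigned"`.
#' @return A list of class `switch_series` with fields `times`, `direction`.
#' @export
switch_series <- function(times = numeric(), direction = character()) {
  if (length(direction) == 0L && length(times) > 0L) {
    direction <- rep("unsigned", length(times))
  }
  stopifnot(length(times) == length(direction))
  if (length(times) >= 2 && any(diff(times) <= 0)) {
    stop("switch times must be strictly increasing", call. = FALSE)
  }
  if (!all(direction %in% c("left_to_right", "right_to_left", "unsigned"))) {
    stop("invalid direction label", call. = FALSE)
  }
  structure(list(times = as.numeric(times), direction = direction),
            class = "switch_series")
}

#' @export
print.switch_series <- function(x, ...) {
  cat(sprintf("<switch_series> %d events", length(x$times)))
  if (length(x$times)) {
    cat(sprintf("  span=[%.3f, %.3f] s", min(x$times), max(x$times)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.switch_series <- function(x) length(x$times)

#' @export
as.data.frame.switch_series <- function(x, ...) {
  data.frame(time_s = x$times, direction = x$direction)
}

# ---- local extrema ---------------------------------------------------------

# Interior local extrema of a series, plateau-aware: a tied run counts once,
# at its earliest sample. Returns data.frame(idx, type) with type in
# {"max","min"}, ordered by idx. Endpoints are never extrema.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(data.frame(idx = integer(), type = character()))
  d <- diff(x)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(data.frame(idx = integer(), type = character()))
  idx <- integer(); type <- character()
  for (k in seq_len(length(nz) - 1L)) {
    s1 <- s[nz[k]]; s2 <- s[nz[k + 1L]]
    if (s1 > 0 && s2 < 0) { idx <- c(idx, nz[k] + 1L); type <- c(type, "max") }
    if (s1 < 0 && s2 > 0) { idx <- c(idx, nz[k] + 1L); type <- c(type, "min") }
  }
  data.frame(idx = idx, type = type, stringsAsFactors = FALSE)
}

# Prominence of the local maximum at index i of x restricted to the window
# lo..hi: height above the higher of the two deepest valleys on either side.
window_prominence <- function(x, i, lo, hi) {
  left_min <- min(x[lo:i])
  right_min <- min(x[i:hi])
  x[i] - max(left_min, right_min)
}

# Drop anchor extrema whose prominence (against the segments running to the
# neighbouring anchors, or to the series ends) is below `frac` of the
# series' peak-to-peak range. Zero-phase filtering still leaves small
# ripples within ~one strong-filter period of the record ends; without this
# guard such a ripple can masquerade as a window anchor and open a spurious
# search window against the lead-in/lead-out motion.
prune_anchors <- function(f, ex, frac = 0.05) {
  if (!nrow(ex)) return(ex)
  rng <- diff(range(f))
  # numerically constant series: round-off wiggles are not anchors
  if (rng <= 1e-9 * max(abs(f), 1)) return(ex[0, , drop = FALSE])
  n <- length(f)
  keep <- logical(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    l <- if (i == 1L) 1L else ex$idx[i - 1L]
    r <- if (i == nrow(ex)) n else ex$idx[i + 1L]
    v <- f[ex$idx[i]]
    prom <- if (ex$type[i] == "max") {
      v - max(min(f[l:ex$idx[i]]), min(f[ex$idx[i]:r]))
    } else {
      min(max(f[l:ex$idx[i]]), max(f[ex$idx[i]:r])) - v
    }
    keep[i] <- prom >= frac * rng
  }
  ex[keep, , drop = FALSE]
}

#' Strong low-pass windowing: anchor extrema and search windows
#'
#' Runs the strong low-pass filter (0.5 Hz for signed axes, 1 Hz for
#' resultants) over a channel and returns the anchors -- its interior local
#' extrema (`mode = "extrema"`) or local minima only (`mode = "minima"`) --
#' in time order. Consecutive anchor pairs delimit the windows in which the
#' actual turn-switch search is performed; a channel with no interior
#' extremum yields an empty window set (not an error).
#'
#' @param channel numeric vector on a uniform grid.
#' @param rate sampling rate in Hz.
#' @param strong_cutoff strong low-pass cutoff in Hz.
#' @param mode `"extrema"` or `"minima"`.
#' @param t optional timestamps (defaults to `(0:(n-1))/rate`).
#' @param filter_design passed to [lowpass_zero_lag()].
#' @return A list of class `window_set`: `anchors` (data frame `idx`,
#'   `time`, `type`), `filtered` (the strongly filtered channel), `t`,
#'   `rate`.
#' @export
find_windows <- function(channel, rate, strong_cutoff,
                         mode = c("extrema", "minima"), t = NULL,
                         filter_design = "order2_filtfilt") {
  mode <- match.arg(mode)
  if (is.null(t)) t <- (seq_along(channel) - 1) / rate
  f <- lowpass_zero_lag(channel, rate, strong_cutoff,
                        filter_design = filter_design)
  ex <- prune_anchors(f, local_extrema(f))
  if (mode == "minima") ex <- ex[ex$type == "min", , drop = FALSE]
  anchors <- data.frame(idx = ex$idx, time = t[ex$idx], type = ex$type,
                        stringsAsFactors = FALSE)
  structure(list(anchors = anchors, filtered = f, t = t, rate = rate),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d anchors (%s)\n", nrow(x$anchors),
              paste(unique(x$anchors$type), collapse = "/")))
  invisible(x)
}

# Search the single best extremum of `detail` strictly inside each window
# (pairs of consecutive rows of `anchors`), looking for local maxima when
# want = "max" (minima are found as maxima of the negated series).
# Returns data.frame(idx, time, value, prominence).
search_windows <- function(detail, t, anchors_idx, want, min_prominence) {
  sgn <- if (want == "max") 1 else -1
  x <- sgn * detail
  out_idx <- integer(); out_prom <- numeric()
  if (length(anchors_idx) < 2L) {
    return(data.frame(idx = integer(), time = numeric(), value = numeric(),
                      prominence = numeric()))
  }
  for (w in seq_len(length(anchors_idx) - 1L)) {
    lo <- anchors_idx[w]; hi <- anchors_idx[w + 1L]
    if (hi - lo < 2L) next
    seg <- x[lo:hi]
    ex <- local_extrema(seg)
    ex <- ex[ex$type == "max", , drop = FALSE]
    if (!nrow(ex)) next
    cand <- lo + ex$idx - 1L
    proms <- vapply(cand, function(i) window_prominence(x, i, lo, hi),
                    numeric(1))
    keep <- proms >= min_prominence
    if (!any(keep)) next
    cand <- cand[keep]; proms <- proms[keep]
    best <- which.max(proms)           # ties: which.max takes the earliest
    out_idx <- c(out_idx, cand[best])
    out_prom <- c(out_prom, proms[best])
  }
  data.frame(idx = out_idx, time = t[out_idx], value = detail[out_idx],
             prominence = out_prom)
}

# Drop events closer than min_sep seconds, discarding the less prominent of
# each offending pair, until all gaps are >= min_sep.
enforce_separation <- function(ev, min_sep) {
  if (min_sep <= 0 || nrow(ev) < 2L) return(ev)
  repeat {
    gaps <- diff(ev$time)
    j <- which(gaps < min_sep)
    if (!length(j)) return(ev)
    j <- j[1]
    drop <- if (ev$prominence[j] < ev$prominence[j + 1L]) j else j + 1L
    ev <- ev[-drop, , drop = FALSE]
  }
}

# Shared core: builds the variant channel from the boots and runs the
# windowed extremum search. Used by detect_z, detect_resultant and
# screen_variant so the dedicated algorithms and the screening pipeline are
# consistent by construction.
detect_core <- function(left, right, cfg, sensor, axis, source) {
  pick <- function(sig) {
    if (axis == "resultant") resultant(sig, sensor)
    else sig[[paste0(substr(sensor, 1, 1), axis)]]
  }
  if (source == "average") {
    if (is.null(left) || is.null(right)) {
      stop("source='average' requires both boots", call. = FALSE)
    }
    if (nrow(left) != nrow(right) ||
        max(abs(left$t - right$t)) > 1e-9) {
      stop("boots are not on a shared time grid; resample first",
           call. = FALSE)
    }
    # resultant per boot first, then average (order matters)
    channel <- average_boots(pick(left), pick(right))
    base <- left
  } else {
    base <- if (source == "left") left else right
    if (is.null(base)) stop("boot '", source, "' is missing", call. = FALSE)
    channel <- pick(base)
  }
  rate <- signal_rate(base)
  t <- base$t
  if (all(channel == channel[1])) {
    warning("constant channel: no turn switches detectable")
    return(switch_series())
  }
  nonneg <- axis == "resultant"
  mode <- if (nonneg) "minima" else "extrema"
  ws <- find_windows(channel, rate, cfg$strong_cutoff_hz, mode = mode, t = t,
                     filter_design = cfg$filter_design)
  co <- cfg$cutoff_hz
  detail <- if (is.na(co) || co == 0) channel else {
    lowpass_zero_lag(channel, rate, co, filter_design = cfg$filter_design)
  }
  an <- ws$anchors
  if (nrow(an) < 2L) {
    warning("fewer than two strong-filter anchors: empty switch series")
    return(switch_series())
  }
  if (nonneg) {
    ev <- search_windows(detail, t, an$idx, "max", cfg$min_peak_prominence)
    ev$direction <- rep("unsigned", nrow(ev))
  } else {
    min_idx <- an$idx[an$type == "min"]
    max_idx <- an$idx[an$type == "max"]
    ev_max <- search_windows(detail, t, min_idx, "max", cfg$min_peak_prominence)
    ev_min <- search_windows(detail, t, max_idx, "min", cfg$min_peak_prominence)
    ev_max$direction <- rep("left_to_right", nrow(ev_max))
    ev_min$direction <- rep("right_to_left", nrow(ev_min))
    ev <- rbind(ev_max, ev_min)
    ev <- ev[order(ev$time), , drop = FALSE]
  }
  ev <- enforce_separation(ev, cfg$min_peak_separation)
  switch_series(ev$time, ev$direction)
}

#' Turn-switch detection from the gyroscope z-axis
#'
#' The roll-rate algorithm: (1) if `source = "average"`, average the raw
#' gyroscope z channels of both boots; (2-3) filter the signal at 0.5 Hz
#' (zero-lag Butterworth) and label its interior local extrema; (4) filter
#' the raw signal at the analysis cutoff (3 Hz recommended; no filtering for
#' the raw variant); (5) search local maxima of the analysis signal between
#' consecutive strong-filter *minima*; (6) search local minima between
#' consecutive strong-filter *maxima*; (7) merge both event sets in
#' ascending time. Positive roll-rate peaks are labelled
#' `"left_to_right"`, negative `"right_to_left"`, so directions alternate.
#'
#' @param left,right [boot_signal()]s on a shared uniform grid (either may be
#'   `NULL` when `source` is a single boot).
#' @param cfg a [detection_config()]; its variant's `source` and `cutoff_hz`
#'   are honoured, the sensor/axis are forced to gyroscope z.
#' @return A [switch_series()].
#' @examples
#' ses <- simulate_session(synth_config(n_turns = 5, seed = 1))
#' g <- common_grid(ses$left, ses$right, 50)
#' detect_z(g$left, g$right, detection_config())
#' @export
detect_z <- function(left = NULL, right = NULL, cfg = detection_config()) {
  detect_core(left, right, cfg, "gyro", "z", cfg$variant$source)
}

#' Turn-switch detection from the gyroscope resultant
#'
#' The magnitude algorithm: (1) compute the per-sample resultant of the
#' three gyroscope axes for each boot; (2) if `source = "average"`, average
#' the two resultants (resultant first, then average -- the order matters);
#' (3-4) filter at 1 Hz and take the interior local *minima* as window
#' anchors; (5-6) search local maxima of the cutoff-filtered resultant
#' between consecutive anchors. Events are unsigned: the magnitude carries
#' no turn direction.
#'
#' @inheritParams detect_z
#' @return A [switch_series()] with `"unsigned"` directions.
#' @export
detect_resultant <- function(left = NULL, right = NULL,
                             cfg = detection_config(
                               variant_spec("gyro", "resultant", "average", 3))) {
  detect_core(left, right, cfg, "gyro", "resultant", cfg$variant$source)
}

#' Generic semi-automatic screening search for any signal variant
#'
#' Builds the channel addressed by `variant` (sensor, axis or resultant, one
#' boot or the two-boot average, analysis cutoff) and runs the windowed
#' extremum search used during variant screening: signed axes use
#' alternating strong-filter extrema as anchors (maxima sought between
#' minima and vice versa); resultants use strong-filter minima anchors with
#' maxima sought in between. For the gyroscope z and resultant variants this
#' is identical to [detect_z()] and [detect_resultant()] by construction.
#'
#' @param left,right [boot_signal()]s on a shared uniform grid.
#' @param variant a [variant_spec()].
#' @param cfg a [detection_config()]; `variant` overrides `cfg$variant`.
#' @return A [switch_series()].
#' @export
screen_variant <- function(left, right, variant, cfg = detection_config()) {
  cfg$variant <- variant
  cfg$cutoff_hz <- variant$cutoff_hz
  if (identical(variant$axis, "resultant") && cfg$strong_cutoff_hz < 1) {
    cfg$strong_cutoff_hz <- 1
  }
  detect_core(left, right, cfg, variant$sensor, variant$axis, variant$source)
}
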
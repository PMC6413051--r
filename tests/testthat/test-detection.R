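# Windowed turn-switch detection: anchors, the two algorithms, screening.

test_that("find_windows anchors the extrema of a slow sinusoid", {
  t <- seq(0, 30, by = 1 / 50)
  ch <- sin(2 * pi * t / 2.9)                 # 0.345 Hz, passes 0.5 Hz
  ws <- find_windows(ch, 50, 0.5, mode = "extrema", t = t)
  an <- ws$anchors
  expect_gt(nrow(an), 15)
  # analytic extrema at 0.725 + k * 1.45 s, alternating max/min
  expected <- 0.725 + (0:19) * 1.45
  for (i in seq_len(nrow(an))) {
    expect_lt(min(abs(an$time[i] - expected)), 1 / 50 + 1e-9)
  }
  expect_true(all(an$type[seq(1, nrow(an), by = 2)] == an$type[1]))
  expect_true(all(diff(an$idx) > 0))
  expect_false(any(an$type[-1] == an$type[-nrow(an)]))
})

test_that("find_windows returns an empty set on constant input and one minimum for a single period", {
  t <- seq(0, 10, by = 1 / 50)
  ws <- find_windows(rep(3.2, length(t)), 50, 0.5, t = t)
  expect_identical(nrow(ws$anchors), 0L)
  # one full period of a sinusoid has exactly one interior minimum
  t1 <- seq(0, 2.9, by = 1 / 50)
  ch <- sin(2 * pi * t1 / 2.9)
  ws1 <- find_windows(ch, 50, 0.5, mode = "minima", t = t1)
  expect_identical(nrow(ws1$anchors), 1L)
  # brute-force scan agrees on its location
  expect_equal(ws1$anchors$idx,
               window_scan_oracle(ws1$filtered, 1L, length(ch), "min"))
})

test_that("z-axis detector finds every switch of noiseless sessions within one frame", {
  for (T_ in c(1.45, 0.90)) {
    for (sl in c("flat", "forward_6.3deg", "left_5.7deg")) {
      s <- session_50(n_turns = 15, turn_duration = T_, slope = sl, seed = 5)
      ev <- detect_z(s$left, s$right, detection_config())
      expect_length(ev$times, 15)
      expect_lt(max(abs(ev$times - s$truth$switch_times)), 0.020)
      # alternating signed directions
      expect_true(all(ev$direction[-1] != ev$direction[-15]))
      expect_identical(ev$direction, s$truth$switch_directions)
    }
  }
})

test_that("resultant detector matches ground truth and degenerates to |z| for single-axis motion", {
  s <- session_50(n_turns = 15, seed = 6)
  ev <- detect_resultant(s$left, s$right)
  expect_length(ev$times, 15)
  expect_lt(max(abs(ev$times - s$truth$switch_times)), 0.020)
  expect_true(all(ev$direction == "unsigned"))
  # single-axis motion: resultant == |z|, detections coincide within a sample
  t <- seq(0, 24, by = 1 / 50)
  gz <- -65 * sin(pi * t / 1.45)
  lb <- make_boot(t, gz = gz, side = "left")
  rb <- make_boot(t, gz = gz, side = "right")
  er <- detect_resultant(lb, rb)
  # |z| peaks at every switch: compare against z-axis detections over the
  # span both algorithms cover (their boundary windows differ by design)
  ez <- detect_z(lb, rb, detection_config())
  lo <- max(min(er$times), min(ez$times)) - 1e-9
  hi <- min(max(er$times), max(ez$times)) + 1e-9
  common <- er$times[er$times >= lo & er$times <= hi]
  expect_gt(length(common), 8)
  matched <- vapply(common, function(x) min(abs(x - ez$times)), numeric(1))
  expect_true(all(matched <= 1 / 50 + 1e-9))
})

test_that("noisy sessions are detected with the documented precision", {
  sd5 <- 0.05 * peak_roll_rate()
  nrep <- 25
  n_ok <- 0; errs <- numeric()
  for (r in seq_len(nrep)) {
    s <- session_50(n_turns = 15, noise_sd_gyro = sd5, seed = 100 + r)
    ev <- suppressWarnings(detect_resultant(s$left, s$right))
    if (length(ev$times) == 15) {
      n_ok <- n_ok + 1
      errs <- c(errs, abs(ev$times - s$truth$switch_times))
    }
  }
  expect_gte(n_ok, ceiling(0.95 * nrep))
  expect_lt(mean(errs), 0.030)
})

test_that("detected switches lie strictly inside their search windows", {
  s <- session_50(n_turns = 12, noise_sd_gyro = 2, seed = 9)
  ch <- average_boots(s$left$gz, s$right$gz)
  ws <- find_windows(ch, 50, 0.5, mode = "extrema", t = s$left$t)
  ev <- suppressWarnings(detect_z(s$left, s$right, detection_config()))
  an <- ws$anchors
  # maxima are sought between consecutive minima anchors and vice versa
  for (i in seq_along(ev$times)) {
    fam <- an$time[an$type == (if (ev$direction[i] == "left_to_right") "min"
                               else "max")]
    k <- findInterval(ev$times[i], fam)
    expect_true(k >= 1 && k < length(fam))
    expect_gt(ev$times[i], fam[k]); expect_lt(ev$times[i], fam[k + 1])
  }
})

test_that("detection is invariant to amplitude scaling when prominence is off", {
  s <- session_50(n_turns = 10, noise_sd_gyro = 1, seed = 13)
  scale_boot <- function(b, k) {
    make_boot(b$t, gx = k * b$gx, gy = k * b$gy, gz = k * b$gz,
              side = signal_side(b), rate = signal_rate(b))
  }
  cfg <- detection_config(min_peak_prominence = 0)
  e1 <- suppressWarnings(detect_z(s$left, s$right, cfg))
  e2 <- suppressWarnings(detect_z(scale_boot(s$left, 12),
                                  scale_boot(s$right, 12), cfg))
  expect_identical(e1$times, e2$times)
})

test_that("in-window selection equals the brute-force scan oracle", {
  for (r in 1:8) {
    s <- session_50(n_turns = 10, noise_sd_gyro = 1.5, seed = 50 + r)
    ch <- average_boots(s$left$gz, s$right$gz)
    detail <- lowpass_zero_lag(ch, 50, 3)
    ws <- find_windows(ch, 50, 0.5, mode = "extrema", t = s$left$t)
    ev <- suppressWarnings(detect_z(s$left, s$right,
                                    detection_config(min_peak_prominence = 0)))
    an <- ws$anchors
    mins <- an$idx[an$type == "min"]; maxs <- an$idx[an$type == "max"]
    for (tm in ev$times) {
      i <- which.min(abs(s$left$t - tm))
      k <- findInterval(i, mins)
      if (k >= 1 && k < length(mins) && i > mins[k] && i < mins[k + 1] &&
          detail[i] > 0) {
        expect_identical(i, window_scan_oracle(detail, mins[k], mins[k + 1]))
      }
      k <- findInterval(i, maxs)
      if (k >= 1 && k < length(maxs) && i > maxs[k] && i < maxs[k + 1] &&
          detail[i] < 0) {
        expect_identical(i,
                         window_scan_oracle(detail, maxs[k], maxs[k + 1], "min"))
      }
    }
  }
})

test_that("flat extrema resolve to the earliest tied sample", {
  x <- c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -2, -1, 0)
  ex <- skiturn:::local_extrema(x)
  expect_identical(ex$idx[ex$type == "max"], 4L)
  expect_identical(ex$idx[ex$type == "min"], 11L)
})

test_that("degenerate inputs give empty series or explicit errors", {
  t <- seq(0, 20, by = 1 / 50)
  zb <- make_boot(t, side = "left"); zr <- make_boot(t, side = "right")
  expect_warning(ev <- detect_z(zb, zr, detection_config()), "constant|anchors")
  expect_length(ev$times, 0)
  expect_error(detect_z(zb, NULL, detection_config()), "both boots")
  s <- session_50(n_turns = 5, seed = 2)
  cfg1 <- detection_config(variant_spec("gyro", "z", "left", 3))
  expect_silent(ev1 <- detect_z(s$left, NULL, cfg1))
  expect_length(ev1$times, 5)
})

test_that("screen_variant reproduces the dedicated algorithms and covers other variants", {
  s <- session_50(n_turns = 8, seed = 21)
  vz <- variant_spec("gyro", "z", "average", 3)
  expect_identical(screen_variant(s$left, s$right, vz)$times,
                   detect_z(s$left, s$right, detection_config(vz))$times)
  vr <- variant_spec("gyro", "resultant", "left", 3)
  cfgr <- detection_config(vr)
  expect_identical(screen_variant(s$left, s$right, vr)$times,
                   detect_resultant(s$left, NULL, cfgr)$times)
  # an accelerometer variant yields one event per search window
  va <- variant_spec("acc", "y", "right", 6)
  ev <- suppressWarnings(screen_variant(s$left, s$right, va))
  ws <- find_windows(s$right$ay, 50, 0.5, mode = "extrema", t = s$right$t)
  an <- ws$anchors
  n_windows <- max(0, sum(an$type == "min") - 1) + max(0, sum(an$type == "max") - 1)
  expect_gt(length(ev$times), 0)
  expect_lte(length(ev$times), n_windows)
})

test_that("the resultant algorithm computes per-boot resultants before averaging", {
  # mirrored boots: averaging the raw axes first would cancel the signal
  t <- seq(0, 24, by = 1 / 50)
  gz <- -65 * sin(pi * t / 1.45)
  lb <- make_boot(t, gz = gz, side = "left")
  rb <- make_boot(t, gz = -gz, side = "right")
  expect_equal(average_boots(lb$gz, rb$gz), rep(0, length(t)))  # raw average dies
  ev <- detect_resultant(lb, rb)
  expect_gt(length(ev$times), 10)                               # resultant-first survives
})

test_that("variant grid enumerates 120 members and round-trips through strings", {
  g <- variant_grid()
  expect_identical(nrow(g), 120L)
  expect_identical(anyDuplicated(g), 0L)
  v <- parse_variant("acc:resultant:right:0")
  expect_identical(v$sensor, "acc")
  expect_true(is.na(v$cutoff_hz))
  expect_identical(format_variant(v), "acc:resultant:right:0")
  expect_error(parse_variant("gyro:z:average"), "variant string")
  expect_error(variant_spec("gyro", "z", "average", 4), "cutoff")
})
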
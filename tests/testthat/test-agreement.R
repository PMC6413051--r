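# Bland-Altman agreement, reference envelope, adjusted precision, selection.

test_that("match_events pairs events one-to-one by nearest neighbour", {
  r <- c(1, 2, 3, 4)
  pd <- match_events(r, r)
  expect_equal(pd$differences, rep(0, 4))
  expect_identical(pd$unmatched_detected, 0L)
  expect_identical(pd$unmatched_reference, 0L)
  pd2 <- match_events(r + 0.010, r)
  expect_equal(pd2$differences, rep(10, 4))
  # an extra detection midway between references, beyond max_lag of both
  det <- sort(c(r, 2.5))
  pd3 <- match_events(det, r, max_lag = 0.3)
  expect_identical(pd3$unmatched_detected, 1L)
  expect_equal(pd3$differences, rep(0, 4))
  # agrees with the brute-force optimal assignment on small inputs
  set.seed(3)
  for (k in 1:5) {
    ref <- sort(runif(4, 0, 10))
    det <- sort(c(ref + rnorm(4, 0, 0.05), runif(1, 0, 10)))
    got <- match_events(det, ref, max_lag = 0.2)
    want <- match_oracle(det, ref, 0.2)
    expect_identical(length(got$differences), want$npairs)
  }
  expect_error(match_events(1:3, numeric()), "empty")
  expect_error(match_events(c(2, 1), c(1, 2)), "ordered")
})

test_that("bland_altman computes bias, 1.96-SD limits and their width", {
  ba <- bland_altman(c(-10, 0, 10))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_lower, -19.6)
  expect_equal(ba$loa_upper, 19.6)
  expect_equal(ba$max_precision, 39.2)
  ba0 <- bland_altman(rep(0, 5))
  expect_equal(ba0$max_precision, 0)
  expect_error(bland_altman(5), "at least 2")
  # symmetry invariant: upper - bias == bias - lower
  set.seed(8)
  d <- rnorm(50, 3, 7)
  ba2 <- bland_altman(d)
  expect_equal(ba2$loa_upper - ba2$bias, ba2$bias - ba2$loa_lower,
               tolerance = 1e-9)
})

test_that("limits of agreement cover ~95% of large Gaussian samples", {
  set.seed(123)
  d <- rnorm(1e4, 2, 12)
  ba <- bland_altman(d)
  cover <- mean(d >= ba$loa_lower & d <= ba$loa_upper)
  expect_equal(cover, 0.95, tolerance = 0.006)
})

test_that("reference_loa takes the widest envelope over rater pairs", {
  ref <- reference_loa(list(c(-19.6, 23.4), c(-21.4, 28.0), c(-19.8, 30.0)))
  expect_equal(ref$lower, -21.4)
  expect_equal(ref$upper, 30.0)
  expect_equal(ref$max_precision, 51.4)
  one <- reference_loa(list(c(-5, 7)))
  expect_equal(c(one$lower, one$upper), c(-5, 7))
  same <- reference_loa(list(c(-5, 7), c(-5, 7), c(-5, 7)))
  expect_equal(c(same$lower, same$upper), c(-5, 7))
  expect_error(reference_loa(list()), "no rater")
})

test_that("adjust_precision implements the four adjustment cases", {
  ref <- c(-21.4, 30.0)
  a <- adjust_precision(c(-28.0, 28.6), ref)
  expect_equal(a$total, 6.6); expect_identical(a$case, "b")
  b <- adjust_precision(c(-33.0, 22.2), ref)
  expect_equal(b$total, 11.6); expect_identical(b$case, "b")
  c2 <- adjust_precision(c(-29.8, 34.4), ref)
  expect_equal(c2$adj_lower, 8.4); expect_equal(c2$adj_upper, 4.4)
  expect_equal(c2$total, 12.8); expect_identical(c2$case, "a")
  d <- adjust_precision(ref, ref)
  expect_equal(d$total, 0); expect_identical(d$case, "c")
  e <- adjust_precision(c(35, 60), ref)
  expect_true(e$discarded); expect_identical(e$case, "d")
  e2 <- adjust_precision(c(-80, -25), ref)
  expect_true(e2$discarded)
  expect_error(adjust_precision(c(10, -10), ref), "lower limit exceeds")
})

test_that("adjusted precision is zero iff contained, and monotone in the limits", {
  ref <- c(-21.4, 30.0)
  set.seed(4)
  for (k in 1:50) {
    lo <- runif(1, -60, 25); hi <- runif(1, lo, 70)
    ap <- adjust_precision(c(lo, hi), ref)
    if (ap$discarded) next
    contained <- lo >= ref[1] && hi <= ref[2]
    expect_identical(ap$total == 0, contained)
    # pushing either limit outward never decreases the total
    ap_wider <- adjust_precision(c(lo - 3, hi + 3), ref)
    if (!ap_wider$discarded) expect_gte(ap_wider$total, ap$total)
  }
})

test_that("three-step selection picks the averaged gyro z at 3 Hz from the published table", {
  tab <- variant_loa_table()
  avg <- tab[tab$source == "average",
             c("sensor", "axis", "source", "cutoff_hz", "bias",
               "loa_lower", "loa_upper")]
  ref <- reference_loa(lapply(1:3, function(i) {
    r <- rater_loa_table(); c(r$loa_lower[i], r$loa_upper[i])
  }))
  sel <- select_best(avg, ref)
  expect_identical(sel$winner$sensor, "gyro")
  expect_identical(sel$winner$axis, "z")
  expect_equal(sel$winner$cutoff_hz, 3)
  expect_equal(sel$winner$adj_total, 6.6)
  # runner-up among the gyroscope variants is the averaged resultant at 3 Hz
  gy <- sel$table[sel$table$sensor == "gyro" & sel$table$fate == "ranked", ]
  expect_equal(sort(gy$adj_total)[2], 11.6)
  # accelerometer x rows fall at step 1 (bias outside the reference limits)
  accx <- sel$table[sel$table$sensor == "acc" & sel$table$axis == "x", ]
  expect_true(all(accx$fate == "excluded_bias"))
  expect_true(any(accx$bias == -57.4))
  # selection is invariant to input row order
  sel2 <- select_best(avg[rev(seq_len(nrow(avg))), ], ref)
  expect_identical(sel2$winner$adj_total, sel$winner$adj_total)
  expect_identical(sel2$table$fate, sel$table$fate)
})

test_that("selection handles gates and empty survivor sets", {
  ref <- c(-21.4, 30.0)
  tab <- data.frame(sensor = "gyro", axis = "z", source = "average",
                    cutoff_hz = 3, bias = 1, loa_lower = -25, loa_upper = 28)
  sel <- select_best(tab, ref)
  expect_equal(sel$winner$adj_total, 3.6)
  tab$bias <- -50
  expect_null(select_best(tab, ref)$winner)
  tab$bias <- 1; tab$loa_lower <- -90
  expect_null(select_best(tab, ref, threshold_ms = 20)$winner)
})

test_that("percentile interval uses linear interpolation of order statistics", {
  ci <- percentile_ci(1:100)
  expect_equal(unname(ci), c(3.475, 97.525))
  sym <- percentile_ci(c(-4, 0, 4))
  expect_equal(unname(sym[1]), -unname(sym[2]))
  expect_equal(unname(percentile_ci(rep(7, 10))), c(7, 7))
  expect_error(percentile_ci(1), "at least 2")
})

test_that("mean/SD accuracy-precision follows the literature convention", {
  expect_equal(unname(mean_sd_accuracy_precision(rep(0, 4))), c(0, 0))
  expect_equal(unname(mean_sd_accuracy_precision(c(-10, 0, 10))), c(0, 10))
  expect_equal(unname(mean_sd_accuracy_precision(rep(5, 3))), c(5, 0))
})
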
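#' Match detected events to reference events
#'
#' Pairs detected turn switches with reference switch times by greedy
#' nearest-neighbour matching in time under a one-to-one constraint:
#' repeatedly take the globally closest (detected, reference) pair among the
#' still-unmatched events, accept it if within `max_lag`, and remove both.
#' Leftover events on either side are counted as unmatched.
#'
#' @param detected a [switch_series()] or numeric vector of times (s).
#' @param reference numeric vector of reference times in seconds.
#' @param max_lag maximum pairing lag in seconds; default half the median
#'   reference inter-switch interval.
#' @return A list of class `paired_diffs`: `differences` (detected minus
#'   reference, in ms, one per matched pair, in reference time order),
#'   `unmatched_detected`, `unmatched_reference`.
#' @examples
#' match_events(c(1.01, 2.00, 3.02), c(1, 2, 3))$differences
#' @export
match_events <- function(detected, reference, max_lag = NULL) {
  if (inherits(detected, "switch_series")) detected <- detected$times
  detected <- as.numeric(detected)
  reference <- as.numeric(reference)
  if (!length(reference)) stop("reference event list is empty", call. = FALSE)
  if (is.unsorted(detected, strictly = FALSE) ||
      is.unsorted(reference, strictly = FALSE)) {
    stop("event lists must be time-ordered", call. = FALSE)
  }
  if (is.null(max_lag)) {
    max_lag <- if (length(reference) >= 2) median(diff(reference)) / 2 else Inf
  }
  if (max_lag <= 0) stop("max_lag must be > 0", call. = FALSE)
  nd <- length(detected); nr <- length(reference)
  used_d <- logical(nd); used_r <- logical(nr)
  pairs_r <- integer(); pairs_d <- integer()
  if (nd > 0) {
    lag <- abs(outer(detected, reference, "-"))
    repeat {
      lag_open <- lag
      lag_open[used_d, ] <- Inf
      lag_open[, used_r] <- Inf
      m <- which.min(lag_open)
      if (!length(m) || lag_open[m] > max_lag) break
      i <- (m - 1L) %% nd + 1L
      j <- (m - 1L) %/% nd + 1L
      used_d[i] <- TRUE; used_r[j] <- TRUE
      pairs_d <- c(pairs_d, i); pairs_r <- c(pairs_r, j)
      if (all(used_d) || all(used_r)) break
    }
  }
  ord <- order(pairs_r)
  diffs_ms <- (detected[pairs_d[ord]] - reference[pairs_r[ord]]) * 1000
  structure(list(differences = diffs_ms,
                 unmatched_detected = sum(!used_d),
                 unmatched_reference = sum(!used_r)),
            class = "paired_diffs")
}

#' @export
print.paired_diffs <- function(x, ...) {
  cat(sprintf("<paired_diffs> n=%d  unmatched detected=%d reference=%d\n",
              length(x$differences), x$unmatched_detected,
              x$unmatched_reference))
  invisible(x)
}

#' Bland-Altman limits of agreement
#'
#' Bias (mean difference) and 95% limits of agreement, bias +/- 1.96 times
#' the sample standard deviation (n-1 denominator) of the paired
#' differences. The maximum precision of the comparison is the width of the
#' interval, upper minus lower.
#'
#' @param diffs a `paired_diffs` from [match_events()], or a numeric vector
#'   of paired differences in ms.
#' @return A list of class `agreement_result`: `bias`, `loa_lower`,
#'   `loa_upper`, `max_precision` (all ms), `n`.
#' @examples
#' bland_altman(c(-10, 0, 10))  # bias 0, LoA -19.6..19.6, width 39.2
#' @export
bland_altman <- function(diffs) {
  if (inherits(diffs, "paired_diffs")) diffs <- diffs$differences
  diffs <- as.numeric(diffs)
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 paired differences", call. = FALSE)
  bias <- mean(diffs)
  s <- sd(diffs)
  structure(list(bias = bias,
                 loa_lower = bias - 1.96 * s,
                 loa_upper = bias + 1.96 * s,
                 max_precision = 2 * 1.96 * s,
                 n = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> bias %.1f ms  LoA [%.1f, %.1f] ms  width %.1f ms  n=%d\n",
    x$bias, x$loa_lower, x$loa_upper, x$max_precision, x$n))
  invisible(x)
}

#' Reference limits of agreement over rater pairs
#'
#' The reference envelope of a multi-rater study: the highest upper limit
#' and the lowest lower limit over all pairwise rater limits of agreement.
#' Its width is the maximum precision attainable by any method evaluated
#' against this reference.
#'
#' @param rater_results a list of `agreement_result` objects (or of
#'   2-vectors `c(lower, upper)` in ms), one per rater pair.
#' @return A list of class `reference_loa`: `lower`, `upper`,
#'   `max_precision` (ms).
#' @examples
#' reference_loa(list(c(-19.6, 23.4), c(-21.4, 28.0), c(-19.8, 30.0)))
#' @export
reference_loa <- function(rater_results) {
  if (!length(rater_results)) stop("no rater pairs supplied", call. = FALSE)
  lims <- lapply(rater_results, function(r) {
    if (inherits(r, "agreement_result")) c(r$loa_lower, r$loa_upper)
    else as.numeric(r)
  })
  lower <- min(vapply(lims, `[`, numeric(1), 1))
  upper <- max(vapply(lims, `[`, numeric(1), 2))
  structure(list(lower = lower, upper = upper,
                 max_precision = upper - lower),
            class = "reference_loa")
}

#' @export
print.reference_loa <- function(x, ...) {
  cat(sprintf("<reference_loa> [%.1f, %.1f] ms  max precision %.1f ms\n",
              x$lower, x$upper, x$max_precision))
  invisible(x)
}

#' Reference-adjusted precision of a measured limits-of-agreement interval
#'
#' A measurement method cannot be more precise than the reference it is
#' judged against. Each measured limit is therefore expressed net of the
#' reference envelope: a limit lying beyond its reference limit contributes
#' its exceedance `|measured - reference|`; a limit lying inside the
#' reference range is replaced by the reference limit and contributes zero.
#' The adjusted precision is the sum of the two sides. Cases:
#' \describe{
#'   \item{a}{both limits beyond their respective reference limits;}
#'   \item{b}{one limit beyond, one inside;}
#'   \item{c}{both inside -- adjusted precision 0, the method is as precise
#'     as the reference allows one to claim;}
#'   \item{d}{the measured interval lies entirely beyond one reference limit
#'     (both limits above the upper, or both below the lower): the method is
#'     discarded.}
#' }
#'
#' @param measured 2-vector `c(lower, upper)` of measured LoA in ms.
#' @param ref a [reference_loa()] (or 2-vector `c(lower, upper)`).
#' @return A list of class `adjusted_precision`: `adj_lower`, `adj_upper`,
#'   `total` (ms; `NA` when discarded), `case` (`"a"`..`"d"`), `discarded`.
#' @examples
#' adjust_precision(c(-28.0, 28.6), c(-21.4, 30.0))  # total 6.6, case b
#' @export
adjust_precision <- function(measured, ref) {
  if (inherits(ref, "reference_loa")) ref <- c(ref$lower, ref$upper)
  measured <- as.numeric(measured); ref <- as.numeric(ref)
  if (measured[1] > measured[2]) {
    stop("measured lower limit exceeds upper limit", call. = FALSE)
  }
  if (measured[1] > ref[2] || measured[2] < ref[1]) {
    return(structure(list(adj_lower = NA_real_, adj_upper = NA_real_,
                          total = NA_real_, case = "d", discarded = TRUE),
                     class = "adjusted_precision"))
  }
  adj_lower <- if (measured[1] < ref[1]) abs(measured[1] - ref[1]) else 0
  adj_upper <- if (measured[2] > ref[2]) measured[2] - ref[2] else 0
  n_out <- (adj_lower > 0) + (adj_upper > 0)
  case <- c("c", "b", "a")[n_out + 1L]
  structure(list(adj_lower = adj_lower, adj_upper = adj_upper,
                 total = adj_lower + adj_upper, case = case,
                 discarded = FALSE),
            class = "adjusted_precision")
}

#' @export
print.adjusted_precision <- function(x, ...) {
  if (x$discarded) cat("<adjusted_precision> discarded (case d)\n")
  else cat(sprintf("<adjusted_precision> total %.1f ms (lower %.1f + upper %.1f), case %s\n",
                   x$total, x$adj_lower, x$adj_upper, x$case))
  invisible(x)
}

#' Three-step selection of the best detection variant
#'
#' Applies the selection rules to a table of per-variant agreement results:
#' \enumerate{
#'   \item exclude variants whose bias falls outside the reference limits of
#'     agreement;
#'   \item compute each survivor's reference-adjusted precision and exclude
#'     discarded (case d) variants and those above `threshold_ms`;
#'   \item rank survivors by adjusted precision ascending (ties broken by
#'     smaller absolute bias, then lower cutoff); the first is the winner.
#' }
#'
#' @param results data frame with columns `sensor`, `axis`, `source`,
#'   `cutoff_hz`, `bias`, `loa_lower`, `loa_upper` (ms; LoA may be `NA` for
#'   variants already excluded upstream -- they are dropped at step 1 only
#'   if the bias rule fires, otherwise at step 2 for lack of limits).
#' @param ref a [reference_loa()] or 2-vector.
#' @param threshold_ms adjusted-precision exclusion threshold, default 20 ms
#'   (one 50 Hz video frame).
#' @return A list of class `selection_report`: `table` (the input plus
#'   `adj_lower`, `adj_upper`, `adj_total`, `case`, `fate`, `rank`) and
#'   `winner` (row of the best variant, or `NULL` if no survivor).
#' @export
select_best <- function(results, ref, threshold_ms = 20) {
  if (inherits(ref, "reference_loa")) ref <- c(ref$lower, ref$upper)
  stopifnot(is.data.frame(results))
  need <- c("sensor", "axis", "source", "cutoff_hz", "bias",
            "loa_lower", "loa_upper")
  miss <- setdiff(need, names(results))
  if (length(miss)) {
    stop("results table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab <- results[order(results$sensor, results$axis, results$source,
                       results$cutoff_hz, na.last = FALSE), , drop = FALSE]
  n <- nrow(tab)
  tab$adj_lower <- tab$adj_upper <- tab$adj_total <- NA_real_
  tab$case <- NA_character_
  tab$fate <- NA_character_
  for (i in seq_len(n)) {
    if (is.na(tab$bias[i]) || tab$bias[i] < ref[1] || tab$bias[i] > ref[2]) {
      tab$fate[i] <- "excluded_bias"
      next
    }
    if (is.na(tab$loa_lower[i]) || is.na(tab$loa_upper[i])) {
      tab$fate[i] <- "excluded_no_loa"
      next
    }
    ap <- adjust_precision(c(tab$loa_lower[i], tab$loa_upper[i]), ref)
    tab$adj_lower[i] <- ap$adj_lower
    tab$adj_upper[i] <- ap$adj_upper
    tab$adj_total[i] <- ap$total
    tab$case[i] <- ap$case
    if (ap$discarded) tab$fate[i] <- "discarded"
    else if (ap$total > threshold_ms) tab$fate[i] <- "excluded_precision"
    else tab$fate[i] <- "ranked"
  }
  ranked <- which(tab$fate == "ranked")
  tab$rank <- NA_integer_
  if (length(ranked)) {
    key <- order(tab$adj_total[ranked], abs(tab$bias[ranked]),
                 tab$cutoff_hz[ranked], na.last = TRUE)
    tab$rank[ranked[key]] <- seq_along(ranked)
  }
  winner <- if (length(ranked)) tab[which(tab$rank == 1L), , drop = FALSE] else NULL
  structure(list(table = tab, winner = winner, ref = ref,
                 threshold_ms = threshold_ms),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d variants, ref LoA [%.1f, %.1f] ms, threshold %.0f ms\n",
              nrow(x$table), x$ref[1], x$ref[2], x$threshold_ms))
  if (is.null(x$winner)) cat("  no variant survived selection\n")
  else cat(sprintf("  winner: %s %s %s @ %s Hz (adjusted precision %.1f ms)\n",
                   x$winner$sensor, x$winner$axis, x$winner$source,
                   ifelse(is.na(x$winner$cutoff_hz), "raw", x$winner$cutoff_hz),
                   x$winner$adj_total))
  invisible(x)
}

#' Empirical percentile confidence interval of timing differences
#'
#' 2.5th and 97.5th percentiles (by default) of the paired differences,
#' using linear interpolation between order statistics (R quantile type 7).
#' Reported alongside the limits of agreement when differences are not
#' normally distributed.
#'
#' @param diffs numeric vector of differences in ms (n >= 2), or a
#'   `paired_diffs`.
#' @param lo,hi percentile bounds in percent.
#' @param type quantile definition passed to [stats::quantile()].
#' @return Named 2-vector `c(lower, upper)` in ms.
#' @export
percentile_ci <- function(diffs, lo = 2.5, hi = 97.5, type = 7) {
  if (inherits(diffs, "paired_diffs")) diffs <- diffs$differences
  if (length(diffs) < 2L) stop("need at least 2 differences", call. = FALSE)
  q <- quantile(diffs, c(lo, hi) / 100, type = type, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Mean/SD accuracy and precision (literature convention)
#'
#' Accuracy as the mean difference and precision as the sample standard
#' deviation of the differences -- the convention of earlier turn-detection
#' studies, provided for comparison only. Unlike limits of agreement, these
#' do not bound where individual detections fall.
#'
#' @param diffs numeric vector of differences in ms (n >= 2), or a
#'   `paired_diffs`.
#' @return Named 2-vector `c(accuracy, precision)` in ms.
#' @export
mean_sd_accuracy_precision <- function(diffs) {
  if (inherits(diffs, "paired_diffs")) diffs <- diffs$differences
  if (length(diffs) < 2L) stop("need at least 2 differences", call. = FALSE)
  c(accuracy = mean(diffs), precision = sd(diffs))
}
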
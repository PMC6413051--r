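#' Read and write boot IMU CSV files
#'
#' The IMU dialect is a plain comma-separated UTF-8 file with header
#' `t,gx,gy,gz,ax,ay,az` and optionally a trailing `side` column when both
#' boots share one file. Times are seconds, gyro channels degrees/s, acc
#' channels g (units are fixed by convention, not autodetected). A JSON
#' sidecar written next to each signal records rate, units and the axis
#' convention.
#'
#' @param path CSV file path.
#' @param side boot side when the file has no `side` column.
#' @param rate nominal rate in Hz; inferred from the timestamps if `NULL`.
#' @return `read_boot_csv()`: a single [boot_signal()], or a named list
#'   `list(left = , right = )` when the file carries a `side` column with
#'   both boots.
#' @export
read_boot_csv <- function(path, side = NULL, rate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "gx", "gy", "gz", "ax", "ay", "az")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("malformed IMU CSV '", path, "': missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  mk <- function(d, s) {
    boot_signal(d$t, d$gx, d$gy, d$gz, d$ax, d$ay, d$az, side = s,
                rate = rate)
  }
  if ("side" %in% names(df)) {
    sides <- unique(df$side)
    out <- lapply(sides, function(s) mk(df[df$side == s, ], s))
    names(out) <- sides
    if (length(out) == 1L) out[[1L]] else out
  } else {
    if (is.null(side)) {
      stop("file has no 'side' column; pass side = 'left' or 'right'",
           call. = FALSE)
    }
    mk(df, side)
  }
}

#' @rdname read_boot_csv
#' @param signal a [boot_signal()] (or list of them) to write.
#' @param sidecar write a JSON sidecar (`<path>.json`) with rate, units and
#'   axis convention; default `TRUE`.
#' @export
write_boot_csv <- function(signal, path, sidecar = TRUE) {
  if (inherits(signal, "boot_signal")) signal <- list(signal)
  rows <- do.call(rbind, lapply(signal, function(s) {
    cbind(as.data.frame(s), side = signal_side(s))
  }))
  if (length(signal) == 1L) rows$side <- NULL
  write.csv(format(rows, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(rate_hz = signal_rate(signal[[1]]),
                 units = list(t = "s", gyro = "deg/s", acc = "g"),
                 axes = list(x = "boot vertical (superior)",
                             y = "lateral (left)",
                             z = "roll / anterior-posterior (posterior)"),
                 sides = vapply(signal, signal_side, character(1)))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read/write turn-switch event CSVs
#'
#' Events are stored as `time_s,direction,variant`, times in seconds with 6
#' decimal places.
#'
#' @param events a [switch_series()].
#' @param path CSV path.
#' @param variant variant label stored with each event.
#' @export
write_events_csv <- function(events, path, variant = "") {
  df <- as.data.frame(events)
  df$time_s <- sprintf("%.6f", df$time_s)
  df$variant <- variant
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "direction") %in% names(df))) {
    stop("malformed events CSV '", path,
         "': need columns time_s, direction", call. = FALSE)
  }
  switch_series(df$time_s, df$direction)
}

#' Read/write rater annotation CSVs
#'
#' Annotations are stored long, one row per (turn, rater):
#' `turn_index,rater_id,time_s`.
#'
#' @param study a `rater_study` from [simulate_raters()] or an annotations
#'   data frame.
#' @param path CSV path.
#' @export
write_raters_csv <- function(study, path) {
  ann <- if (inherits(study, "rater_study")) study$annotations else study
  ann$time_s <- sprintf("%.6f", ann$time_s)
  write.csv(ann, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raters_csv
#' @return `read_raters_csv()`: annotations data frame with per-turn
#'   reference times (mean across raters) in attribute `"reference"`.
#' @export
read_raters_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("turn_index", "rater_id", "time_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("malformed rater CSV '", path, "': missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ref <- tapply(df$time_s, df$turn_index, mean)
  attr(df, "reference") <- as.numeric(ref[order(as.numeric(names(ref)))])
  df
}

#' Published screening-study agreement tables
#'
#' Returns the per-variant measured bias and 95% limits of agreement (ms)
#' from the boot-IMU ergometer validation experiment
#' (`variant_loa_table()`), and the pairwise inter-rater limits of
#' agreement of its three-expert video reference (`rater_loa_table()`).
#' These printed values are shipped with the package so the
#' reference-adjusted precision arithmetic and the selection pipeline can
#' be exercised on the study's own numbers. `adj_printed` is the adjusted
#' precision as published (3-significant-figure rounding in places); `NA`
#' limits mark variants that were excluded at the bias step, where no
#' limits were published.
#'
#' @return A data frame.
#' @export
variant_loa_table <- function() {
  read.csv(system.file("extdata", "variant_loa_ms.csv", package = "skiturn"),
           stringsAsFactors = FALSE)
}

#' @rdname variant_loa_table
#' @export
rater_loa_table <- function() {
  read.csv(system.file("extdata", "rater_loa_ms.csv", package = "skiturn"),
           stringsAsFactors = FALSE)
}
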
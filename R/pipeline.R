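#' Pipeline run configuration
#'
#' Composes the simulator, detector and evaluation settings of a full
#' `simulate -> detect -> evaluate -> select` run into one validated,
#' JSON-serializable object. Unknown keys are rejected so a typo in a
#' config file fails loudly instead of being ignored.
#'
#' @param synth `NULL`, or a list of [synth_config()] arguments (the session
#'   is then simulated; otherwise `left_csv`/`right_csv` must be given).
#' @param detection list of [detection_config()] arguments (less `variant`).
#' @param variants character vector of variant strings
#'   (`"sensor:axis:source:cutoff"`, `0` = no filter), or `"all"` for the
#'   full 120-member grid.
#' @param analysis_rate_hz rate every signal is resampled to before
#'   detection, default 50 (the video reference rate).
#' @param max_lag_s event-pairing lag cap in seconds; `NULL` = half the
#'   median reference inter-switch interval.
#' @param threshold_ms selection threshold on adjusted precision, default 20.
#' @param percentile_type quantile definition for [percentile_ci()].
#' @param left_csv,right_csv input IMU CSVs when not simulating.
#' @param raters_csv rater annotation CSV when not simulating.
#' @param rater_sd_ms,rater_bias_ms,n_raters simulated rater study settings.
#' @param out_dir output directory, or `NULL` to write nothing.
#' @param seed integer seed for all randomness in the run.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synth = list(), detection = list(),
                       variants = "gyro:z:average:3",
                       analysis_rate_hz = 50,
                       max_lag_s = NULL, threshold_ms = 20,
                       percentile_type = 7,
                       left_csv = NULL, right_csv = NULL, raters_csv = NULL,
                       rater_sd_ms = 6.3, rater_bias_ms = 0, n_raters = 3,
                       out_dir = NULL, seed = 1L,
                       log_level = c("info", "quiet", "debug")) {
  log_level <- match.arg(log_level)
  cfg <- list(synth = synth, detection = detection, variants = variants,
              analysis_rate_hz = analysis_rate_hz, max_lag_s = max_lag_s,
              threshold_ms = threshold_ms, percentile_type = percentile_type,
              left_csv = left_csv, right_csv = right_csv,
              raters_csv = raters_csv, rater_sd_ms = rater_sd_ms,
              rater_bias_ms = rater_bias_ms, n_raters = n_raters,
              out_dir = out_dir, seed = as.integer(seed),
              log_level = log_level)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON file to read/write.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in c("synth", "detection")) {
    if (!is.null(raw[[k]])) raw[[k]] <- as.list(raw[[k]])
  }
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

pipe_log <- function(cfg, level, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[cfg$log_level]] >= lv[[level]]) message("[skiturn] ", ...)
}

#' Run the full detection-evaluation-selection pipeline
#'
#' Executes, in order: session simulation (or CSV ingestion), resampling of
#' both boots onto a shared grid at the analysis rate, turn-switch detection
#' for every requested variant, event matching against the per-turn
#' reference, Bland-Altman agreement, reference-adjusted precision, and the
#' three-step variant selection. When `cfg$out_dir` is set, writes the
#' per-variant events CSVs, the variant agreement table, the selection
#' report JSON and a manifest with the full config and seed.
#'
#' @param cfg a [run_config()].
#' @return A list of class `pipeline_report`: `variant_table` (per-variant
#'   bias/LoA/adjusted columns), `selection` (a `selection_report`),
#'   `reference` (the [reference_loa()] used), `events` (named list of
#'   [switch_series()]), `truth` (when simulated), `cfg`.
#' @examples
#' rep <- run_pipeline(run_config(synth = list(n_turns = 5), seed = 3,
#'                                log_level = "quiet"))
#' rep$variant_table
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  # --- inputs ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$synth)) {
    sargs <- cfg$synth
    if (is.null(sargs$seed)) sargs$seed <- cfg$seed
    scfg <- do.call(synth_config, sargs)
    pipe_log(cfg, "info", "simulating session: ", scfg$n_turns, " turns, T=",
             scfg$turn_duration, " s, slope=", scfg$slope)
    ses <- simulate_session(scfg)
    left <- ses$left; right <- ses$right; truth <- ses$truth
    study <- simulate_raters(truth, n_raters = cfg$n_raters,
                             rater_bias = cfg$rater_bias_ms,
                             rater_sd = cfg$rater_sd_ms,
                             seed = cfg$seed + 1L)
    reference <- study$reference
  } else {
    if (is.null(cfg$left_csv) || is.null(cfg$right_csv)) {
      stop("no synth config and no input CSVs; nothing to analyze",
           call. = FALSE)
    }
    left <- read_boot_csv(cfg$left_csv, side = "left")
    right <- read_boot_csv(cfg$right_csv, side = "right")
    if (is.null(cfg$raters_csv)) {
      stop("raters_csv is required when analyzing recorded data",
           call. = FALSE)
    }
    ann <- read_raters_csv(cfg$raters_csv)
    study <- ann
    reference <- attr(ann, "reference")
  }
  g <- common_grid(left, right, cfg$analysis_rate_hz)
  # --- rater reference envelope --------------------------------------------
  pw <- tryCatch(rater_pairwise(study), error = function(e) NULL)
  ref <- if (is.null(pw)) NULL else reference_loa(pw)
  # --- detect every variant -------------------------------------------------
  vstr <- cfg$variants
  if (identical(vstr, "all")) {
    gr <- variant_grid()
    vstr <- apply(gr, 1, function(r) {
      co <- if (is.na(r[["cutoff_hz"]])) "0" else r[["cutoff_hz"]]
      paste(r[["sensor"]], r[["axis"]], r[["source"]], co, sep = ":")
    })
  }
  dargs <- cfg$detection
  events <- list()
  rows <- list()
  for (vs in vstr) {
    v <- parse_variant(vs)
    dcfg <- do.call(detection_config, c(list(variant = v), dargs))
    ev <- withCallingHandlers(
      screen_variant(g$left, g$right, v, dcfg),
      warning = function(w) {
        pipe_log(cfg, "debug", vs, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    events[[vs]] <- ev
    row <- data.frame(variant = vs, sensor = v$sensor, axis = v$axis,
                      source = v$source,
                      cutoff_hz = ifelse(is.na(v$cutoff_hz), 0, v$cutoff_hz),
                      n_detected = length(ev$times),
                      bias = NA_real_, loa_lower = NA_real_,
                      loa_upper = NA_real_, pct_lower = NA_real_,
                      pct_upper = NA_real_,
                      unmatched_detected = NA_integer_,
                      unmatched_reference = NA_integer_,
                      stringsAsFactors = FALSE)
    if (length(ev$times) >= 2) {
      pd <- match_events(ev, reference, max_lag = cfg$max_lag_s)
      row$unmatched_detected <- pd$unmatched_detected
      row$unmatched_reference <- pd$unmatched_reference
      if (length(pd$differences) >= 2) {
        ba <- bland_altman(pd)
        pc <- percentile_ci(pd, type = cfg$percentile_type)
        row$bias <- ba$bias
        row$loa_lower <- ba$loa_lower
        row$loa_upper <- ba$loa_upper
        row$pct_lower <- pc[["lower"]]
        row$pct_upper <- pc[["upper"]]
      }
    }
    rows[[vs]] <- row
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  sel <- if (!is.null(ref)) {
    select_best(tab[, c("sensor", "axis", "source", "cutoff_hz", "bias",
                        "loa_lower", "loa_upper")],
                ref, threshold_ms = cfg$threshold_ms)
  } else NULL
  if (!is.null(sel)) {
    tab <- merge(tab, sel$table[, c("sensor", "axis", "source", "cutoff_hz",
                                    "adj_lower", "adj_upper", "adj_total",
                                    "case", "fate", "rank")],
                 by = c("sensor", "axis", "source", "cutoff_hz"),
                 all.x = TRUE, sort = FALSE)
    tab <- tab[order(tab$variant), , drop = FALSE]
    rownames(tab) <- NULL
  }
  report <- structure(list(variant_table = tab, selection = sel,
                           reference = ref, events = events, truth = truth,
                           cfg = cfg),
                      class = "pipeline_report")
  # --- outputs --------------------------------------------------------------
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- cfg$out_dir
    write_boot_csv(list(g$left, g$right), file.path(od, "session_50hz.csv"))
    for (vs in names(events)) {
      safe <- gsub(":", "_", vs, fixed = TRUE)
      write_events_csv(events[[vs]],
                       file.path(od, paste0("events_", safe, ".csv")),
                       variant = vs)
    }
    if (!is.null(truth)) {
      write.csv(data.frame(time_s = sprintf("%.6f", truth$switch_times),
                           direction = truth$switch_directions),
                file.path(od, "truth.csv"), row.names = FALSE, quote = FALSE)
      write_raters_csv(study, file.path(od, "raters.csv"))
    }
    write.csv(tab, file.path(od, "variant_table.csv"), row.names = FALSE)
    if (!is.null(sel)) {
      jsonlite::write_json(
        list(reference = list(lower = ref$lower, upper = ref$upper,
                              max_precision = ref$max_precision),
             threshold_ms = cfg$threshold_ms,
             winner = if (is.null(sel$winner)) NULL else
               as.list(sel$winner[1, c("sensor", "axis", "source",
                                       "cutoff_hz", "bias", "adj_total")]),
             table = sel$table),
        file.path(od, "selection.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE, null = "null", na = "null")
      writeLines(selection_markdown(sel), file.path(od, "selection.md"))
    }
    manifest <- list(config = unclass(cfg), seed = cfg$seed,
                     package_version = as.character(utils::packageVersion("skiturn")),
                     r_version = R.version.string)
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    pipe_log(cfg, "info", "outputs written to ", od)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d variant(s)\n", nrow(x$variant_table)))
  if (!is.null(x$selection)) print(x$selection)
  invisible(x)
}

# Markdown rendering of a selection report, one row per variant in the
# published table's bias / lower / upper / adjusted layout.
selection_markdown <- function(sel) {
  tb <- sel$table
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.1f", v))
  c(sprintf("| %s | %s | %s | %s | %s | %s | %s | %s | %s |",
            "sensor", "axis", "source", "cutoff (Hz)", "bias (ms)",
            "lower (ms)", "upper (ms)", "adjusted (ms)", "fate"),
    "|---|---|---|---|---|---|---|---|---|",
    vapply(seq_len(nrow(tb)), function(i) {
      sprintf("| %s | %s | %s | %s | %s | %s | %s | %s | %s |",
              tb$sensor[i], tb$axis[i], tb$source[i],
              ifelse(is.na(tb$cutoff_hz[i]) | tb$cutoff_hz[i] == 0, "raw",
                     tb$cutoff_hz[i]),
              fmt(tb$bias[i]), fmt(tb$loa_lower[i]), fmt(tb$loa_upper[i]),
              fmt(tb$adj_total[i]), tb$fate[i])
    }, character(1)))
}
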
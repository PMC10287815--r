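# File interchange: trace CSVs with JSON sidecars, tidy outcome CSVs,
# run configuration, and report serialization. All units are fixed in the
# column headers (s, pct, N, MPa, cmH2O, uV, Hz); decimal point is '.'.

MECH_COLS <- c("time_s", "strain_x_pct", "strain_y_pct", "force_x_N", "force_y_N")

read_csv_strict <- function(path, required) {
  stop_unless(file.exists(path), sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write / read a biaxial mechanics trace
#'
#' The trace data go to `<path>` as CSV (`time_s`, `strain_x_pct`,
#' `strain_y_pct`, `force_x_N`, `force_y_N`); geometry, protocol and the
#' specimen id go to a `<path>.json` sidecar. Numeric payloads round-trip to
#' better than 1e-9 relative.
#'
#' @param trace A `mech_trace`.
#' @param path CSV file path (sidecar written next to it).
#' @return `write_mech_trace()` returns `path` invisibly; `read_mech_trace()`
#'   returns a `mech_trace`.
#' @export
write_mech_trace <- function(trace, path) {
  stop_unless(inherits(trace, "mech_trace"), "`trace` must be a mech_trace")
  readr::write_csv(trace$data, path)
  meta <- list(specimen_id = trace$specimen_id,
               geometry = unclass(trace$geometry),
               protocol = unclass(trace$protocol))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mech_trace
#' @export
read_mech_trace <- function(path) {
  df <- read_csv_strict(path, MECH_COLS)
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop(sprintf("%s: time_s must be strictly increasing", path), call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  stop_unless(file.exists(sidecar), sprintf("missing sidecar: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  structure(
    list(data = tibble::as_tibble(df[MECH_COLS]),
         geometry = do.call(specimen_geometry, meta$geometry),
         protocol = do.call(mech_protocol, meta$protocol),
         params = NULL, specimen_id = meta$specimen_id),
    class = "mech_trace"
  )
}

#' Write / read an ephys trial (voltage CSV + marker sidecar)
#'
#' Voltage samples go to `<path>` (`time_s`, `value_uV`); sample rate,
#' channel, marker windows and the filtered flag go to `<path>.json`. For an
#' LPP trial the pressure channel is written to a parallel
#' `<path>.pressure.csv` with its own markers in the main sidecar.
#'
#' @param trial Either a `neuro_trace` (ENG) or a list with `pressure` and
#'   `emg` (LPP trial).
#' @param path CSV file path.
#' @return `path` invisibly; readers return the corresponding object.
#' @export
write_ephys_trial <- function(trial, path) {
  trace <- if (inherits(trial, "neuro_trace")) trial else trial$emg
  stop_unless(inherits(trace, "neuro_trace"), "no neuro_trace found in `trial`")
  readr::write_csv(trace$data, path)
  meta <- list(sample_rate = trace$sample_rate, channel = trace$channel,
               markers = trace$markers, filtered = trace$filtered)
  if (!inherits(trial, "neuro_trace")) {
    readr::write_csv(trial$pressure$data, paste0(path, ".pressure.csv"))
    meta$pressure_markers <- trial$pressure$markers
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ephys_trial
#' @export
read_ephys_trial <- function(path) {
  df <- read_csv_strict(path, c("time_s", "value_uV"))
  sidecar <- paste0(path, ".json")
  stop_unless(file.exists(sidecar), sprintf("missing sidecar: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  trace <- new_neuro_trace(df$time_s, df$value_uV, meta$sample_rate,
                           meta$channel, meta$markers,
                           filtered = isTRUE(meta$filtered))
  pfile <- paste0(path, ".pressure.csv")
  if (!is.null(meta$pressure_markers) && file.exists(pfile)) {
    pdf <- read_csv_strict(pfile, c("time_s", "pressure_cmH2O"))
    pressure <- structure(
      list(data = tibble::as_tibble(pdf), markers = meta$pressure_markers),
      class = "pressure_trace"
    )
    return(list(pressure = pressure, emg = trace))
  }
  trace
}

#' @rdname read_ephys_trial
#' @export
read_lpp_trial <- function(path) {
  out <- read_ephys_trial(path)
  stop_unless(is.list(out) && !inherits(out, "neuro_trace") &&
                inherits(out$pressure, "pressure_trace"),
              sprintf("%s holds no pressure channel", path))
  out
}

#' Write / read tidy per-animal outcomes
#'
#' @param outcomes Tibble as returned by [animal_outcome()] /
#'   [analyze_cohort()].
#' @param path CSV path.
#' @return `path` invisibly / the outcomes tibble.
#' @export
write_outcomes <- function(outcomes, path) {
  readr::write_csv(outcomes, path)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  read_csv_strict(path, c("animal_id", "group"))
}

RUN_CONFIG_KEYS <- c("seed", "k_last", "window_pct", "threshold_sd",
                     "dunn_method", "alpha", "strain_levels",
                     "cycles_per_level", "strain_rate", "sample_rate")

#' Load / save a run configuration (YAML)
#'
#' Analysis options with their defaults: `seed` (1), `k_last` (3),
#' `window_pct` (1), `threshold_sd` (4), `dunn_method` ("bonferroni"),
#' `alpha` (0.05), plus protocol overrides (`strain_levels`,
#' `cycles_per_level`, `strain_rate`, `sample_rate`). Unknown keys are
#' rejected; `save_run_config()` then `load_run_config()` is the identity.
#'
#' @param path YAML file path.
#' @param config Named list of options.
#' @return The validated config list.
#' @export
load_run_config <- function(path) {
  stop_unless(file.exists(path), sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname load_run_config
#' @export
save_run_config <- function(config, path) {
  config <- validate_run_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_run_config <- function(cfg) {
  stop_unless(is.list(cfg), "config must be a named list")
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults <- list(seed = 1L, k_last = 3, window_pct = 1, threshold_sd = 4,
                   dunn_method = "bonferroni", alpha = 0.05)
  out <- utils::modifyList(defaults, cfg)
  stop_unless(out$k_last >= 1, "`k_last` must be >= 1")
  stop_unless(out$window_pct > 0, "`window_pct` must be > 0")
  stop_unless(out$threshold_sd > 0, "`threshold_sd` must be > 0")
  stop_unless(out$dunn_method %in% c("bonferroni", "holm", "none"),
              "`dunn_method` must be bonferroni, holm or none")
  out
}

#' Write an analysis report as JSON
#'
#' Serializes the result of [run_study_pipeline()] (group summaries,
#' statistical results and provenance: seed, options, package version).
#'
#' @param report List as returned by [run_study_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  ser_stat <- function(s) {
    if (is.null(s)) return(NULL)
    list(test = s$test, omnibus = s$omnibus,
         pairwise = if (!is.null(s$pairwise)) as.data.frame(s$pairwise),
         alpha = s$alpha, notes = s$notes)
  }
  payload <- list(
    provenance = report$provenance,
    summaries = lapply(report$summaries, as.data.frame),
    mech_stats = lapply(report$mech_stats, ser_stat),
    ai_stats = ser_stat(report$ai_stats),
    functional_stats = lapply(report$functional_stats, ser_stat)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
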
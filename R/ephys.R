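# Leak point pressure, spike detection, firing-rate/amplitude metrics and
# per-animal outcome aggregation.

#' Leak point pressure from a pressure trace
#'
#' LPP is the peak bladder pressure at leakage minus the mean baseline
#' bladder pressure. The peak is taken as the maximum within a small
#' neighborhood of the leak marker; the baseline is the mean over the
#' baseline window, which must precede the marker.
#'
#' @param trace A `pressure_trace` (tibble `time_s`/`pressure_cmH2O` plus
#'   `markers$baseline_window` and `markers$peak_time`).
#' @param peak_halfwidth_s Half-width (s) of the neighborhood searched for the
#'   peak around the marker.
#' @return LPP in cm H2O.
#' @export
compute_lpp <- function(trace, peak_halfwidth_s = 0.5) {
  stop_unless(inherits(trace, "pressure_trace"), "`trace` must be a pressure_trace")
  bw <- trace$markers$baseline_window
  pk <- trace$markers$peak_time
  stop_unless(is.numeric(bw) && length(bw) == 2 && bw[1] < bw[2],
              "baseline window must be an increasing time pair")
  stop_unless(is_scalar_num(pk), "peak marker must be a single time")
  if (pk <= bw[2]) {
    stop("leak/peak marker must come after the baseline window", call. = FALSE)
  }
  tt <- trace$data$time_s
  pr <- trace$data$pressure_cmH2O
  stop_unless(all(is.finite(pr)), "pressure trace contains non-finite values")
  base <- mean(pr[tt >= bw[1] & tt <= bw[2]])
  near <- pr[tt >= pk - peak_halfwidth_s & tt <= pk + peak_halfwidth_s]
  stop_unless(length(near) > 0, "no samples near the peak marker")
  max(near) - base
}

#' Detect spikes by noise-relative threshold crossing
#'
#' The detection threshold is `noise mean + threshold_sd * noise SD`, with
#' noise statistics taken from a designated quiet reference window. Spike
#' events are upward threshold crossings separated by at least the 1 ms
#' refractory period; each event's amplitude is the local peak-to-peak
#' voltage within +/- 1 ms of the spike peak following the crossing. If the
#' trace is marked raw
#' (`filtered = FALSE`) it is band-passed at 3 Hz - 3 kHz first.
#'
#' @param trace A `neuro_trace`.
#' @param window Optional `c(t0, t1)` restricting detection to a time window
#'   (default: whole trace).
#' @param threshold_sd Threshold in noise SDs above the noise mean
#'   (default 4).
#' @param reference Optional `c(t0, t1)` quiet window for noise estimation;
#'   defaults to the trace's `reference` marker.
#' @return A tibble with `time_s` and `amplitude_uV`, one row per detected
#'   spike.
#' @export
detect_spikes <- function(trace, window = NULL, threshold_sd = 4,
                          reference = NULL) {
  stop_unless(inherits(trace, "neuro_trace"), "`trace` must be a neuro_trace")
  stop_unless(is_scalar_num(threshold_sd) && threshold_sd > 0,
              "`threshold_sd` must be > 0")
  reference <- reference %||% trace$markers$reference
  stop_unless(is.numeric(reference) && length(reference) == 2,
              "a quiet reference window is required for noise estimation")
  fs <- trace$sample_rate
  v <- trace$data$value_uV
  tt <- trace$data$time_s
  if (!isTRUE(trace$filtered)) {
    bf <- signal::butter(2, c(3, 3000) / (fs / 2), type = "pass")
    v <- signal::filtfilt(bf, v)
  }
  ref <- v[tt >= reference[1] & tt <= reference[2]]
  stop_unless(length(ref) >= 10, "reference window holds too few samples")
  if (stats::sd(ref) == 0) {
    stop("reference window has zero variance; cannot set a noise-relative threshold",
         call. = FALSE)
  }
  threshold <- mean(ref) + threshold_sd * stats::sd(ref)

  in_win <- if (is.null(window)) rep(TRUE, length(v)) else
    tt >= window[1] & tt < window[2]
  cross <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  cross <- cross[in_win[cross]]
  if (length(cross) > 1) {
    ref_n <- round(REFRACTORY_S * fs)
    keep <- logical(length(cross))
    last <- -Inf
    for (i in seq_along(cross)) {
      if (cross[i] - last >= ref_n) {
        keep[i] <- TRUE
        last <- cross[i]
      }
    }
    cross <- cross[keep]
  }
  half <- round(0.001 * fs)
  amp <- vapply(cross, function(i) {
    # locate the spike peak just after the crossing, then take the local
    # peak-to-peak within +/- 1 ms of that peak (covers a biphasic waveform)
    ahead <- i:min(length(v), i + half)
    pk <- ahead[which.max(v[ahead])]
    ii <- max(1L, pk - half):min(length(v), pk + half)
    diff(range(v[ii]))
  }, numeric(1))
  tibble::tibble(time_s = tt[cross], amplitude_uV = amp)
}

#' Firing rate and amplitude of one analysis segment
#'
#' @param spikes Tibble from [detect_spikes()] restricted to the segment.
#' @param duration_s Segment duration in seconds (the study convention is
#'   1 s segments).
#' @return A list with `firing_rate_Hz`, `amplitude_uV` (mean peak-to-peak;
#'   0 when no spikes) and `duration_s`.
#' @export
segment_metrics <- function(spikes, duration_s = 1) {
  stop_unless(is_scalar_num(duration_s) && duration_s > 0,
              "`duration_s` must be > 0")
  n <- nrow(spikes)
  list(firing_rate_Hz = n / duration_s,
       amplitude_uV = if (n > 0) mean(spikes$amplitude_uV) else 0,
       duration_s = duration_s)
}

#' Baseline-to-stimulated deltas of firing rate and amplitude
#'
#' @param baseline,stim Segment metric lists from [segment_metrics()].
#' @return A list with `d_rate_Hz` and `d_amp_uV` (stimulated minus
#'   baseline).
#' @export
delta_metrics <- function(baseline, stim) {
  list(d_rate_Hz = stim$firing_rate_Hz - baseline$firing_rate_Hz,
       d_amp_uV = stim$amplitude_uV - baseline$amplitude_uV)
}

#' Analyze one LPP trial (pressure + EUS EMG)
#'
#' @param trial A list with `pressure` and `emg`, as produced by
#'   [simulate_lpp_trial()] or [read_lpp_trial()].
#' @param threshold_sd Spike-detection threshold (noise SDs).
#' @return A list with `lpp_cmH2O`, `d_emg_rate_Hz`, `d_emg_amp_uV`.
#' @export
analyze_lpp_trial <- function(trial, threshold_sd = 4) {
  lpp <- compute_lpp(trial$pressure)
  m <- trial$emg$markers
  base <- segment_metrics(detect_spikes(trial$emg, window = m$baseline,
                                        threshold_sd = threshold_sd),
                          duration_s = diff(m$baseline))
  stim <- segment_metrics(detect_spikes(trial$emg, window = m$stim,
                                        threshold_sd = threshold_sd),
                          duration_s = diff(m$stim))
  d <- delta_metrics(base, stim)
  list(lpp_cmH2O = lpp, d_emg_rate_Hz = d$d_rate_Hz, d_emg_amp_uV = d$d_amp_uV)
}

#' Analyze one ENG trial (rest vs brushing)
#'
#' @param trace A `neuro_trace` with `baseline` and `stim` marker windows.
#' @param threshold_sd Spike-detection threshold (noise SDs).
#' @return A list with `d_eng_rate_Hz` and `d_eng_amp_uV`.
#' @export
analyze_eng_trial <- function(trace, threshold_sd = 4) {
  m <- trace$markers
  base <- segment_metrics(detect_spikes(trace, window = m$baseline,
                                        threshold_sd = threshold_sd),
                          duration_s = diff(m$baseline))
  stim <- segment_metrics(detect_spikes(trace, window = m$stim,
                                        threshold_sd = threshold_sd),
                          duration_s = diff(m$stim))
  d <- delta_metrics(base, stim)
  list(d_eng_rate_Hz = d$d_rate_Hz, d_eng_amp_uV = d$d_amp_uV)
}

#' Per-animal functional outcome: trial means
#'
#' Each outcome is the arithmetic mean over that animal's trials; a metric
#' with no trials is recorded as missing (`NA`), never zero.
#'
#' @param animal_id,group Identifiers carried into the output.
#' @param lpp_trials List of analyzed LPP trials ([analyze_lpp_trial()]
#'   results).
#' @param eng_trials List of analyzed ENG trials ([analyze_eng_trial()]
#'   results).
#' @return One-row tibble with `animal_id`, `group`, `lpp_cmH2O`,
#'   `d_emg_rate_Hz`, `d_emg_amp_uV`, `d_eng_rate_Hz`, `d_eng_amp_uV`.
#' @export
animal_outcome <- function(animal_id, group, lpp_trials = list(),
                           eng_trials = list()) {
  pull_mean <- function(trials, field) {
    vals <- vapply(trials, function(x) x[[field]], numeric(1))
    if (length(vals) == 0) NA_real_ else mean(vals)
  }
  out <- tibble::tibble(
    animal_id = animal_id, group = group,
    lpp_cmH2O = pull_mean(lpp_trials, "lpp_cmH2O"),
    d_emg_rate_Hz = pull_mean(lpp_trials, "d_emg_rate_Hz"),
    d_emg_amp_uV = pull_mean(lpp_trials, "d_emg_amp_uV"),
    d_eng_rate_Hz = pull_mean(eng_trials, "d_eng_rate_Hz"),
    d_eng_amp_uV = pull_mean(eng_trials, "d_eng_amp_uV")
  )
  if (anyNA(out)) {
    warning(sprintf("animal '%s': missing trials for %s", animal_id,
                    paste(names(out)[vapply(out, anyNA, logical(1))],
                          collapse = ", ")), call. = FALSE)
  }
  out
}
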
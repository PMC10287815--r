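# Synthetic leak-point-pressure and EMG/ENG trial generation.

SPIKE_TEMPLATE_MS <- 2
REFRACTORY_S <- 0.001

# Biphasic spike template sampled at `fs`; peak-to-peak amplitude 1.
spike_template <- function(fs) {
  n <- max(4L, round(SPIKE_TEMPLATE_MS / 1000 * fs))
  sin(2 * pi * seq(0, 1, length.out = n)) / 2
}

# Homogeneous Poisson spike times on [0, duration) with a 1 ms dead time.
poisson_spike_times <- function(rate, duration) {
  if (rate <= 0 || duration <= 0) return(numeric(0))
  n <- stats::rpois(1, rate * duration)
  if (n == 0) return(numeric(0))
  times <- sort(stats::runif(n, 0, duration))
  keep <- rep(TRUE, n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (times[i] - last < REFRACTORY_S) keep[i] <- FALSE else last <- times[i]
  }
  times[keep]
}

# Gaussian noise band-limited with a 2nd-order Butterworth low-pass at
# `bw` Hz, rescaled to the requested SD. Band-limiting keeps the rate of
# noise upcrossings of a k*SD threshold near the Rice-formula value for a
# ~500 Hz process rather than the much higher white-noise rate.
bandlimited_noise <- function(n, sd, fs, bw = 500) {
  if (sd <= 0) return(numeric(n))
  raw <- stats::rnorm(n + 200)
  bf <- signal::butter(2, min(bw / (fs / 2), 0.99), type = "low")
  smooth <- signal::filtfilt(bf, raw)[101:(n + 100)]
  smooth * (sd / stats::sd(smooth))
}

# Render a spike train plus noise into a voltage vector (uV).
render_spike_train <- function(n, fs, spike_times, amps, noise_sd) {
  v <- bandlimited_noise(n, noise_sd, fs)
  if (length(spike_times) > 0) {
    tpl <- spike_template(fs)
    idx0 <- round(spike_times * fs) + 1L
    for (k in seq_along(idx0)) {
      ii <- idx0[k]:min(idx0[k] + length(tpl) - 1L, n)
      v[ii] <- v[ii] + amps[k] * tpl[seq_along(ii)]
    }
  }
  v
}

new_neuro_trace <- function(time, voltage, sample_rate, channel, markers,
                            filtered = TRUE, spike_times = NULL) {
  structure(
    list(data = tibble::tibble(time_s = time, value_uV = voltage),
         sample_rate = sample_rate, channel = channel, markers = markers,
         filtered = filtered, spike_times = spike_times),
    class = "neuro_trace"
  )
}

#' @export
print.neuro_trace <- function(x, ...) {
  cat(sprintf("<neuro_trace> %s: %.2f s at %g Hz, %d marker(s)%s\n",
              x$channel, nrow(x$data) / x$sample_rate, x$sample_rate,
              length(x$markers), if (isTRUE(x$filtered)) ", band-limited" else ", raw"))
  invisible(x)
}

# Spike train over a structured trial: `segments` is a data.frame with
# columns t0, t1, rate. Amplitudes ~ Normal(amp_mean, amp_sd), truncated at 0.
trial_spikes <- function(segments, params) {
  st <- numeric(0)
  for (i in seq_len(nrow(segments))) {
    s <- poisson_spike_times(segments$rate[i],
                             segments$t1[i] - segments$t0[i]) + segments$t0[i]
    st <- c(st, s)
  }
  st <- sort(st)
  amps <- pmax(stats::rnorm(length(st), params$amp_mean, params$amp_sd), 0)
  list(times = st, amps = amps)
}

#' Simulate one leak-point-pressure trial with simultaneous EUS EMG
#'
#' The bladder pressure holds at `p_baseline` (plus low-pass noise), ramps to
#' `p_leak`, then drops when leakage occurs; the leak marker sits at the
#' pressure peak. The paired EMG trace (10 kHz) fires at `rate_baseline`
#' during the hold and at `rate_stim` during the 1 s surrounding the peak,
#' with a linear rate transition over the ramp. The first 0.4 s of the EMG
#' record is a spike-free quiet reference window for noise estimation.
#'
#' @param params An [ephys_params()] object.
#' @param seed Optional integer seed.
#' @return A list with elements `pressure` (a `pressure_trace`: tibble
#'   `time_s`, `pressure_cmH2O` plus `markers$baseline_window` and
#'   `markers$peak_time`) and `emg` (a `neuro_trace` with `baseline`,
#'   `stim` and `reference` marker windows and the true spike times).
#' @export
simulate_lpp_trial <- function(params, seed = NULL) {
  stop_unless(inherits(params, "ephys_params"), "`params` must be ephys_params")
  with_optional_seed(seed, {
    fs_p <- 100
    t_hold <- 4; t_ramp <- 6; t_fall <- 1; t_post <- 2
    dur <- t_hold + t_ramp + t_fall + t_post
    tp <- seq(0, dur, by = 1 / fs_p)
    peak_time <- t_hold + t_ramp
    pr <- ifelse(tp < t_hold, params$p_baseline,
          ifelse(tp < peak_time,
                 params$p_baseline + (params$p_leak - params$p_baseline) * (tp - t_hold) / t_ramp,
          ifelse(tp < peak_time + t_fall,
                 params$p_leak - (params$p_leak - params$p_baseline) * (tp - peak_time) / t_fall,
                 params$p_baseline)))
    p_noise_sd <- 0.02 * (params$p_leak - params$p_baseline) * (params$noise_sd > 0)
    pr <- pr + bandlimited_noise(length(tp), p_noise_sd, fs_p, bw = 2)
    pressure <- structure(
      list(data = tibble::tibble(time_s = tp, pressure_cmH2O = pr),
           markers = list(baseline_window = c(0.5, 3.5), peak_time = peak_time)),
      class = "pressure_trace"
    )

    fs <- 10000
    n <- round(dur * fs)
    te <- (seq_len(n) - 1) / fs
    ref_win <- c(0, 0.4)
    segs <- data.frame(
      t0 = c(ref_win[2], t_hold, peak_time - 0.5, peak_time + 0.5),
      t1 = c(t_hold, peak_time - 0.5, peak_time + 0.5, dur - SPIKE_TEMPLATE_MS / 1000),
      rate = c(params$rate_baseline,
               (params$rate_baseline + params$rate_stim) / 2,
               params$rate_stim, params$rate_baseline)
    )
    sp <- trial_spikes(segs, params)
    v <- render_spike_train(n, fs, sp$times, sp$amps, params$noise_sd)
    emg <- new_neuro_trace(te, v, fs, "EUS_EMG",
                           markers = list(reference = ref_win,
                                          baseline = c(1.0, 2.0),
                                          stim = c(peak_time - 0.5, peak_time + 0.5)),
                           spike_times = sp$times)
    list(pressure = pressure, emg = emg)
  })
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace> %.1f s, peak marker at %.2f s\n",
              max(x$data$time_s), x$markers$peak_time))
  invisible(x)
}

#' Simulate one pudendal-nerve ENG trial (rest vs genital brushing)
#'
#' As [simulate_lpp_trial()] but without a pressure channel: the trace fires
#' at `rate_baseline` during the rest window and `rate_stim` during the
#' brushing window. Both analysis windows are 1 s long; the first 0.4 s is a
#' spike-free quiet reference.
#'
#' @param params An [ephys_params()] object.
#' @param seed Optional integer seed.
#' @return A `neuro_trace` with `reference`, `baseline` (rest) and `stim`
#'   (brushing) marker windows and the true spike times.
#' @export
simulate_eng_trial <- function(params, seed = NULL) {
  stop_unless(inherits(params, "ephys_params"), "`params` must be ephys_params")
  with_optional_seed(seed, {
    fs <- 10000
    t_rest_end <- 2; t_brush0 <- 2.25; t_brush1 <- 3.75
    dur <- 4.5
    n <- round(dur * fs)
    te <- (seq_len(n) - 1) / fs
    ref_win <- c(0, 0.4)
    segs <- data.frame(
      t0 = c(ref_win[2], t_brush0),
      t1 = c(t_rest_end, t_brush1),
      rate = c(params$rate_baseline, params$rate_stim)
    )
    sp <- trial_spikes(segs, params)
    v <- render_spike_train(n, fs, sp$times, sp$amps, params$noise_sd)
    new_neuro_trace(te, v, fs, "pudendal_ENG",
                    markers = list(reference = ref_win,
                                   baseline = c(0.75, 1.75),
                                   stim = c(t_brush0 + 0.25, t_brush0 + 1.25)),
                    spike_times = sp$times)
  })
}
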
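# Shared fixtures: all test inputs are generated in code.

# Effectively linear material sigma = k * eps: exponential law with a
# vanishing exponent so that A*B = k (relative curvature ~ B*eps/2 < 1e-7).
linear_mech_params <- function(k, eta = 1, noise_sd = 0) {
  B <- 1e-6
  tissue_mech_params(A_x = k / B, A_y = k / B, B_x = B, B_y = B, eta = eta,
                     precond_drop = 0, noise_sd = noise_sd)
}

# Noise-free exponential specimen parameters used across biomech tests.
exp_mech_params <- function(A_x = 0.012, A_y = 0.012, B_x = 16, B_y = 16,
                            eta = 0.8, precond_drop = 0.15) {
  tissue_mech_params(A_x = A_x, A_y = A_y, B_x = B_x, B_y = B_y, eta = eta,
                     precond_drop = precond_drop, noise_sd = 0)
}

# Minimal cycle object for direct metric tests.
make_cycle <- function(strain_l, stress_l, strain_u = rev(strain_l),
                       stress_u = rev(stress_l)) {
  list(loading = list(strain = strain_l, stress_MPa = stress_l),
       unloading = list(strain = strain_u, stress_MPa = stress_u))
}

# Independent least-squares slope oracle via the normal equations.
ne_slope <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[2]
}

# Hand-built neuro trace: `spike_times` get a biphasic template of
# peak-to-peak `amp` on Gaussian noise of sd `noise_sd`; the first 0.4 s is
# kept spike-free as the quiet reference.
make_neuro_trace <- function(spike_times, amp = 120, noise_sd = 5,
                             duration = 2, fs = 10000, seed = 42,
                             markers = list(reference = c(0, 0.4))) {
  set.seed(seed)
  n <- duration * fs
  v <- rnorm(n, 0, noise_sd)
  tpl_n <- round(0.002 * fs)
  tpl <- sin(2 * pi * seq(0, 1, length.out = tpl_n)) * amp / 2
  for (st in spike_times) {
    i0 <- round(st * fs) + 1
    ii <- i0:min(i0 + tpl_n - 1, n)
    v[ii] <- v[ii] + tpl[seq_along(ii)]
  }
  structure(
    list(data = tibble::tibble(time_s = (seq_len(n) - 1) / fs, value_uV = v),
         sample_rate = fs, channel = "EUS_EMG", markers = markers,
         filtered = TRUE, spike_times = spike_times),
    class = "neuro_trace"
  )
}

# Pressure trace with explicit baseline window and peak marker.
make_pressure_trace <- function(pressure, fs = 100,
                                baseline_window = c(0.5, 3.5),
                                peak_time = NULL) {
  tt <- (seq_along(pressure) - 1) / fs
  if (is.null(peak_time)) peak_time <- tt[which.max(pressure)]
  structure(
    list(data = tibble::tibble(time_s = tt, pressure_cmH2O = pressure),
         markers = list(baseline_window = baseline_window,
                        peak_time = peak_time)),
    class = "pressure_trace"
  )
}

# Null four-group outcome table for calibration checks.
null_outcomes <- function(n_per_group = 8, groups = paste0("g", 1:4)) {
  tibble::tibble(
    animal_id = paste0("a", seq_len(n_per_group * length(groups))),
    group = rep(groups, each = n_per_group),
    y = rnorm(n_per_group * length(groups))
  )
}

# Long-format repeated-measures table: four strain levels per animal with a
# per-animal random intercept; group shifts are additive.
make_rm_data <- function(n_per_group = 7, group_shift = c(0, 0, 0, 0),
                         sd_animal = 0.5, sd_resid = 0.3) {
  groups <- paste0("g", seq_along(group_shift))
  levels <- c(4.6, 10, 15.7, 21.6)
  rows <- list()
  for (gi in seq_along(groups)) {
    for (i in seq_len(n_per_group)) {
      id <- paste0(groups[gi], "_", i)
      intercept <- rnorm(1, group_shift[gi], sd_animal)
      rows[[id]] <- tibble::tibble(
        animal_id = id, group = groups[gi], strain_level_pct = levels,
        tangent_modulus_MPa = intercept + 0.1 * seq_along(levels) +
          rnorm(4, 0, sd_resid)
      )
    }
  }
  dplyr::bind_rows(rows)
}
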
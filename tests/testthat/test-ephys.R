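# LPP extraction, spike detection, segment metrics and per-animal outcomes.

test_that("LPP is peak minus baseline mean and ignores constant offsets", {
  pr <- c(rep(10, 400), seq(10, 35, length.out = 200), rep(10, 100))
  tr <- make_pressure_trace(pr)
  expect_equal(compute_lpp(tr), 25)
  tr$data$pressure_cmH2O <- tr$data$pressure_cmH2O + 13.7
  expect_equal(compute_lpp(tr), 25)
  flat <- make_pressure_trace(rep(12, 700), peak_time = 6)
  expect_equal(compute_lpp(flat), 0)
  bad <- make_pressure_trace(pr, peak_time = 1)  # inside the baseline window
  expect_error(compute_lpp(bad), "after the baseline")
})

test_that("noise-free simulated trials leak exactly at p_leak", {
  p <- ephys_params(noise_sd = 0, amp_sd = 0)
  trial <- simulate_lpp_trial(p, seed = 3)
  expect_equal(max(trial$pressure$data$pressure_cmH2O), p$p_leak)
  expect_equal(compute_lpp(trial$pressure), p$p_leak - p$p_baseline)
})

test_that("a clean train of 50 template spikes yields 50 detections with their amplitude", {
  st <- seq(0.5, 1.48, length.out = 50)
  tr <- make_neuro_trace(st, amp = 120, noise_sd = 5)
  # the fixture noise is white (not band-limited), so use a threshold with
  # negligible white-noise upcrossing rate to test pure event counting
  sp <- detect_spikes(tr, window = c(0.5, 1.5), threshold_sd = 5)
  expect_equal(nrow(sp), 50)
  expect_equal(mean(sp$amplitude_uV), 120, tolerance = 0.15)
})

test_that("all-zero signals trip the zero-variance reference guard", {
  tr <- make_neuro_trace(numeric(0), noise_sd = 0)
  tr$data$value_uV <- rep(0, nrow(tr$data))
  expect_error(detect_spikes(tr), "zero variance")
})

test_that("noise-only false positives stay below 5 events/s at a 3 SD threshold", {
  p <- ephys_params(rate_baseline = 0, rate_stim = 0)
  fp3 <- fp4 <- numeric(6)
  for (i in seq_along(fp3)) {
    e <- simulate_eng_trial(p, seed = 100 + i)
    dur <- max(e$data$time_s)
    fp3[i] <- nrow(detect_spikes(e, threshold_sd = 3)) / dur
    fp4[i] <- nrow(detect_spikes(e, threshold_sd = 4)) / dur
  }
  expect_lt(mean(fp3), 5)
  expect_lt(mean(fp4), 0.5)
})

test_that("detection counts are invariant to global gain scaling", {
  p <- ephys_params()
  e <- simulate_eng_trial(p, seed = 11)
  n1 <- nrow(detect_spikes(e))
  e$data$value_uV <- e$data$value_uV * 8.5
  expect_equal(nrow(detect_spikes(e)), n1)
})

test_that("segment metrics count and average; empty segments give zero", {
  sp <- tibble::tibble(time_s = seq_len(50), amplitude_uV = rep(120, 50))
  m <- segment_metrics(sp, duration_s = 1)
  expect_equal(m$firing_rate_Hz, 50)
  expect_equal(m$amplitude_uV, 120)
  m0 <- segment_metrics(sp[0, ], duration_s = 1)
  expect_equal(m0$firing_rate_Hz, 0)
  expect_equal(m0$amplitude_uV, 0)
})

test_that("delta metrics are stim minus baseline and antisymmetric under swap", {
  b <- list(firing_rate_Hz = 20, amplitude_uV = 100, duration_s = 1)
  s <- list(firing_rate_Hz = 60, amplitude_uV = 140, duration_s = 1)
  expect_equal(delta_metrics(b, s), list(d_rate_Hz = 40, d_amp_uV = 40))
  expect_equal(delta_metrics(b, b), list(d_rate_Hz = 0, d_amp_uV = 0))
  fwd <- delta_metrics(b, s)
  rev <- delta_metrics(s, b)
  expect_equal(rev$d_rate_Hz, -fwd$d_rate_Hz)
  expect_equal(rev$d_amp_uV, -fwd$d_amp_uV)
})

test_that("animal outcomes are trial means; absent trials become NA with a flag", {
  lt <- list(list(lpp_cmH2O = 24, d_emg_rate_Hz = 10, d_emg_amp_uV = 5),
             list(lpp_cmH2O = 26, d_emg_rate_Hz = 14, d_emg_amp_uV = 7))
  et <- list(list(d_eng_rate_Hz = 30, d_eng_amp_uV = 12))
  out <- animal_outcome("a1", "sham_veh", lt, et)
  expect_equal(out$lpp_cmH2O, 25)
  expect_equal(out$d_emg_rate_Hz, 12)
  expect_equal(out$d_eng_rate_Hz, 30)  # single trial passes through
  expect_warning(out2 <- animal_outcome("a2", "sham_veh", lt, list()),
                 "missing trials")
  expect_true(is.na(out2$d_eng_rate_Hz))
})

test_that("detected firing rates track the spike-train truth over repeated trials", {
  p <- ephys_params(rate_baseline = 10, rate_stim = 40)
  n_tr <- 40
  det_s <- true_s <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    e <- simulate_eng_trial(p, seed = 500 + i)
    m <- e$markers
    det_s[i] <- nrow(detect_spikes(e, window = m$stim))
    true_s[i] <- sum(e$spike_times >= m$stim[1] & e$spike_times < m$stim[2])
  }
  # detector vs realized generator truth: near-exact at the 4 SD threshold
  expect_lt(abs(mean(det_s) - mean(true_s)), 0.5)
  # realized counts vs the refractory-thinned Poisson expectation
  lam_eff <- p$rate_stim / (1 + p$rate_stim * 0.001)
  expect_lt(abs(mean(true_s) - lam_eff), 3 * sqrt(lam_eff / n_tr))
})

test_that("trial analysis wrappers recover the programmed rate contrast", {
  p <- ephys_params(noise_sd = 8)
  r <- analyze_eng_trial(simulate_eng_trial(p, seed = 77))
  expect_true(is.finite(r$d_eng_rate_Hz) && r$d_eng_rate_Hz > 0)
  trial <- simulate_lpp_trial(p, seed = 78)
  a <- analyze_lpp_trial(trial)
  expect_gt(a$lpp_cmH2O, 0)
  expect_gt(a$d_emg_rate_Hz, 0)
})
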
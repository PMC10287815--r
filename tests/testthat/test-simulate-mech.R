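# Generator contracts: strain profile, preconditioning decay, seeding,
# and the closed-form material oracles.

test_that("noise-free cycle peaks hit their protocol level within one sample step", {
  protocol <- mech_protocol()
  tr <- simulate_specimen_mech(exp_mech_params(), protocol)
  ss <- compute_stress_strain(tr)
  cyc <- segment_cycles(ss$x, protocol)
  step_pct <- protocol$strain_rate / 60 / protocol$sample_rate
  expect_equal(nrow(cyc), 40)
  dev <- abs(cyc$peak_strain * 100 - cyc$strain_level_pct)
  expect_lt(max(dev), step_pct)
})

test_that("preconditioning reaches steady state: cycles 8-10 peaks agree within 1%", {
  # factor formula: 1 - drop * rate^(c-1); relative 8 vs 10 difference for the
  # defaults is drop*(r^7 - r^9)/(1 - drop*r^7) ~ 0.09%
  p <- exp_mech_params()
  predicted <- p$precond_drop * (p$precond_rate^7 - p$precond_rate^9) /
    (1 - p$precond_drop * p$precond_rate^7)
  expect_lt(predicted, 0.01)

  tr <- simulate_specimen_mech(p)
  cyc <- segment_cycles(compute_stress_strain(tr)$x, tr$protocol)
  for (lev in tr$protocol$strain_levels) {
    at <- cyc[cyc$strain_level_pct == lev & cyc$cycle >= 8, ]
    peaks <- vapply(at$loading, function(ld) max(ld$stress_MPa), numeric(1))
    expect_lt(diff(range(peaks)) / max(peaks), 0.01)
  }
})

test_that("early preconditioning cycles are measurably softer than steady state", {
  p <- exp_mech_params()
  tr <- simulate_specimen_mech(p)
  cyc <- segment_cycles(compute_stress_strain(tr)$x, tr$protocol)
  at <- cyc[cyc$strain_level_pct == 21.6, ]
  peaks <- vapply(at$loading, function(ld) max(ld$stress_MPa), numeric(1))
  expect_equal(peaks[1] / peaks[10],
               (1 - p$precond_drop) / (1 - p$precond_drop * p$precond_rate^9),
               tolerance = 5e-3)
})

test_that("seeding contract: same seed is bit-identical, different seeds differ", {
  p <- tissue_mech_params(noise_sd = 0.02)
  a <- simulate_specimen_mech(p, seed = 7)
  b <- simulate_specimen_mech(p, seed = 7)
  c <- simulate_specimen_mech(p, seed = 8)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data$force_x_N, c$data$force_x_N))
})

test_that("non-physical parameters are rejected", {
  expect_error(tissue_mech_params(A_x = -1), "A_x")
  expect_error(tissue_mech_params(eta = 0), "eta")
  expect_error(tissue_mech_params(precond_drop = 1), "precond_drop")
  expect_error(mech_protocol(strain_levels = c(10, 4.6)), "increasing")
  expect_error(mech_protocol(cycles_per_level = 2), "cycles_per_level")
  expect_error(specimen_geometry(thickness = 0), "thickness")
})

test_that("closed-form tangent matches central-difference differentiation", {
  p <- tissue_mech_params(A_x = 0.01, B_x = 20)
  # A=0.01, B=20 at 21.6%: A*B*exp(B*0.216) = 0.2*exp(4.32)
  expect_equal(true_tangent_modulus(p, "x", 21.6), 0.2 * exp(4.32))
  h <- 1e-6
  for (lev in c(4.6, 10, 15.7, 21.6)) {
    eps <- lev / 100
    cd <- (0.01 * (exp(20 * (eps + h)) - 1) - 0.01 * (exp(20 * (eps - h)) - 1)) / (2 * h)
    expect_equal(true_tangent_modulus(p, "x", lev), cd, tolerance = 1e-8)
  }
})

test_that("tangent oracle degenerate and symmetry cases", {
  expect_equal(true_tangent_modulus(tissue_mech_params(B_x = 0), "x", 15), 0)
  p <- tissue_mech_params(A_x = 0.02, A_y = 0.02, B_x = 12, B_y = 12)
  expect_equal(true_tangent_modulus(p, "x", 10), true_tangent_modulus(p, "y", 10))
  expect_error(true_tangent_modulus(p, "z", 10), "axis")
  # strict increase across the four protocol levels for B > 0
  tms <- vapply(c(4.6, 10, 15.7, 21.6),
                function(l) true_tangent_modulus(p, "x", l), numeric(1))
  expect_true(all(diff(tms) > 0))
})

test_that("window-slope oracle converges to the pointwise tangent as the window shrinks", {
  p <- tissue_mech_params(A_x = 0.012, B_x = 16)
  expect_equal(true_window_slope(p, "x", 21.6, window_pct = 1e-4),
               true_tangent_modulus(p, "x", 21.6), tolerance = 1e-4)
  # and against a brute-force discrete least-squares fit of the material curve
  w <- 0.01
  eps <- seq(0.216 - w, 0.216, length.out = 20001)
  brute <- ne_slope(eps, 0.012 * (exp(16 * eps) - 1))
  expect_equal(true_window_slope(p, "x", 21.6, window_pct = 1), brute,
               tolerance = 1e-6)
})
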
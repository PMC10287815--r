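# Biomechanics analysis chain: stress normalization, segmentation,
# steady-cycle selection, slope metrics, tangent modulus, anisotropy index.

test_that("nominal stress is force over initial cross-section", {
  tr <- structure(
    list(data = tibble::tibble(time_s = 0:2, strain_x_pct = c(0, 1, 2),
                               strain_y_pct = c(0, 1, 2),
                               force_x_N = c(0.1, 0.1, 0.1),
                               force_y_N = c(0, 0, 0)),
         geometry = specimen_geometry(thickness = 1, width_x = 10, width_y = 10),
         protocol = mech_protocol(), specimen_id = "s"),
    class = "mech_trace"
  )
  ss <- compute_stress_strain(tr)
  expect_equal(ss$x$stress_MPa, rep(0.01, 3))   # 0.1 N / 10 mm^2
  expect_equal(ss$y$stress_MPa, rep(0, 3))
  expect_equal(ss$x$strain, c(0, 0.01, 0.02))
  tr$geometry$thickness <- 0
  expect_error(compute_stress_strain(tr), "positive")
})

test_that("noise-free simulation round-trips the material law pointwise", {
  p <- tissue_mech_params(A_x = 0.012, B_x = 16, eta = 1, precond_drop = 0,
                          noise_sd = 0)
  tr <- simulate_specimen_mech(p)
  ss <- compute_stress_strain(tr)$x
  expect_lt(max(abs(ss$stress_MPa - p$A_x * (exp(p$B_x * ss$strain) - 1))), 1e-12)
})

test_that("segmentation finds ten cycles per level and errors on truncation", {
  p <- exp_mech_params()
  tr <- simulate_specimen_mech(p)
  ss <- compute_stress_strain(tr)
  cyc <- segment_cycles(ss$x, tr$protocol)
  expect_equal(as.integer(table(cyc$strain_level_pct)), rep(10L, 4))
  expect_equal(cyc$cycle[cyc$strain_level_pct == 10], 1:10)

  # truncate just after the third level starts: levels 15.7 and 21.6 lack cycles
  short <- ss$x[1:round(0.30 * nrow(ss$x)), ]
  attr(short, "axis") <- "x"
  class(short) <- class(ss$x)
  expect_error(segment_cycles(short, tr$protocol), "15.7")
})

test_that("segmentation is robust to strain jitter and assigns peaks to the nearest level", {
  p <- exp_mech_params()
  tr <- simulate_specimen_mech(p)
  set.seed(5)
  tr$data$strain_x_pct <- tr$data$strain_x_pct + rnorm(nrow(tr$data), 0, 0.2)
  ss <- compute_stress_strain(tr)
  cyc <- segment_cycles(ss$x, tr$protocol)
  expect_equal(as.integer(table(cyc$strain_level_pct)), rep(10L, 4))
})

test_that("steady-cycle selection keeps the last k per level", {
  tr <- simulate_specimen_mech(exp_mech_params())
  cyc <- segment_cycles(compute_stress_strain(tr)$x, tr$protocol)
  sel <- select_steady_cycles(cyc, k = 3)
  expect_equal(as.integer(table(sel$strain_level_pct)), rep(3L, 4))
  expect_equal(sort(unique(sel$cycle)), 8:10)
  expect_equal(select_steady_cycles(cyc, k = 10)$cycle, cyc$cycle)
  two <- cyc[cyc$cycle <= 2, ]
  class(two) <- class(cyc)
  expect_error(select_steady_cycles(two, k = 3), "fewer than k")
})

test_that("mean slope averages the loading and unloading first-order fits", {
  eps <- seq(0, 0.1, length.out = 50)
  k <- 3.2
  cy <- make_cycle(eps, k * eps, rev(eps), 0.8 * k * rev(eps))
  expect_equal(mean_slope(cy), 0.9 * k, tolerance = 1e-12)
  # degenerate constant-strain segment
  expect_error(mean_slope(make_cycle(rep(0.1, 5), 1:5)), "degenerate")
})

test_that("mean slope on a generator cycle matches the normal-equations oracle", {
  p <- exp_mech_params()
  tr <- simulate_specimen_mech(p)
  cyc <- select_steady_cycles(segment_cycles(compute_stress_strain(tr)$x,
                                             tr$protocol))
  ld <- cyc$loading[[12]]; ul <- cyc$unloading[[12]]
  oracle <- (ne_slope(ld$strain, ld$stress_MPa) +
               ne_slope(ul$strain, ul$stress_MPa)) / 2
  got <- mean_slope(list(loading = ld, unloading = ul))
  expect_lt(abs(got / oracle - 1), 1e-9)
})

test_that("tangent modulus recovers a linear material exactly and guards its window", {
  k <- 2.5
  tr <- simulate_specimen_mech(linear_mech_params(k))
  cyc <- select_steady_cycles(segment_cycles(compute_stress_strain(tr)$x,
                                             tr$protocol))
  for (lev in c(4.6, 10, 15.7, 21.6)) {
    tm <- tangent_modulus(cyc[cyc$strain_level_pct == lev, ])
    expect_equal(tm$tangent_MPa, k, tolerance = 1e-6)
  }
  expect_error(tangent_modulus(cyc[cyc$strain_level_pct == 4.6, ],
                               window_pct = 50), "window")
  tiny <- tibble::tibble(
    strain_level_pct = 10, cycle = 1,
    loading = list(list(strain = c(0, 0.05, 0.1), stress_MPa = c(0, 1, 2))),
    unloading = list(list(strain = c(0.1, 0), stress_MPa = c(2, 0)))
  )
  expect_error(tangent_modulus(tiny, window_pct = 0.001), "fewer than 2 samples")
})

test_that("anisotropy index is the longitudinal/transverse modulus ratio", {
  expect_equal(anisotropy_index(2.0, 1.0), 2.0)
  expect_equal(anisotropy_index(c(1, 3), c(1, 1.5)), c(1, 2))
  expect_error(anisotropy_index(1, 0), "positive")
})

test_that("full analysis matches the material oracle and is deterministic", {
  p <- exp_mech_params(A_x = 0.015, A_y = 0.009, B_x = 16, B_y = 14)
  tr <- simulate_specimen_mech(p)
  sm <- analyze_specimen(tr)
  m <- sm$moduli
  oracle <- mapply(function(ax, wc) {
    A <- if (ax == "x") p$A_x else p$A_y
    B <- if (ax == "x") p$B_x else p$B_y
    A * B * exp(B * wc)
  }, m$axis, m$window_center_strain)
  expect_lt(max(abs(m$tangent_modulus_MPa / oracle - 1)), 0.02)
  # strict modulus increase across levels for B > 0
  for (ax in c("x", "y")) {
    expect_true(all(diff(m$tangent_modulus_MPa[m$axis == ax]) > 0))
  }
  expect_identical(analyze_specimen(tr)$moduli, sm$moduli)
})

test_that("isotropic specimens give AI = 1 and AI ignores common force rescaling", {
  tr <- simulate_specimen_mech(exp_mech_params())
  sm <- analyze_specimen(tr)
  expect_equal(sm$ai$ai, rep(1, 4), tolerance = 1e-6)

  tr2 <- simulate_specimen_mech(exp_mech_params(A_x = 0.015, A_y = 0.009))
  ai1 <- analyze_specimen(tr2)$ai$ai
  tr2$data$force_x_N <- tr2$data$force_x_N * 3.7
  tr2$data$force_y_N <- tr2$data$force_y_N * 3.7
  ai2 <- analyze_specimen(tr2)$ai$ai
  expect_equal(ai2, ai1, tolerance = 1e-12)
})
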
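# Synthetic biaxial cyclic-loading traces with known ground truth.

# Piecewise-linear (triangle wave) strain profile through all protocol levels.
# Returns breakpoint times/strains plus per-segment level and cycle bookkeeping.
strain_breakpoints <- function(protocol) {
  rate <- protocol$strain_rate / 60  # % strain per second
  n_cyc <- protocol$cycles_per_level
  bp_t <- 0
  bp_eps <- 0
  seg_level <- numeric(0)   # protocol level (%) of each ramp segment
  seg_cycle <- integer(0)   # 1-based cycle index within its level
  seg_loading <- logical(0)
  t_cur <- 0
  for (lev in protocol$strain_levels) {
    half <- lev / rate  # seconds per ramp
    for (cyc in seq_len(n_cyc)) {
      bp_t <- c(bp_t, t_cur + half, t_cur + 2 * half)
      bp_eps <- c(bp_eps, lev, 0)
      seg_level <- c(seg_level, lev, lev)
      seg_cycle <- c(seg_cycle, cyc, cyc)
      seg_loading <- c(seg_loading, TRUE, FALSE)
      t_cur <- t_cur + 2 * half
    }
  }
  list(time = bp_t, strain = bp_eps, seg_level = seg_level,
       seg_cycle = seg_cycle, seg_loading = seg_loading, duration = t_cur)
}

# Stress (MPa) of the exponential material at strain eps (fraction).
material_stress <- function(A, B, eps) A * (exp(B * eps) - 1)

# Unloading stress at strain eps for a cycle peaking at eps_p: continuous at
# the peak, ~eta * loading stress over the body of the limb, zero at zero
# strain. Exposed for oracle computations in tests.
material_stress_unloading <- function(A, B, eps, eps_p, eta) {
  s_load <- material_stress(A, B, eps)
  s_peak <- material_stress(A, B, eps_p)
  if (s_peak <= 0) return(rep(0, length(eps)))
  eta * s_load + (1 - eta) * s_load^3 / s_peak^2
}

#' Simulate a biaxial cyclic-loading specimen trace
#'
#' Strain on both axes follows a triangle wave through `cycles_per_level`
#' cycles at each protocol strain level in order, at constant strain-rate
#' magnitude, sampled uniformly at `protocol$sample_rate`. Loading stress on
#' axis *a* is \eqn{A_a (e^{B_a \epsilon} - 1)} scaled by the preconditioning
#' factor \eqn{1 - d\,r^{c-1}} for cycle *c* within its level (`d` =
#' `precond_drop`, `r` = `precond_rate`). Unloading follows
#' \eqn{\eta \sigma_l + (1-\eta)\sigma_p(\sigma_l/\sigma_p)^3}: continuous at
#' the cycle peak stress \eqn{\sigma_p}, approximately `eta` times the
#' loading stress over the body of the limb, and zero at zero strain, closing
#' the hysteresis loop. Force is stress times the initial cross-section;
#' Gaussian noise of SD `noise_sd` (N) is then added per load-cell sample.
#'
#' @param params A [tissue_mech_params()] object.
#' @param protocol A [mech_protocol()] object.
#' @param geometry A [specimen_geometry()] object.
#' @param seed Optional integer; identical seeds give bit-identical traces.
#' @param specimen_id Identifier stored with the trace.
#' @return A `mech_trace` object: a list with `data` (tibble with columns
#'   `time_s`, `strain_x_pct`, `strain_y_pct`, `force_x_N`, `force_y_N`),
#'   `geometry`, `protocol`, `params` and `specimen_id`.
#' @export
simulate_specimen_mech <- function(params, protocol = mech_protocol(),
                                   geometry = specimen_geometry(),
                                   seed = NULL, specimen_id = "specimen") {
  stop_unless(inherits(params, "tissue_mech_params"), "`params` must be tissue_mech_params")
  stop_unless(inherits(protocol, "mech_protocol"), "`protocol` must be mech_protocol")
  stop_unless(inherits(geometry, "specimen_geometry"), "`geometry` must be specimen_geometry")

  bp <- strain_breakpoints(protocol)
  tt <- seq(0, bp$duration, by = 1 / protocol$sample_rate)
  eps_pct <- stats::approx(bp$time, bp$strain, xout = tt, rule = 2)$y
  # Segment membership of each sample (segment i spans bp$time[i]..bp$time[i+1]).
  seg <- findInterval(tt, bp$time, rightmost.closed = TRUE, left.open = TRUE)
  seg[seg < 1] <- 1L
  cyc <- bp$seg_cycle[seg]
  loading <- bp$seg_loading[seg]

  pc <- 1 - params$precond_drop * params$precond_rate^(cyc - 1)
  eps <- eps_pct / 100
  area_x <- geometry$thickness * geometry$width_x  # mm^2; MPa * mm^2 = N
  area_y <- geometry$thickness * geometry$width_y
  # Unloading is continuous at the cycle peak (stress equals the loading
  # stress there) and decays to eta times the loading curve away from it,
  # closing the hysteresis loop at zero stress / zero strain:
  #   sigma_unl = eta sigma_l + (1 - eta) sigma_p (sigma_l / sigma_p)^3.
  axis_force <- function(A, B, area) {
    s_load <- material_stress(A, B, eps)
    s_peak <- material_stress(A, B, bp$seg_level[seg] / 100)
    s_unl <- params$eta * s_load +
      ifelse(s_peak > 0, (1 - params$eta) * s_load^3 / s_peak^2, 0)
    ifelse(loading, s_load, s_unl) * pc * area
  }
  force_x <- axis_force(params$A_x, params$B_x, area_x)
  force_y <- axis_force(params$A_y, params$B_y, area_y)

  if (params$noise_sd > 0) {
    noise <- with_optional_seed(seed, matrix(stats::rnorm(2 * length(tt), 0, params$noise_sd), ncol = 2))
    force_x <- force_x + noise[, 1]
    force_y <- force_y + noise[, 2]
  }

  structure(
    list(
      data = tibble::tibble(time_s = tt,
                            strain_x_pct = eps_pct, strain_y_pct = eps_pct,
                            force_x_N = force_x, force_y_N = force_y),
      geometry = geometry, protocol = protocol, params = params,
      specimen_id = specimen_id
    ),
    class = "mech_trace"
  )
}

#' @export
print.mech_trace <- function(x, ...) {
  cat(sprintf("<mech_trace> '%s': %d samples over %.1f s, levels %s %%\n",
              x$specimen_id, nrow(x$data), max(x$data$time_s),
              paste(x$protocol$strain_levels, collapse = "/")))
  invisible(x)
}

#' Closed-form tangent modulus of the generator material
#'
#' Steady-state material tangent \eqn{d\sigma/d\epsilon = A_a B_a
#' e^{B_a \epsilon}} evaluated at `strain_level` (no preconditioning factor).
#' Serves as the analytic oracle for estimator validation.
#'
#' @param params A [tissue_mech_params()] object.
#' @param axis `"x"` (longitudinal) or `"y"` (transverse).
#' @param strain_level Strain in %, converted to a fraction internally.
#' @return Tangent modulus in MPa.
#' @export
true_tangent_modulus <- function(params, axis, strain_level) {
  stop_unless(inherits(params, "tissue_mech_params"), "`params` must be tissue_mech_params")
  if (!(is.character(axis) && length(axis) == 1L && axis %in% c("x", "y"))) {
    stop("`axis` must be \"x\" or \"y\"", call. = FALSE)
  }
  A <- if (axis == "x") params$A_x else params$A_y
  B <- if (axis == "x") params$B_x else params$B_y
  A * B * exp(B * strain_level / 100)
}

#' Exact least-squares slope of the material curve over a strain window
#'
#' Closed-form continuous least-squares slope of
#' \eqn{\sigma = A (e^{B\epsilon} - 1)} over the window
#' \eqn{[\epsilon_p - w, \epsilon_p]}: with half-width \eqn{a = w/2},
#' midpoint \eqn{m = \epsilon_p - a} and \eqn{h = Ba}, the slope is
#' \eqn{A e^{Bm} \frac{3}{B a^2}(\cosh h - \sinh h / h)}, reducing to
#' \eqn{A B e^{Bm}} as \eqn{w \to 0}. This is the estimand of the
#' window-slope tangent-modulus estimator on noise-free data.
#'
#' @inheritParams true_tangent_modulus
#' @param window_pct Width of the terminal strain window in % strain
#'   (default 1).
#' @return Slope in MPa.
#' @export
true_window_slope <- function(params, axis, strain_level, window_pct = 1) {
  stop_unless(is_scalar_num(window_pct) && window_pct > 0, "`window_pct` must be > 0")
  A <- if (axis == "x") params$A_x else if (axis == "y") params$A_y else
    stop("`axis` must be \"x\" or \"y\"", call. = FALSE)
  B <- if (axis == "x") params$B_x else params$B_y
  if (B == 0) return(0)
  a <- window_pct / 100 / 2
  m <- strain_level / 100 - a
  h <- B * a
  A * exp(B * m) * 3 / (B * a^2) * (cosh(h) - sinh(h) / h)
}
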
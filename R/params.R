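# Parameter objects for the synthetic cohort generator and testing protocol.

#' Material parameters for the synthetic biaxial specimen
#'
#' The generator uses an exponential constitutive law per axis,
#' \eqn{\sigma_a(\epsilon) = A_a (e^{B_a \epsilon} - 1)} with strain
#' \eqn{\epsilon} as a fraction, which produces the toe region followed by a
#' quasi-linear high-strain region characteristic of soft connective tissue,
#' and has a closed-form tangent \eqn{A_a B_a e^{B_a \epsilon}}. Hysteresis is
#' modelled by an unloading path that is continuous at the cycle peak and
#' decays toward `eta` times the loading stress (see
#' [simulate_specimen_mech()]); cyclic preconditioning by a geometric decay of
#' a peak-stress deficit across cycles within a strain level.
#'
#' @param A_x,A_y Stress scale per axis (MPa); x is the longitudinal tissue
#'   axis, y the transverse axis. Must be positive.
#' @param B_x,B_y Dimensionless exponential stiffening exponent per axis
#'   (strain as a fraction). Non-negative; `B = 0` gives identically zero
#'   stress.
#' @param eta Unloading-to-loading stress ratio in (0, 1]; 1 means no
#'   hysteresis.
#' @param precond_drop Fractional peak-stress deficit of cycle 1 relative to
#'   the steady state, in [0, 1).
#' @param precond_rate Per-cycle geometric decay of the preconditioning
#'   transient, in (0, 1). The default (0.5) makes cycles 8-10 agree to well
#'   under 1%.
#' @param noise_sd Additive Gaussian force noise (N) applied to both load
#'   cells. The default (0.01 N) corresponds to 0.2% of a 5 N load cell's full
#'   scale.
#' @return An object of class `tissue_mech_params`.
#' @seealso [simulate_specimen_mech()], [true_tangent_modulus()]
#' @export
tissue_mech_params <- function(A_x = 0.012, A_y = 0.012,
                               B_x = 16, B_y = 16,
                               eta = 0.8,
                               precond_drop = 0.15, precond_rate = 0.5,
                               noise_sd = 0.01) {
  stop_unless(is_scalar_num(A_x) && A_x > 0, "`A_x` must be a positive number")
  stop_unless(is_scalar_num(A_y) && A_y > 0, "`A_y` must be a positive number")
  stop_unless(is_scalar_num(B_x) && B_x >= 0, "`B_x` must be >= 0")
  stop_unless(is_scalar_num(B_y) && B_y >= 0, "`B_y` must be >= 0")
  stop_unless(is_scalar_num(eta) && eta > 0 && eta <= 1,
              "`eta` must lie in (0, 1]")
  stop_unless(is_scalar_num(precond_drop) && precond_drop >= 0 && precond_drop < 1,
              "`precond_drop` must lie in [0, 1)")
  stop_unless(is_scalar_num(precond_rate) && precond_rate > 0 && precond_rate < 1,
              "`precond_rate` must lie in (0, 1)")
  stop_unless(is_scalar_num(noise_sd) && noise_sd >= 0, "`noise_sd` must be >= 0")
  structure(
    list(A_x = A_x, A_y = A_y, B_x = B_x, B_y = B_y, eta = eta,
         precond_drop = precond_drop, precond_rate = precond_rate,
         noise_sd = noise_sd),
    class = "tissue_mech_params"
  )
}

#' Cyclic biaxial loading protocol
#'
#' Defaults follow the equibiaxial protocol used for rat vaginal wall testing:
#' cyclic loading to 4.6, 10, 15.7 and 21.6% strain, ten cycles per level at
#' 100% strain/min, sampled at 30 Hz after a 0.1 N preload.
#'
#' @param strain_levels Ordered vector of peak strains (%), strictly
#'   increasing and positive.
#' @param cycles_per_level Cycles per strain level (>= 3).
#' @param strain_rate Constant strain rate magnitude (% strain per minute).
#' @param sample_rate Sampling frequency (Hz).
#' @param preload Preload force (N); recorded for provenance, the simulated
#'   traces start from the preloaded reference state at zero strain.
#' @return An object of class `mech_protocol`.
#' @export
mech_protocol <- function(strain_levels = c(4.6, 10, 15.7, 21.6),
                          cycles_per_level = 10,
                          strain_rate = 100,
                          sample_rate = 30,
                          preload = 0.1) {
  stop_unless(is.numeric(strain_levels) && length(strain_levels) >= 1 &&
                all(strain_levels > 0) && !is.unsorted(strain_levels, strictly = TRUE),
              "`strain_levels` must be positive and strictly increasing")
  stop_unless(is_scalar_num(cycles_per_level) && cycles_per_level >= 3,
              "`cycles_per_level` must be >= 3")
  stop_unless(is_scalar_num(strain_rate) && strain_rate > 0,
              "`strain_rate` must be > 0")
  stop_unless(is_scalar_num(sample_rate) && sample_rate > 0,
              "`sample_rate` must be > 0")
  stop_unless(is_scalar_num(preload) && preload >= 0, "`preload` must be >= 0")
  structure(
    list(strain_levels = as.numeric(strain_levels),
         cycles_per_level = as.integer(cycles_per_level),
         strain_rate = strain_rate, sample_rate = sample_rate,
         preload = preload),
    class = "mech_protocol"
  )
}

#' Specimen geometry for stress normalization
#'
#' Nominal (first Piola-Kirchhoff) stress is computed from the initial
#' cross-section `thickness * width` of each loading direction. The default
#' 10 x 10 mm square follows the cutting-block specimen preparation; thickness
#' is measured per specimen.
#'
#' @param thickness Tissue thickness (mm).
#' @param width_x,width_y Effective loaded width perpendicular to each axis
#'   (mm).
#' @param gauge_length Rake-to-rake gauge length (mm), used only for
#'   provenance.
#' @return An object of class `specimen_geometry`.
#' @export
specimen_geometry <- function(thickness = 0.9, width_x = 10, width_y = 10,
                              gauge_length = 10) {
  for (nm in c("thickness", "width_x", "width_y", "gauge_length")) {
    v <- get(nm)
    stop_unless(is_scalar_num(v) && v > 0,
                sprintf("`%s` must be a positive number", nm))
  }
  structure(
    list(thickness = thickness, width_x = width_x, width_y = width_y,
         gauge_length = gauge_length),
    class = "specimen_geometry"
  )
}

#' Electrophysiology generator parameters
#'
#' Governs Poisson spike trains (with a 1 ms refractory period) riding on
#' band-limited Gaussian noise, and the bladder-pressure ramp to a leak point.
#' Rates are the Poisson intensities before refractory thinning; amplitudes
#' are peak-to-peak values of the biphasic 2 ms spike template.
#'
#' @param rate_baseline,rate_stim Mean firing rate (Hz) at baseline and during
#'   stimulation (peak pressure for EUS EMG, genital brushing for pudendal
#'   ENG).
#' @param amp_mean,amp_sd Spike peak-to-peak amplitude mean and between-spike
#'   SD (uV).
#' @param noise_sd Baseline noise SD (uV) after band-limiting.
#' @param p_baseline,p_leak Baseline bladder pressure and pressure at the leak
#'   point (cm H2O); `p_leak` must exceed `p_baseline`.
#' @param n_lpp_trials Leak-point-pressure trials per animal (3-6).
#' @param n_eng_trials ENG trials per animal (5-10).
#' @return An object of class `ephys_params`.
#' @export
ephys_params <- function(rate_baseline = 10, rate_stim = 40,
                         amp_mean = 150, amp_sd = 15,
                         noise_sd = 8,
                         p_baseline = 8, p_leak = 42,
                         n_lpp_trials = 4, n_eng_trials = 6) {
  stop_unless(is_scalar_num(rate_baseline) && rate_baseline >= 0,
              "`rate_baseline` must be >= 0")
  stop_unless(is_scalar_num(rate_stim) && rate_stim >= 0,
              "`rate_stim` must be >= 0")
  stop_unless(is_scalar_num(amp_mean) && amp_mean > 0, "`amp_mean` must be > 0")
  stop_unless(is_scalar_num(amp_sd) && amp_sd >= 0, "`amp_sd` must be >= 0")
  stop_unless(is_scalar_num(noise_sd) && noise_sd >= 0, "`noise_sd` must be >= 0")
  stop_unless(is_scalar_num(p_baseline) && is_scalar_num(p_leak) &&
                p_leak > p_baseline,
              "`p_leak` must exceed `p_baseline`")
  stop_unless(is_scalar_num(n_lpp_trials) && n_lpp_trials >= 3 && n_lpp_trials <= 6,
              "`n_lpp_trials` must lie in 3..6")
  stop_unless(is_scalar_num(n_eng_trials) && n_eng_trials >= 5 && n_eng_trials <= 10,
              "`n_eng_trials` must lie in 5..10")
  structure(
    list(rate_baseline = rate_baseline, rate_stim = rate_stim,
         amp_mean = amp_mean, amp_sd = amp_sd, noise_sd = noise_sd,
         p_baseline = p_baseline, p_leak = p_leak,
         n_lpp_trials = as.integer(n_lpp_trials),
         n_eng_trials = as.integer(n_eng_trials)),
    class = "ephys_params"
  )
}

#' Default group effect presets for the four-arm injury/treatment design
#'
#' Multiplicative factors applied to (`A_x`, `A_y`, `rate_stim`, `p_leak`)
#' per group. The defaults emulate the qualitative study pattern: simulated
#' childbirth injury (pudendal nerve crush + vaginal distension, PNC+VD)
#' lowers stiffness by 30% on both axes and depresses urethral/pudendal
#' function; mesenchymal stem cells (MSC) restore stiffness on both axes but
#' not function; the heparan-sulfate mimetic (RGTA) restores longitudinal
#' stiffness only, raising the anisotropy index to about 1/0.7.
#'
#' @return Named list of numeric factor vectors, one per group.
#' @export
default_group_effects <- function() {
  list(
    sham_veh   = c(A_x = 1.0, A_y = 1.0, rate_stim = 1.00, p_leak = 1.00),
    pncvd_veh  = c(A_x = 0.7, A_y = 0.7, rate_stim = 0.60, p_leak = 0.70),
    pncvd_msc  = c(A_x = 1.0, A_y = 1.0, rate_stim = 0.65, p_leak = 0.75),
    pncvd_rgta = c(A_x = 1.0, A_y = 0.7, rate_stim = 0.60, p_leak = 0.70)
  )
}

#' Cohort configuration for the synthetic study
#'
#' @param groups Character vector of group labels.
#' @param n_per_group Named integer vector, animals per group. The default
#'   (12/7/9/7) matches the biomechanics arm sizes of the four-group design.
#' @param group_effects Named list mapping each group label to multiplicative
#'   factors on `A_x`, `A_y`, `rate_stim` and `p_leak`
#'   (see [default_group_effects()]).
#' @param base_mech,base_ephys Baseline (sham) parameter objects that group
#'   factors and between-animal variability modify.
#' @param between_animal_cv Between-animal coefficient of variation applied as
#'   independent log-normal multipliers (mean 1) to `A_x`, `A_y`, `rate_stim`
#'   and `p_leak`.
#' @param seed Integer seed making the whole cohort reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(groups = names(default_group_effects()),
                          n_per_group = c(sham_veh = 12, pncvd_veh = 7,
                                          pncvd_msc = 9, pncvd_rgta = 7),
                          group_effects = default_group_effects(),
                          base_mech = tissue_mech_params(),
                          base_ephys = ephys_params(),
                          between_animal_cv = 0.10,
                          seed = 1L) {
  stop_unless(is.character(groups) && length(groups) >= 1 && !anyDuplicated(groups),
              "`groups` must be unique labels")
  stop_unless(all(groups %in% names(n_per_group)),
              "`n_per_group` must name every group")
  stop_unless(all(n_per_group[groups] >= 1), "each group needs >= 1 animal")
  missing_fx <- setdiff(groups, names(group_effects))
  if (length(missing_fx) > 0) {
    stop("no group effects defined for: ", paste(missing_fx, collapse = ", "),
         call. = FALSE)
  }
  for (g in groups) {
    fx <- group_effects[[g]]
    stop_unless(is.numeric(fx) &&
                  all(c("A_x", "A_y", "rate_stim", "p_leak") %in% names(fx)) &&
                  all(fx > 0),
                sprintf("effects for group '%s' must be positive factors on A_x, A_y, rate_stim, p_leak", g))
  }
  stop_unless(inherits(base_mech, "tissue_mech_params"),
              "`base_mech` must be a tissue_mech_params object")
  stop_unless(inherits(base_ephys, "ephys_params"),
              "`base_ephys` must be an ephys_params object")
  stop_unless(is_scalar_num(between_animal_cv) && between_animal_cv >= 0,
              "`between_animal_cv` must be >= 0")
  stop_unless(is_scalar_num(seed), "`seed` must be a number")
  structure(
    list(groups = groups, n_per_group = n_per_group[groups],
         group_effects = group_effects[groups],
         base_mech = base_mech, base_ephys = base_ephys,
         between_animal_cv = between_animal_cv, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.tissue_mech_params <- function(x, ...) {
  cat("<tissue_mech_params>\n")
  cat(sprintf("  sigma_a(eps) = A_a (exp(B_a eps) - 1); A = (%.4g, %.4g) MPa, B = (%.3g, %.3g)\n",
              x$A_x, x$A_y, x$B_x, x$B_y))
  cat(sprintf("  eta = %.3g, preconditioning drop %.3g (rate %.3g), force noise sd %.3g N\n",
              x$eta, x$precond_drop, x$precond_rate, x$noise_sd))
  invisible(x)
}

#' @export
print.mech_protocol <- function(x, ...) {
  cat("<mech_protocol>\n")
  cat(sprintf("  levels: %s %% strain, %d cycles each\n",
              paste(x$strain_levels, collapse = ", "), x$cycles_per_level))
  cat(sprintf("  strain rate %g %%/min, sampled at %g Hz, preload %g N\n",
              x$strain_rate, x$sample_rate, x$preload))
  invisible(x)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", x$groups, x$n_per_group), collapse = ", ")))
  cat(sprintf("  between-animal CV %.3g, seed %d\n", x$between_animal_cv, x$seed))
  invisible(x)
}
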
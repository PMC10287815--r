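# Four-group synthetic cohort with per-animal ground truth.

lognormal_multiplier <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a full study cohort with known ground truth
#'
#' Draws per-animal parameters by applying the group's multiplicative factors
#' and independent log-normal between-animal multipliers (mean 1, CV
#' `between_animal_cv`) to the base parameters, then simulates the requested
#' raw records. Everything is recorded in the returned truth tables, and the
#' whole cohort is reproducible from `config$seed`.
#'
#' @param config A [cohort_config()] object.
#' @param include Which raw records to simulate per animal: any of `"mech"`
#'   and `"ephys"`. Restricting to `"mech"` keeps replicated biomechanics
#'   simulations fast.
#' @param protocol,geometry Protocol and geometry shared by all specimens.
#' @return A `cohort` object: list with `animals` (each with `animal_id`,
#'   `group`, and the simulated `mech` trace / `lpp_trials` / `eng_trials`),
#'   and `truth` holding `params` (one row per animal: realized material and
#'   ephys parameters plus `lpp_true` and `d_rate_true`) and `mech_targets`
#'   (per animal x axis x strain level: pointwise tangent `tangent_true_MPa`
#'   and the window-slope estimand `tangent_target_MPa`, plus `ai_true`).
#' @export
simulate_cohort <- function(config = cohort_config(),
                            include = c("mech", "ephys"),
                            protocol = mech_protocol(),
                            geometry = specimen_geometry()) {
  stop_unless(inherits(config, "cohort_config"), "`config` must be a cohort_config")
  include <- match.arg(include, c("mech", "ephys"), several.ok = TRUE)

  withr::with_seed(config$seed, {
    animals <- list()
    truth_rows <- list()
    target_rows <- list()
    aid <- 0L
    for (g in config$groups) {
      fx <- config$group_effects[[g]]
      for (i in seq_len(config$n_per_group[[g]])) {
        aid <- aid + 1L
        id <- sprintf("%s_%02d", g, i)
        mult <- lognormal_multiplier(4, config$between_animal_cv)
        bm <- config$base_mech
        be <- config$base_ephys
        pm <- tissue_mech_params(
          A_x = bm$A_x * fx[["A_x"]] * mult[1],
          A_y = bm$A_y * fx[["A_y"]] * mult[2],
          B_x = bm$B_x, B_y = bm$B_y, eta = bm$eta,
          precond_drop = bm$precond_drop, precond_rate = bm$precond_rate,
          noise_sd = bm$noise_sd
        )
        pe <- ephys_params(
          rate_baseline = be$rate_baseline,
          rate_stim = be$rate_stim * fx[["rate_stim"]] * mult[3],
          amp_mean = be$amp_mean, amp_sd = be$amp_sd, noise_sd = be$noise_sd,
          p_baseline = be$p_baseline,
          p_leak = max(be$p_leak * fx[["p_leak"]] * mult[4],
                       be$p_baseline + 1),
          n_lpp_trials = be$n_lpp_trials, n_eng_trials = be$n_eng_trials
        )

        animal <- list(animal_id = id, group = g, mech_params = pm,
                       ephys_params = pe)
        if ("mech" %in% include) {
          animal$mech <- simulate_specimen_mech(pm, protocol, geometry,
                                                specimen_id = id)
        }
        if ("ephys" %in% include) {
          animal$lpp_trials <- lapply(seq_len(pe$n_lpp_trials),
                                      function(k) simulate_lpp_trial(pe))
          animal$eng_trials <- lapply(seq_len(pe$n_eng_trials),
                                      function(k) simulate_eng_trial(pe))
        }
        animals[[id]] <- animal

        truth_rows[[id]] <- tibble::tibble(
          animal_id = id, group = g,
          A_x = pm$A_x, A_y = pm$A_y, B_x = pm$B_x, B_y = pm$B_y,
          eta = pm$eta,
          rate_baseline = pe$rate_baseline, rate_stim = pe$rate_stim,
          p_baseline = pe$p_baseline, p_leak = pe$p_leak,
          lpp_true = pe$p_leak - pe$p_baseline,
          d_rate_true = pe$rate_stim - pe$rate_baseline
        )
        target_rows[[id]] <- tidyr::expand_grid(
          animal_id = id, group = g,
          axis = c("x", "y"),
          strain_level_pct = protocol$strain_levels
        ) |>
          dplyr::mutate(
            tangent_true_MPa = mapply(function(ax, lv) true_tangent_modulus(pm, ax, lv),
                                      .data$axis, .data$strain_level_pct),
            tangent_target_MPa = mapply(function(ax, lv) true_window_slope(pm, ax, lv),
                                        .data$axis, .data$strain_level_pct),
            ai_true = true_tangent_modulus(pm, "x", .data$strain_level_pct) /
              true_tangent_modulus(pm, "y", .data$strain_level_pct)
          )
      }
    }
    structure(
      list(animals = animals,
           truth = list(params = dplyr::bind_rows(truth_rows),
                        mech_targets = dplyr::bind_rows(target_rows)),
           config = config, protocol = protocol, geometry = geometry,
           include = include),
      class = "cohort"
    )
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d animals (%s), records: %s\n",
              length(x$animals),
              paste(sprintf("%s n=%d", x$config$groups, x$config$n_per_group),
                    collapse = ", "),
              paste(x$include, collapse = " + ")))
  invisible(x)
}
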
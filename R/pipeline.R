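# End-to-end composition: simulate -> analyze -> statistics -> report.

#' Analyze every record of a cohort
#'
#' Runs the biomechanics chain over each animal's biaxial trace and the
#' electrophysiology chain over each animal's trials, returning tidy tables
#' ready for the statistical layer.
#'
#' @param cohort A `cohort` from [simulate_cohort()] (or an equivalent list
#'   of animals read from disk).
#' @param k_last,window_pct Biomechanics options (see [analyze_specimen()]).
#' @param threshold_sd Spike-detection threshold (noise SDs).
#' @return A list with `moduli` (per animal x axis x level), `ai` (per
#'   animal x level) and `outcomes` (one row per animal with functional
#'   metrics; `NULL` when the cohort holds no ephys records).
#' @export
analyze_cohort <- function(cohort, k_last = 3, window_pct = 1,
                           threshold_sd = 4) {
  moduli <- list(); ai <- list(); outcomes <- list()
  for (animal in cohort$animals) {
    if (!is.null(animal$mech)) {
      sm <- analyze_specimen(animal$mech, k_last = k_last,
                             window_pct = window_pct)
      moduli[[animal$animal_id]] <- dplyr::mutate(sm$moduli,
                                                  group = animal$group,
                                                  .after = "specimen_id")
      ai[[animal$animal_id]] <- dplyr::mutate(sm$ai, group = animal$group,
                                              .after = "specimen_id")
    }
    if (!is.null(animal$lpp_trials) || !is.null(animal$eng_trials)) {
      lt <- lapply(animal$lpp_trials %||% list(), analyze_lpp_trial,
                   threshold_sd = threshold_sd)
      et <- lapply(animal$eng_trials %||% list(), analyze_eng_trial,
                   threshold_sd = threshold_sd)
      outcomes[[animal$animal_id]] <- animal_outcome(animal$animal_id,
                                                     animal$group, lt, et)
    }
  }
  list(
    moduli = if (length(moduli) > 0) dplyr::bind_rows(moduli),
    ai = if (length(ai) > 0) dplyr::bind_rows(ai),
    outcomes = if (length(outcomes) > 0) dplyr::bind_rows(outcomes)
  )
}

#' Run the full study pipeline on a synthetic cohort
#'
#' Simulates a cohort, analyzes every record, and applies the study's
#' statistical layer: Kruskal-Wallis + Dunn for each functional metric,
#' two-way repeated-measures ANOVA with Bonferroni contrasts for the tangent
#' moduli of each axis, and the mixed model for the anisotropy index.
#'
#' @param config A [cohort_config()].
#' @param include Records to simulate (`"mech"`, `"ephys"`).
#' @param k_last,window_pct,threshold_sd Analysis options.
#' @param contrasts Pass `FALSE` to skip post hoc contrasts.
#' @return A list with `analysis` (tidy tables), `summaries`, `mech_stats`
#'   (per axis), `ai_stats`, `functional_stats` (per metric) and
#'   `provenance`.
#' @export
run_study_pipeline <- function(config = cohort_config(),
                               include = c("mech", "ephys"),
                               k_last = 3, window_pct = 1, threshold_sd = 4,
                               contrasts = TRUE) {
  cohort <- simulate_cohort(config, include = include)
  analysis <- analyze_cohort(cohort, k_last = k_last, window_pct = window_pct,
                             threshold_sd = threshold_sd)

  summaries <- list()
  mech_stats <- NULL
  ai_stats <- NULL
  functional_stats <- NULL

  if (!is.null(analysis$moduli)) {
    mech_stats <- lapply(c(x = "x", y = "y"), function(ax) {
      d <- analysis$moduli[analysis$moduli$axis == ax, ]
      d$animal_id <- d$specimen_id
      rm_anova_bonferroni(d, metric = "tangent_modulus_MPa",
                          contrasts = contrasts)
    })
    top <- max(analysis$moduli$strain_level_pct)
    for (ax in c("x", "y")) {
      d <- analysis$moduli[analysis$moduli$axis == ax &
                             analysis$moduli$strain_level_pct == top, ]
      summaries[[paste0("tangent_", ax, "_at_", top)]] <-
        summarize_groups(d, "tangent_modulus_MPa")
    }
    ai_stats <- mixed_model_ai(
      dplyr::rename(analysis$ai, ai = "ai"), contrasts = contrasts
    )
  }
  if (!is.null(analysis$outcomes)) {
    metrics <- c("lpp_cmH2O", "d_emg_rate_Hz", "d_emg_amp_uV",
                 "d_eng_rate_Hz", "d_eng_amp_uV")
    functional_stats <- lapply(stats::setNames(metrics, metrics), function(m) {
      kruskal_dunn(analysis$outcomes, m)
    })
    for (m in metrics) {
      summaries[[m]] <- summarize_groups(analysis$outcomes, m)
    }
  }

  list(
    analysis = analysis,
    truth = cohort$truth,
    summaries = summaries,
    mech_stats = mech_stats,
    ai_stats = ai_stats,
    functional_stats = functional_stats,
    provenance = list(
      seed = config$seed,
      options = list(k_last = k_last, window_pct = window_pct,
                     threshold_sd = threshold_sd),
      package_version = as.character(utils::packageVersion("pelvimech"))
    )
  )
}
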
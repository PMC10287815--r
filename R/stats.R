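# Group-level statistics: descriptive summaries, Kruskal-Wallis + Dunn,
# two-way repeated-measures ANOVA, mixed model for the anisotropy index,
# and the t-test based sample-size calculation.

#' Group summaries (mean +/- SEM)
#'
#' @param data Tidy tibble of per-animal outcomes.
#' @param metric Column name of the outcome to summarize.
#' @param group Grouping column name (default `"group"`).
#' @return Tibble with `group`, `n` (non-missing), `mean` and `sem`
#'   (`sd/sqrt(n)`; `NA` when n < 2).
#' @export
summarize_groups <- function(data, metric, group = "group") {
  stop_unless(metric %in% names(data), sprintf("no column '%s' in data", metric))
  stop_unless(group %in% names(data), sprintf("no column '%s' in data", group))
  out <- data |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(
      n = sum(!is.na(.data[[metric]])),
      mean = mean(.data[[metric]], na.rm = TRUE),
      sem = stats::sd(.data[[metric]], na.rm = TRUE) / sqrt(.data$n),
      .groups = "drop"
    )
  if (any(out$n == 0)) {
    stop("group(s) with no non-missing values: ",
         paste(out$group[out$n == 0], collapse = ", "), call. = FALSE)
  }
  out$metric <- metric
  dplyr::relocate(out, "metric")
}

new_stat_result <- function(test, omnibus, pairwise, alpha = 0.05,
                            notes = character(0)) {
  structure(list(test = test, omnibus = omnibus, pairwise = pairwise,
                 alpha = alpha, notes = notes),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s\n", x$test))
  om <- x$omnibus
  cat(sprintf("  omnibus: %s\n",
              paste(sprintf("%s = %.4g", names(om), unlist(om)), collapse = ", ")))
  if (!is.null(x$pairwise) && nrow(x$pairwise) > 0) {
    cat(sprintf("  %d pairwise comparison(s), adjustment: %s\n",
                nrow(x$pairwise), x$pairwise$adjust_method[1]))
  }
  for (nt in x$notes) cat("  note: ", nt, "\n", sep = "")
  invisible(x)
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis rank test across groups followed by Dunn's
#' pairwise z-tests on mean ranks over all group pairs, with multiplicity
#' adjustment (default Bonferroni). If every observation is identical the
#' omnibus statistic is 0 with p = 1 and no comparisons are attempted.
#'
#' @param data Tidy tibble of per-animal outcomes.
#' @param metric Outcome column name.
#' @param group Grouping column name.
#' @param adjust Dunn adjustment: `"bonferroni"`, `"holm"` or `"none"`.
#' @param alpha Significance level recorded with the result.
#' @return A `stat_result` with the omnibus H statistic/p-value and a
#'   pairwise tibble (`pair`, `z`, `p_raw`, `p_adj`, `adjust_method`).
#' @export
kruskal_dunn <- function(data, metric, group = "group",
                         adjust = c("bonferroni", "holm", "none"),
                         alpha = 0.05) {
  adjust <- match.arg(adjust)
  stop_unless(metric %in% names(data), sprintf("no column '%s' in data", metric))
  d <- data[!is.na(data[[metric]]), c(group, metric)]
  names(d) <- c("group", "y")
  d$group <- factor(d$group)
  stop_unless(nlevels(d$group) >= 2, "need at least two groups")

  if (stats::var(d$y) == 0 || length(unique(d$y)) == 1) {
    return(new_stat_result(
      "Kruskal-Wallis + Dunn",
      list(H = 0, df = nlevels(d$group) - 1, p = 1),
      tibble::tibble(pair = character(0), z = numeric(0), p_raw = numeric(0),
                     p_adj = numeric(0), adjust_method = character(0)),
      alpha = alpha, notes = "all values identical; rank test degenerate"
    ))
  }

  kw <- stats::kruskal.test(y ~ group, data = d)

  # Dunn's test: z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))
  # with tie correction T = sum(t^3 - t) / (12 (N - 1)).
  N <- nrow(d)
  r <- rank(d$y)
  rbar <- tapply(r, d$group, mean)
  ns <- tapply(r, d$group, length)
  ties <- table(d$y)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(d$group)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  pw <- lapply(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    tibble::tibble(pair = paste(pr, collapse = " - "), z = z,
                   p_raw = 2 * stats::pnorm(-abs(z)))
  })
  pw <- dplyr::bind_rows(pw)
  pw$p_adj <- stats::p.adjust(pw$p_raw, method = adjust)
  pw$adjust_method <- adjust

  new_stat_result("Kruskal-Wallis + Dunn",
                  list(H = unname(kw$statistic), df = unname(kw$parameter),
                       p = kw$p.value),
                  pw, alpha = alpha)
}

#' Two-way repeated-measures ANOVA with Bonferroni-adjusted group contrasts
#'
#' Split-plot ANOVA of a modulus measured at every protocol strain level on
#' every animal: group as the between-animal factor, strain level as the
#' repeated (within-animal) factor, with the animal as the error stratum.
#' Animals missing any level are excluded with a warning. Pairwise group
#' contrasts are tested within each strain level and Bonferroni-adjusted
#' over the whole family.
#'
#' @param data Tidy tibble with columns `animal_id`, `group`,
#'   `strain_level_pct` and the `value` column named by `metric`.
#' @param metric Value column name (default `"tangent_modulus_MPa"`).
#' @param contrasts Set `FALSE` to skip the post hoc contrasts (omnibus
#'   only), e.g. in calibration simulations.
#' @param alpha Significance level recorded with the result.
#' @return A `stat_result`; omnibus holds F and p for the group, level and
#'   interaction effects.
#' @export
rm_anova_bonferroni <- function(data, metric = "tangent_modulus_MPa",
                                contrasts = TRUE, alpha = 0.05) {
  needed <- c("animal_id", "group", "strain_level_pct", metric)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- data[, needed]
  names(d) <- c("animal_id", "group", "level", "y")
  d <- d[!is.na(d$y), ]
  n_levels <- length(unique(d$level))
  complete <- d |>
    dplyr::count(.data$animal_id) |>
    dplyr::filter(.data$n == n_levels)
  dropped <- setdiff(unique(d$animal_id), complete$animal_id)
  if (length(dropped) > 0) {
    warning("excluding animal(s) missing a strain level: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    d <- d[d$animal_id %in% complete$animal_id, ]
  }
  d$animal_id <- factor(d$animal_id)
  d$group <- factor(d$group)
  d$level <- factor(d$level)

  if (stats::var(d$y) == 0) {
    return(new_stat_result(
      "Two-way RM ANOVA + Bonferroni",
      list(F_group = 0, p_group = 1, F_level = 0, p_level = 1,
           F_interaction = 0, p_interaction = 1),
      NULL, alpha = alpha, notes = "zero variance; all effects null"
    ))
  }

  fit <- stats::aov(y ~ group * level + Error(animal_id), data = d)
  # embed the data so emmeans can re-evaluate the split-plot call later
  attr(fit, "call")$data <- d
  sm <- summary(fit)
  between <- sm[["Error: animal_id"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  pick <- function(tab, term, col) {
    i <- trimws(rownames(tab)) == term
    if (!any(i)) NA_real_ else tab[i, col]
  }
  omnibus <- list(
    F_group = pick(between, "group", "F value"),
    p_group = pick(between, "group", "Pr(>F)"),
    F_level = pick(within, "level", "F value"),
    p_level = pick(within, "level", "Pr(>F)"),
    F_interaction = pick(within, "group:level", "F value"),
    p_interaction = pick(within, "group:level", "Pr(>F)")
  )

  pw <- NULL
  if (isTRUE(contrasts)) {
    em <- emmeans::emmeans(fit, ~ group | level, data = d)
    pw <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise",
                                                  adjust = "none")))
    pw <- tibble::tibble(
      pair = as.character(pw$contrast),
      strain_level_pct = as.numeric(as.character(pw$level)),
      estimate = pw$estimate, p_raw = pw$p.value
    )
    pw$p_adj <- pmin(1, pw$p_raw * nrow(pw))  # Bonferroni over the family
    pw$adjust_method <- "bonferroni"
  }
  new_stat_result("Two-way RM ANOVA + Bonferroni", omnibus, pw, alpha = alpha)
}

#' Mixed-model analysis of the anisotropy index
#'
#' Fits `ai ~ group * strain level` with a per-specimen random intercept
#' (REML, Satterthwaite degrees of freedom for contrasts). On a singular fit
#' (zero random-intercept variance) it falls back to the fixed-effects model
#' with a warning. Pairwise group contrasts are tested within each strain
#' level and Bonferroni-adjusted over the family.
#'
#' @param data Tidy tibble with columns `specimen_id`, `group`,
#'   `strain_level_pct`, `ai`.
#' @param contrasts Set `FALSE` to skip post hoc contrasts.
#' @param alpha Significance level recorded with the result.
#' @return A `stat_result`; omnibus holds Type-III-style F tests when
#'   available.
#' @export
mixed_model_ai <- function(data, contrasts = TRUE, alpha = 0.05) {
  needed <- c("specimen_id", "group", "strain_level_pct", "ai")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- data[!is.na(data$ai), needed]
  d$specimen_id <- factor(d$specimen_id)
  d$group <- factor(d$group)
  d$level <- factor(d$strain_level_pct)
  notes <- character(0)

  fit <- NULL
  if (stats::var(d$ai) > 0) {
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(ai ~ group * level + (1 | specimen_id),
                                      data = d)),
      error = function(e) NULL
    )
    if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-5)) {
      fit <- NULL
      notes <- c(notes, "singular random-intercept fit")
    }
  } else {
    notes <- c(notes, "zero variance in AI")
  }

  if (is.null(fit)) {
    warning("mixed model unavailable (", paste(notes, collapse = "; "),
            "); falling back to fixed-effects model", call. = FALSE)
    fit <- stats::lm(ai ~ group * level, data = d)
    an <- suppressWarnings(stats::anova(fit))
    omnibus <- list(
      F_group = an["group", "F value"], p_group = an["group", "Pr(>F)"],
      F_level = an["level", "F value"], p_level = an["level", "Pr(>F)"],
      F_interaction = an["group:level", "F value"],
      p_interaction = an["group:level", "Pr(>F)"]
    )
    model_label <- "fixed-effects fallback"
  } else {
    an <- stats::anova(fit)  # lmerTest: Satterthwaite F tests
    omnibus <- list(
      F_group = an["group", "F value"], p_group = an["group", "Pr(>F)"],
      F_level = an["level", "F value"], p_level = an["level", "Pr(>F)"],
      F_interaction = an["group:level", "F value"],
      p_interaction = an["group:level", "Pr(>F)"]
    )
    model_label <- "random intercept per specimen"
  }
  omnibus <- lapply(omnibus, function(v) if (is.finite(v)) v else 0)
  if (identical(omnibus$F_group, 0) && !("zero variance in AI" %in% notes)) {
    # keep honest p when F was truly computed as 0
    omnibus$p_group <- omnibus$p_group %||% 1
  }

  pw <- NULL
  if (isTRUE(contrasts)) {
    degenerate <- model_label == "fixed-effects fallback"
    maybe_quiet <- if (degenerate) suppressWarnings else identity
    em <- maybe_quiet(emmeans::emmeans(fit, ~ group | level, data = d,
                                       lmer.df = "satterthwaite"))
    pwdf <- maybe_quiet(as.data.frame(summary(
      emmeans::contrast(em, method = "pairwise", adjust = "none"))))
    pw <- tibble::tibble(
      pair = as.character(pwdf$contrast),
      strain_level_pct = as.numeric(as.character(pwdf$level)),
      estimate = pwdf$estimate, p_raw = pwdf$p.value
    )
    pw$p_adj <- pmin(1, pw$p_raw * nrow(pw))
    pw$adjust_method <- "bonferroni"
  }
  new_stat_result(paste0("Mixed model AI (", model_label, ") + Bonferroni"),
                  omnibus, pw, alpha = alpha, notes = notes)
}

#' Sample size for a relative group difference (two-sample t-test)
#'
#' Smallest per-group n such that a two-sided two-sample t-test at level
#' `alpha` detects a relative mean difference of `relative_difference`
#' (difference / control mean) with the target power, given the outcome's
#' relative SD (SD / control mean). With `relative_difference = 0.30`,
#' `alpha = 0.05`, `power = 0.90` and `relative_sd = 0.15`, the minimum is 7
#' animals per group. The assumed variance is study-specific, so
#' `relative_sd` has no default.
#'
#' @param relative_difference Relative mean difference to detect (> 0).
#' @param relative_sd Relative standard deviation (> 0). Required.
#' @param alpha Two-sided significance level.
#' @param power Target power in (0, 1).
#' @return Integer n per group (>= 2).
#' @export
sample_size <- function(relative_difference = 0.30, relative_sd,
                        alpha = 0.05, power = 0.90) {
  stop_unless(is_scalar_num(relative_difference) && relative_difference > 0,
              "`relative_difference` must be > 0")
  if (missing(relative_sd)) {
    stop("`relative_sd` is required: the assumed variance must be stated explicitly",
         call. = FALSE)
  }
  stop_unless(is_scalar_num(relative_sd) && relative_sd > 0,
              "`relative_sd` must be > 0")
  stop_unless(is_scalar_num(alpha) && alpha > 0 && alpha < 1,
              "`alpha` must lie in (0, 1)")
  stop_unless(is_scalar_num(power) && power > alpha && power < 1,
              "`power` must lie in (alpha, 1)")
  pw_at <- function(n) stats::power.t.test(n = n, delta = relative_difference,
                                           sd = relative_sd,
                                           sig.level = alpha)$power
  if (pw_at(2) >= power) return(2L)
  sol <- tryCatch(
    stats::power.t.test(delta = relative_difference, sd = relative_sd,
                        sig.level = alpha, power = power),
    error = function(e) stop("requested power unattainable: ",
                             conditionMessage(e), call. = FALSE)
  )
  n <- max(2L, as.integer(ceiling(sol$n)))
  while (n > 2L && pw_at(n - 1L) >= power) n <- n - 1L
  while (pw_at(n) < power) n <- n + 1L  # guard against ceiling under-shoot
  n
}
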
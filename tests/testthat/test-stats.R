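# Statistical layer: summaries, Kruskal-Wallis + Dunn, repeated-measures
# ANOVA, AI mixed model, and the sample-size calculation.

test_that("group summaries report mean and sd/sqrt(n)", {
  d <- tibble::tibble(group = c("a", "a", "a", "b"), y = c(1, 2, 3, 5))
  s <- summarize_groups(d, "y")
  expect_equal(s$mean[s$group == "a"], 2)
  expect_equal(s$sem[s$group == "a"], 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$n[s$group == "b"], 1)
  expect_true(is.na(s$sem[s$group == "b"]))  # undefined for a single value
  d2 <- tibble::tibble(group = c("a", "b"), y = c(1, NA))
  expect_error(summarize_groups(d2, "y"), "no non-missing")
})

test_that("identical observations give a degenerate Kruskal-Wallis result, not an error", {
  d <- tibble::tibble(group = rep(c("a", "b", "c"), each = 4), y = rep(7, 12))
  r <- kruskal_dunn(d, "y")
  expect_equal(r$omnibus$H, 0)
  expect_equal(r$omnibus$p, 1)
  expect_equal(nrow(r$pairwise), 0)
})

test_that("Dunn z statistics match an independent implementation of the rank formula", {
  set.seed(21)
  d <- tibble::tibble(group = rep(c("a", "b", "c"), times = c(5, 6, 4)),
                      y = c(rnorm(5), rnorm(6, 1), rnorm(4, 2)))
  r <- kruskal_dunn(d, "y", adjust = "none")
  # independent oracle, recomputed from scratch
  N <- nrow(d); rk <- rank(d$y)
  ties <- table(d$y); Tc <- sum(ties^3 - ties) / (12 * (N - 1))
  for (pr in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    ni <- sum(d$group == pr[1]); nj <- sum(d$group == pr[2])
    z <- (mean(rk[d$group == pr[1]]) - mean(rk[d$group == pr[2]])) /
      sqrt((N * (N + 1) / 12 - Tc) * (1 / ni + 1 / nj))
    got <- r$pairwise$z[r$pairwise$pair == paste(pr, collapse = " - ")]
    expect_equal(unname(got), z, tolerance = 1e-12)
  }
  # omnibus agrees with stats::kruskal.test
  expect_equal(r$omnibus$H, unname(stats::kruskal.test(y ~ group, d)$statistic))
})

test_that("Dunn adjustment respects p_adj in [p_raw, 1] and detects a shifted group", {
  set.seed(22)
  d <- null_outcomes(n_per_group = 8)
  d$y[d$group == "g1"] <- d$y[d$group == "g1"] + 5
  r <- kruskal_dunn(d, "y", adjust = "bonferroni")
  expect_true(all(r$pairwise$p_adj >= r$pairwise$p_raw))
  expect_true(all(r$pairwise$p_adj <= 1))
  expect_lt(r$omnibus$p, 0.01)
  expect_lt(min(r$pairwise$p_adj[grepl("g1", r$pairwise$pair)]), 0.05)
})

test_that("RM ANOVA detects a between-group effect and honors Bonferroni", {
  set.seed(23)
  d <- make_rm_data(group_shift = c(2, 0, 0, 0))
  r <- rm_anova_bonferroni(d)
  expect_lt(r$omnibus$p_group, 0.01)
  expect_true(all(r$pairwise$p_adj >= r$pairwise$p_raw))
  expect_true(all(r$pairwise$p_adj <= 1))
  # family-wise Bonferroni: adjusted = min(1, m * raw)
  m <- nrow(r$pairwise)
  expect_equal(r$pairwise$p_adj, pmin(1, r$pairwise$p_raw * m))
})

test_that("RM ANOVA excludes animals missing a level and degenerates gracefully", {
  set.seed(24)
  d <- make_rm_data()
  d <- d[!(d$animal_id == "g1_1" & d$strain_level_pct == 10), ]
  expect_warning(r <- rm_anova_bonferroni(d, contrasts = FALSE), "g1_1")
  expect_true(is.finite(r$omnibus$F_group))

  flat <- make_rm_data(sd_animal = 0, sd_resid = 0)
  flat$tangent_modulus_MPa <- 1  # no variance anywhere
  r0 <- rm_anova_bonferroni(flat)
  expect_equal(r0$omnibus$F_group, 0)
  expect_equal(r0$omnibus$p_group, 1)
})

test_that("constant AI collapses the mixed model to null contrasts via the fallback", {
  d <- tidyr::expand_grid(specimen_id = paste0("s", 1:10),
                          strain_level_pct = c(4.6, 10, 15.7, 21.6))
  d$group <- rep(rep(c("a", "b"), each = 4), 5)[seq_len(nrow(d))]
  d$group <- rep(c("a", "b"), each = 20)
  d$ai <- 1
  expect_warning(r <- mixed_model_ai(d), "falling back")
  expect_true(all(abs(r$pairwise$estimate) < 1e-12))
})

test_that("the AI mixed model recovers a group contrast with valid adjustment", {
  set.seed(25)
  levels <- c(4.6, 10, 15.7, 21.6)
  d <- tidyr::expand_grid(specimen_id = sprintf("s%02d", 1:16),
                          strain_level_pct = levels)
  d$group <- rep(c("veh", "rgta"), each = nrow(d) / 2)
  spec_int <- rnorm(16, 0, 0.08)[match(d$specimen_id, sprintf("s%02d", 1:16))]
  d$ai <- 1 + spec_int + ifelse(d$group == "rgta", 0.4, 0) + rnorm(nrow(d), 0, 0.05)
  r <- mixed_model_ai(d)
  expect_lt(r$omnibus$p_group, 0.01)
  expect_true(all(r$pairwise$p_adj >= r$pairwise$p_raw))
  expect_true(grepl("random intercept", r$test))
})

test_that("sample size matches the noncentral-t oracle and the study's published design", {
  # independent oracle: two-sample two-sided t-test power via the noncentral t
  nct_power <- function(n, delta, sd, alpha = 0.05) {
    df <- 2 * (n - 1)
    ncp <- delta / sd * sqrt(n / 2)
    q <- qt(1 - alpha / 2, df)
    1 - pt(q, df, ncp) + pt(-q, df, ncp)
  }
  oracle_n <- function(delta, sd, power = 0.9) {
    n <- 2
    while (nct_power(n, delta, sd) < power) n <- n + 1
    n
  }
  # 30% difference, SD 15% of the control mean -> 7 animals per group
  expect_equal(sample_size(0.30, relative_sd = 0.15), 7L)
  expect_equal(sample_size(0.30, relative_sd = 0.15), oracle_n(0.30, 0.15))
  expect_equal(sample_size(0.25, relative_sd = 0.20), oracle_n(0.25, 0.20))
  expect_equal(sample_size(0.30, relative_sd = 0.30), oracle_n(0.30, 0.30))
  # saturating and monotone behavior
  expect_equal(sample_size(0.30, relative_sd = 1e-6), 2L)
  expect_gte(sample_size(0.30, relative_sd = 0.30),
             sample_size(0.30, relative_sd = 0.15))
  expect_error(sample_size(0.30), "relative_sd")
})
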
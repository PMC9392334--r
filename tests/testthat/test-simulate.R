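test_that("generated arm-level baseline moments match the scenario", {
  rec <- generate_trial(clean_default_scenario(seed = 101))
  base <- rec[rec$timepoint == "baseline", ]
  for (a in c("original", "adapted")) {
    x <- base$total_minutes[base$arm == a]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - 126), 2 * se + 9)  # target window 122-131
    expect_gt(sd(x), 38)
    expect_lt(sd(x), 54)
  }
})

test_that("noise-free scenario reproduces the deterministic baseline transform", {
  cp0 <- lapply(default_component_params(), function(cp)
    component_params(zero_prob = 1, gamma_mean = cp$gamma_mean,
                     gamma_shape = cp$gamma_shape))
  sc <- trial_scenario(n_schools_per_arm = 4, arm_effect = 0,
                       school_sd = 0, residual_sd = 0,
                       component_params = cp0,
                       missing_rate_baseline = 0, missing_rate_followup = 0,
                       invalid_rate = 0, seed = 8)
  rec <- generate_trial(sc)
  wide <- tidyr::pivot_wider(rec[, c("teacher_id", "arm", "timepoint",
                                     "total_minutes")],
                             names_from = "timepoint",
                             values_from = "total_minutes")
  alpha <- sc$followup_mean - sc$baseline_slope * sc$baseline_mean
  expected <- alpha + sc$baseline_slope * wide$baseline
  # minutes recorded at 2-decimal precision
  expect_lt(max(abs(wide$followup - expected)), 0.05)
  # with no arm effect the baseline-adjusted arm difference is exactly zero
  adj <- wide$followup - sc$baseline_slope * wide$baseline
  diff <- mean(adj[wide$arm == "adapted"]) -
    mean(adj[wide$arm == "original"])
  expect_lt(abs(diff), 0.05)
})

test_that("degenerate hurdle (zero_prob = 1) yields all-zero component", {
  cps <- default_component_params()
  cps$energisers <- component_params(zero_prob = 1, gamma_mean = 40,
                                     gamma_shape = 1.5)
  rec <- generate_trial(small_scenario(seed = 3, component_params = cps))
  expect_true(all(rec$minutes_energisers == 0))
})

test_that("totals equal the sum of component minutes on every record", {
  rec <- generate_trial(trial_scenario(seed = 11))
  obs <- !is.na(rec$total_minutes)
  sums <- rowSums(rec[obs, c("minutes_pe", "minutes_sport",
                             "minutes_energisers",
                             "minutes_active_lessons")])
  expect_equal(rec$total_minutes[obs], sums)
})

test_that("generation is reproducible by seed and varies across seeds", {
  sc <- trial_scenario(seed = 21)
  expect_identical(generate_trial(sc), generate_trial(sc))
  sc2 <- sc
  sc2$seed <- 22L
  expect_false(identical(generate_trial(sc), generate_trial(sc2)))
})

test_that("between-school variance of school means matches the scenario", {
  m_teachers <- 5
  sc <- clean_default_scenario(teachers_per_school = m_teachers)
  # follow-up school means vary through the intercept plus the mean of the
  # teacher-level residual and baseline-tracking terms
  target <- sc$school_sd^2 +
    (sc$residual_sd^2 + sc$baseline_slope^2 * sc$baseline_sd^2) / m_teachers
  vars <- vapply(1:200, function(s) {
    sci <- sc
    sci$seed <- 1000L + s
    rec <- generate_trial(sci)
    fup <- rec[rec$timepoint == "followup", ]
    # pool within-arm variances of school means (arm effect excluded)
    orig <- tapply(fup$total_minutes[fup$arm == "original"],
                   fup$school_id[fup$arm == "original"], mean)
    adap <- tapply(fup$total_minutes[fup$arm == "adapted"],
                   fup$school_id[fup$arm == "adapted"], mean)
    (var(orig) + var(adap)) / 2
  }, numeric(1L))
  expect_lt(abs(mean(vars) - target) / target, 0.15)
})

test_that("hurdle component marginal means match (1 - zero_prob) * gamma_mean", {
  # headroom-rich scenario so the total-reconciliation rescaling is inactive
  sc <- trial_scenario(
    n_schools_per_arm = 12, teachers_per_school = 10,
    baseline_mean = 400, baseline_sd = 30, followup_mean = 420,
    missing_rate_baseline = 0, missing_rate_followup = 0, invalid_rate = 0,
    seed = 31)
  rec <- generate_trial(sc)
  for (comp in c("energisers", "active_lessons", "pe")) {
    cp <- sc$component_params[[comp]]
    for (tp in c("baseline", "followup")) {
      x <- rec[[paste0("minutes_", comp)]][rec$timepoint == tp]
      target <- (1 - cp$zero_prob[tp, "original"]) *
        cp$gamma_mean[tp, "original"]
      se <- sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - target), 3 * se)
    }
  }
})

test_that("missingness masks at the configured rates and keeps identifiers", {
  rec <- generate_trial(small_scenario(seed = 41, teachers_per_school = 10,
                                       n_schools_per_arm = 50))
  expect_identical(inject_missingness(rec, 0, 0, seed = 1), rec)
  all_fup <- inject_missingness(rec, 0, 1, seed = 1)
  fup <- all_fup[all_fup$timepoint == "followup", ]
  expect_true(all(is.na(fup$total_minutes)))
  expect_false(anyNA(fup$teacher_id))
  expect_false(anyNA(fup$arm))

  masked <- inject_missingness(rec, 0, 0.3, seed = 9)
  n <- sum(rec$timepoint == "followup")
  frac <- mean(is.na(masked$total_minutes[masked$timepoint == "followup"]))
  halfwidth <- qnorm(0.995) * sqrt(0.3 * 0.7 / n)  # binomial 99% interval
  expect_lt(abs(frac - 0.3), halfwidth)
  expect_error(inject_missingness(rec, -0.1, 0),
               class = "niclust_config_error")
})

test_that("invalid injection hits about the configured share of schools", {
  rec <- generate_trial(small_scenario(seed = 51, n_schools_per_arm = 24))
  out <- inject_invalid(rec, 0.125, seed = 77)
  hit_schools <- unique(out$school_id[out$.invalid_injected])
  expect_gte(length(hit_schools), 2)   # binomial(48, .125): 99% in [1, 13]
  expect_lte(length(hit_schools), 13)
  expect_true(all(out$total_minutes[out$.invalid_injected] > 250))
  expect_identical(inject_invalid(rec, 0, seed = 1), rec)
  expect_error(inject_invalid(rec, 1.5), class = "niclust_config_error")
})
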
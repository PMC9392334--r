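test_that("the linear mixed model recovers a known group effect from
           near-noise-free data", {
  sc <- small_scenario(seed = 61, arm_effect = -7.5, school_sd = 0.01,
                       residual_sd = 0.01)
  ds <- make_dataset(sc)
  fit <- fit_lmm(ds, quick_mcmc(seed = 62))
  beta <- extract_draws(fit$draws, "beta_group")
  expect_lt(abs(mean(beta) - (-7.5)), 0.5)
})

test_that("with complete data the one-step imputation is a no-op", {
  ds <- build_analysis_dataset(generate_trial(small_scenario(seed = 63)))
  expect_equal(sum(is.na(ds$teachers$baseline)), 0L)
  expect_equal(sum(is.na(ds$teachers$followup)), 0L)
  fit_a <- fit_lmm(ds, quick_mcmc(seed = 64), monitor_imputations = TRUE)
  fit_b <- fit_lmm(ds, quick_mcmc(seed = 64), monitor_imputations = FALSE)
  expect_equal(fit_a$n_imputed_baseline + fit_a$n_imputed_followup, 0L)
  expect_identical(extract_draws(fit_a$draws, "beta_group"),
                   extract_draws(fit_b$draws, "beta_group"))
})

test_that("posterior means agree with a frequentist mixed-model cross-check", {
  skip_if_not_installed("lme4")
  ds <- make_dataset(clean_default_scenario(seed = 65))
  fit <- fit_lmm(ds, mcmc_config(2, 1000, 1500, seed = 66))
  td <- ds$teachers
  ml <- lme4::lmer(followup ~ arm_indicator + baseline + (1 | school_id),
                   data = td, REML = FALSE)
  freq <- lme4::fixef(ml)[["arm_indicator"]]
  freq_se <- sqrt(diag(as.matrix(stats::vcov(ml))))[2L]
  beta <- mean(extract_draws(fit$draws, "beta_group"))
  expect_lt(abs(beta - freq), freq_se)
})

test_that("imputation draws are stored for missing outcomes and widen with
           missingness", {
  rec <- generate_trial(clean_default_scenario(seed = 67))
  rec30 <- inject_missingness(rec, 0.05, 0.3, seed = 670)
  ds <- build_analysis_dataset(validity_filter(rec30)$valid)
  fit <- fit_lmm(ds, quick_mcmc(seed = 68))
  expect_gt(fit$n_imputed_followup, 0L)
  imp_names <- grep("^y[bf]\\[", dimnames(fit$draws$draws)[[3L]],
                    value = TRUE)
  expect_equal(length(imp_names),
               fit$n_imputed_baseline + fit$n_imputed_followup)
  # an imputed follow-up varies across iterations (posterior predictive)
  expect_gt(sd(extract_draws(fit$draws, imp_names[length(imp_names)])), 0)

  # paired comparison: the same records without any masking
  ds0 <- build_analysis_dataset(validity_filter(rec)$valid)
  fit0 <- fit_lmm(ds0, quick_mcmc(seed = 68))
  width <- function(f) {
    q <- quantile(extract_draws(f$draws, "beta_group"), c(0.025, 0.975))
    diff(q)
  }
  expect_gt(width(fit), width(fit0))
})

test_that("prior mode validation and model degeneracy errors fire", {
  ds <- make_dataset(small_scenario(seed = 69))
  expect_error(fit_lmm(ds, quick_mcmc(), prior_mode = "informative"),
               class = "niclust_config_error")
  td <- ds$teachers
  td$baseline[td$arm == "adapted"] <- NA
  td$followup[td$arm == "adapted"] <- NA
  ds_bad <- ds
  ds_bad$teachers <- td
  expect_error(fit_lmm(ds_bad, quick_mcmc()),
               class = "niclust_model_error")
})

test_that("data dominate the prior: informative and uninformative fits agree", {
  ds <- make_dataset(clean_default_scenario(seed = 70,
                                            teachers_per_school = 8))
  f1 <- fit_lmm(ds, quick_mcmc(seed = 71))
  f2 <- fit_lmm(ds, quick_mcmc(seed = 71), prior_mode = "informative",
                beta_prior = c(5, 30))
  b1 <- mean(extract_draws(f1$draws, "beta_group"))
  b2 <- mean(extract_draws(f2$draws, "beta_group"))
  expect_lt(abs(b1 - b2), 1)
})

test_that("hurdle fit recovers the marginal mean identity (1 - pi) * mu", {
  rec <- hurdle_records(n_schools = 20, teachers = 8, zero_prob = 0.5,
                        gamma_mean = 40, shape = 1.5, seed = 72)
  ds <- build_analysis_dataset(rec)
  fit <- fit_gamma_hurdle(ds, "energisers", quick_mcmc(seed = 73))
  g <- function(p) extract_draws(fit$draws, p)
  pp_mean_draws <- stats::plogis(g("a0")) * exp(g("b0"))
  x <- rec$minutes_energisers[rec$timepoint == "baseline"]
  xx <- c(x, rec$minutes_energisers[rec$timepoint == "followup"])
  se_data <- sd(xx) / sqrt(length(xx))
  mcse <- sd(pp_mean_draws) /
    sqrt(effective_sample_size(fit$draws)[["a0"]])
  expect_lt(abs(mean(pp_mean_draws) - 20), 3 * sqrt(se_data^2 + mcse^2))
})

test_that("a null time-by-group interaction is covered by its interval", {
  rec <- hurdle_records(n_schools = 24, teachers = 8, zero_prob = 0.4,
                        gamma_mean = 35, shape = 2, seed = 74)
  ds <- build_analysis_dataset(rec)
  fit <- fit_gamma_hurdle(ds, "energisers", quick_mcmc(seed = 75))
  ratio <- exponentiate_interaction(fit)
  ci <- quantile(ratio, c(0.025, 0.975))
  expect_gt(1.0, ci[1L])
  expect_lt(1.0, ci[2L])
})

test_that("a small positive-part interaction is recovered within its own
           interval", {
  true_ratio <- 1.04
  gm <- function(t, g) exp(log(35) + 0.1 * t + 0.05 * g +
                             log(true_ratio) * t * g)
  rec <- hurdle_records(n_schools = 30, teachers = 12, zero_prob = 0.3,
                        gamma_mean = gm, shape = 3, seed = 78)
  ds <- build_analysis_dataset(rec)
  fit <- fit_gamma_hurdle(ds, "energisers", quick_mcmc(seed = 79))
  ratio <- exponentiate_interaction(fit)
  ci <- quantile(ratio, c(0.025, 0.975))
  expect_gt(true_ratio, ci[1L])
  expect_lt(true_ratio, ci[2L])
})

test_that("degenerate components are rejected with guidance", {
  rec <- hurdle_records(zero_prob = 0, seed = 76)
  ds <- build_analysis_dataset(rec)
  expect_error(fit_gamma_hurdle(ds, "energisers", quick_mcmc()),
               class = "niclust_degenerate_error")
  rec0 <- hurdle_records(zero_prob = 1, seed = 77)
  ds0 <- build_analysis_dataset(rec0)
  expect_error(fit_gamma_hurdle(ds0, "energisers", quick_mcmc()),
               class = "niclust_degenerate_error")
})

test_that("exponentiated interaction is the elementwise exponential", {
  d <- new_draws_for_test(rep(c(-0.1, 0, 0.1), length.out = 40), "b_tg")
  expect_equal(mean(exponentiate_interaction(d)),
               mean(exp(rep(c(-0.1, 0, 0.1), length.out = 40))))
  expect_equal(exponentiate_interaction(
    new_draws_for_test(rep(log(2), 4), "b_tg")), rep(2, 4))
})

test_that("minutes-scale hurdle difference matches direct evaluation", {
  pars <- c(a0 = 0.2, a_time = 0.5, a_group = -0.1, a_tg = 0.3,
            b0 = 3.0, b_time = 0.2, b_group = -0.05, b_tg = 0.15)
  arr <- array(rep(pars, each = 4L), dim = c(4L, 1L, length(pars)),
               dimnames = list(NULL, NULL, names(pars)))
  d <- niclust:::new_ni_draws(arr)
  cellval <- function(t, g) {
    p <- stats::plogis(pars["a0"] + pars["a_time"] * t +
                         pars["a_group"] * g + pars["a_tg"] * t * g)
    mu <- exp(pars["b0"] + pars["b_time"] * t + pars["b_group"] * g +
                pars["b_tg"] * t * g)
    unname(p * mu)
  }
  expected <- (cellval(1, 1) - cellval(0, 1)) - (cellval(1, 0) - cellval(0, 0))
  expect_equal(unique(hurdle_minutes_difference(d)), expected)

  # equal coefficients across arms: difference identically zero
  pars0 <- pars
  pars0[c("a_group", "a_tg", "b_group", "b_tg")] <- 0
  arr0 <- array(rep(pars0, each = 4L), dim = c(4L, 1L, length(pars0)),
                dimnames = list(NULL, NULL, names(pars0)))
  expect_equal(unique(hurdle_minutes_difference(niclust:::new_ni_draws(arr0))),
               0)
})

test_that("with no zero part the difference collapses to gamma mean DiD", {
  pars <- c(a0 = 30, a_time = 0, a_group = 0, a_tg = 0,
            b0 = 3.0, b_time = 0.2, b_group = -0.05, b_tg = 0.15)
  arr <- array(rep(pars, each = 4L), dim = c(4L, 1L, length(pars)),
               dimnames = list(NULL, NULL, names(pars)))
  d <- niclust:::new_ni_draws(arr)
  mu <- function(t, g) exp(3.0 + 0.2 * t - 0.05 * g + 0.15 * t * g)
  expected <- (mu(1, 1) - mu(0, 1)) - (mu(1, 0) - mu(0, 0))
  expect_equal(unique(hurdle_minutes_difference(d)), expected,
               tolerance = 1e-10)
})
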
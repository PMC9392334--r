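# Shared fixtures: small scenarios and short MCMC runs keep the unit tests
# fast; the acceptance tests use the study-scale settings.

quick_mcmc <- function(seed = 1L, chains = 2L, burn = 400L, samp = 600L) {
  mcmc_config(n_chains = chains, n_burnin = burn, n_samples = samp,
              seed = seed)
}

small_scenario <- function(seed = 1L, n_schools_per_arm = 6,
                           teachers_per_school = c(4, 6), ...) {
  trial_scenario(n_schools_per_arm = n_schools_per_arm,
                 teachers_per_school = teachers_per_school,
                 missing_rate_baseline = 0, missing_rate_followup = 0,
                 invalid_rate = 0, seed = seed, ...)
}

clean_default_scenario <- function(seed = 1L, ...) {
  trial_scenario(missing_rate_baseline = 0, missing_rate_followup = 0,
                 invalid_rate = 0, seed = seed, ...)
}

make_dataset <- function(scenario) {
  rec <- generate_trial(scenario)
  filt <- validity_filter(rec)
  build_analysis_dataset(filt$valid, filt$excluded)
}

# Wrap a plain numeric vector as a 4-chain ni_draws for diagnostic tests.
new_draws_for_test <- function(values, name = "theta") {
  n <- length(values) / 4L
  niclust:::new_ni_draws(array(values, dim = c(4L, n, 1L),
                               dimnames = list(NULL, NULL, name)))
}

# Component-only records drawn straight from the hurdle distribution, for
# tests of the hurdle model itself (no total-activity reconciliation).
# zero_prob and gamma_mean may be scalars or functions of (time01, group01).
hurdle_records <- function(n_schools = 20, teachers = 8, zero_prob = 0.5,
                           gamma_mean = 40, shape = 1.5, seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(school = seq_len(n_schools),
                      teacher = seq_len(teachers),
                      timepoint = c("baseline", "followup"),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  t01 <- as.integer(grid$timepoint == "followup")
  g01 <- as.integer(grid$school > n_schools / 2)
  zp <- if (is.function(zero_prob)) zero_prob(t01, g01) else zero_prob
  gm <- if (is.function(gamma_mean)) gamma_mean(t01, g01) else gamma_mean
  mins <- rbinom(n, 1, 1 - zp) *
    rgamma(n, shape = shape, rate = shape / gm)
  tibble::tibble(
    school_id = sprintf("S%02d", grid$school),
    teacher_id = sprintf("S%02dT%02d", grid$school, grid$teacher),
    arm = ifelse(grid$school <= n_schools / 2, "original", "adapted"),
    region = "R1", geolocation = "major_city",
    timepoint = grid$timepoint,
    minutes_pe = 0, minutes_sport = 0,
    minutes_energisers = round(mins, 2),
    minutes_active_lessons = 0,
    total_minutes = round(mins, 2)
  )
}
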
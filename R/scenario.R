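#' Hurdle parameters for one activity component
#'
#' Each component of scheduled weekly activity (energisers, active lessons,
#' PE) is modelled as a hurdle: a point mass at zero minutes with probability
#' `zero_prob`, and a right-skewed gamma distribution for positive minutes.
#' Parameters may differ by timepoint and, optionally, by arm.
#'
#' @param zero_prob probability of exactly zero minutes. A length-2 vector
#'   `c(baseline, followup)` shared by both arms, or a 2x2 matrix with rows
#'   `baseline`/`followup` and columns `original`/`adapted`.
#' @param gamma_mean mean of the positive part (minutes/week), same shapes
#'   accepted as `zero_prob`.
#' @param gamma_shape gamma shape parameter (> 0); larger is less skewed.
#' @return A list of class `ni_component_params` with 2x2 matrices
#'   `zero_prob` and `gamma_mean` plus scalar `gamma_shape`.
#' @examples
#' component_params(zero_prob = c(0.5, 0.15), gamma_mean = c(37, 46),
#'                  gamma_shape = 1.5)
#' @export
component_params <- function(zero_prob, gamma_mean, gamma_shape) {
  expand22 <- function(x, name) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(2L, 2L))) {
        ni_abort(sprintf("`%s` matrix must be 2x2 (timepoint x arm).", name),
                 "niclust_config_error")
      }
      m <- x
    } else if (length(x) %in% c(1L, 2L)) {
      m <- matrix(rep(x, length.out = 2L), nrow = 2L, ncol = 2L)
    } else {
      ni_abort(sprintf("`%s` must be length 1, 2, or a 2x2 matrix.", name),
               "niclust_config_error")
    }
    dimnames(m) <- list(c("baseline", "followup"), c("original", "adapted"))
    m
  }
  zp <- expand22(zero_prob, "zero_prob")
  gm <- expand22(gamma_mean, "gamma_mean")
  check_prob(zp, "zero_prob")
  check_positive(gm, "gamma_mean")
  check_positive(gamma_shape, "gamma_shape")
  structure(list(zero_prob = zp, gamma_mean = gm,
                 gamma_shape = gamma_shape),
            class = "ni_component_params")
}

default_component_params <- function() {
  # Calibrated to the observed component means/SDs of a two-arm teacher
  # logbook trial: energisers rise sharply by follow-up, active lessons are
  # rare and small, PE is near-universal and large.
  list(
    energisers = component_params(zero_prob = c(0.50, 0.15),
                                  gamma_mean = c(37, 46),
                                  gamma_shape = 1.5),
    active_lessons = component_params(zero_prob = c(0.55, 0.45),
                                      gamma_mean = c(24, 28),
                                      gamma_shape = 1.2),
    pe = component_params(zero_prob = c(0.05, 0.03),
                          gamma_mean = c(50, 58),
                          gamma_shape = 2.8)
  )
}

default_strata <- function() {
  tibble::tibble(
    region = c("CC", "CC", "HNE", "HNE"),
    geolocation = c("major_city", "regional_remote",
                    "major_city", "regional_remote"),
    prop = c(0.23, 0.27, 0.23, 0.27)
  )
}

#' Define a synthetic cluster-trial scenario
#'
#' A scenario fixes the data-generating process for a two-arm
#' cluster-randomised trial of school implementation support: schools are
#' randomised 1:1 within region-by-geolocation strata, teachers are nested in
#' schools, and each teacher contributes weekly scheduled activity minutes at
#' baseline and 12-month follow-up. Total weekly minutes follow a Normal
#' linear model at follow-up,
#' \deqn{y_{ij} = \alpha + \beta\,\mathrm{arm}_j + \gamma\, b_{ij} + u_j +
#'   \epsilon_{ij},}
#' with school random intercept \eqn{u_j \sim N(0, \sigma_u^2)}, while the
#' component minutes (energisers, active lessons, PE) are zero-inflated gamma
#' hurdles; a sport/other remainder reconciles the two (see the methods
#' vignette).
#'
#' @param n_schools_per_arm schools randomised to each arm.
#' @param teachers_per_school a single count or a length-2 inclusive range
#'   sampled uniformly per school.
#' @param strata data frame with columns `region`, `geolocation`, `prop`
#'   (allocation proportions summing to 1).
#' @param baseline_mean,baseline_sd marginal mean and SD of total weekly
#'   minutes at baseline.
#' @param followup_mean marginal follow-up mean of total minutes in the
#'   original arm; fixes the model intercept
#'   `alpha = followup_mean - baseline_slope * baseline_mean`.
#' @param arm_effect true between-arm difference at follow-up
#'   (adapted minus original, minutes/week).
#' @param baseline_slope coefficient of baseline total on follow-up total.
#' @param school_sd SD of the school random intercept (minutes/week).
#' @param residual_sd residual SD of follow-up totals (minutes/week).
#' @param component_params named list (`energisers`, `active_lessons`, `pe`)
#'   of [component_params()] objects.
#' @param missing_rate_baseline,missing_rate_followup probabilities that a
#'   teacher's outcome record at that timepoint is missing completely at
#'   random.
#' @param invalid_rate probability that a school contains an
#'   over-threshold (> 250 min/week) invalid record.
#' @param seed integer seed; the same scenario and seed reproduce the
#'   dataset bit for bit.
#' @return A list of class `ni_scenario`.
#' @examples
#' sc <- trial_scenario(seed = 7)
#' sc$n_schools_per_arm
#' @export
trial_scenario <- function(n_schools_per_arm = 24,
                           teachers_per_school = c(3, 8),
                           strata = default_strata(),
                           baseline_mean = 126,
                           baseline_sd = 46,
                           followup_mean = 164,
                           arm_effect = -7.5,
                           baseline_slope = 0.35,
                           school_sd = 16,
                           residual_sd = 33,
                           component_params = default_component_params(),
                           missing_rate_baseline = 0.05,
                           missing_rate_followup = 0.30,
                           invalid_rate = 0.125,
                           seed = 1L) {
  check_count(n_schools_per_arm, "n_schools_per_arm")
  if (!length(teachers_per_school) %in% c(1L, 2L)) {
    ni_abort("`teachers_per_school` must be a count or a length-2 range.",
             "niclust_config_error")
  }
  check_count(min(teachers_per_school), "teachers_per_school")
  if (!is.data.frame(strata) ||
      !all(c("region", "geolocation", "prop") %in% names(strata))) {
    ni_abort("`strata` needs columns region, geolocation, prop.",
             "niclust_config_error")
  }
  if (abs(sum(strata$prop) - 1) > 1e-8) {
    ni_abort("`strata$prop` must sum to 1.", "niclust_config_error")
  }
  check_positive(baseline_sd, "baseline_sd")
  check_positive(school_sd, "school_sd", strict = FALSE)
  check_positive(residual_sd, "residual_sd", strict = FALSE)
  check_prob(missing_rate_baseline, "missing_rate_baseline")
  check_prob(missing_rate_followup, "missing_rate_followup")
  check_prob(invalid_rate, "invalid_rate")
  if (!setequal(names(component_params),
                c("energisers", "active_lessons", "pe")) ||
      !all(vapply(component_params, inherits, TRUE, "ni_component_params"))) {
    ni_abort(paste("`component_params` must be a named list of",
                   "component_params() for energisers, active_lessons, pe."),
             "niclust_config_error")
  }
  structure(
    list(n_schools_per_arm = as.integer(n_schools_per_arm),
         teachers_per_school = as.integer(teachers_per_school),
         strata = tibble::as_tibble(strata),
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         followup_mean = followup_mean, arm_effect = arm_effect,
         baseline_slope = baseline_slope,
         school_sd = school_sd, residual_sd = residual_sd,
         component_params = component_params,
         missing_rate_baseline = missing_rate_baseline,
         missing_rate_followup = missing_rate_followup,
         invalid_rate = invalid_rate,
         seed = as.integer(seed)),
    class = "ni_scenario"
  )
}

#' @export
print.ni_scenario <- function(x, ...) {
  cat("<ni_scenario>\n")
  cat(sprintf("  %d schools/arm, %s teachers/school, seed %d\n",
              x$n_schools_per_arm,
              paste(x$teachers_per_school, collapse = "-"), x$seed))
  cat(sprintf("  baseline %g (SD %g); follow-up %g + arm effect %g\n",
              x$baseline_mean, x$baseline_sd, x$followup_mean, x$arm_effect))
  cat(sprintf("  school SD %g, residual SD %g, slope %g\n",
              x$school_sd, x$residual_sd, x$baseline_slope))
  cat(sprintf("  missing: %g (baseline) / %g (follow-up); invalid rate %g\n",
              x$missing_rate_baseline, x$missing_rate_followup,
              x$invalid_rate))
  invisible(x)
}

#' Read or write a scenario as a plain-text key:value config
#'
#' Scalar fields are written one per line as `key: value`; strata and
#' component parameters are flattened with dotted keys
#' (e.g. `energisers.zero_prob.baseline`). Round-trips exactly for scalar
#' and component fields.
#'
#' @param scenario an `ni_scenario`.
#' @param path file path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns an `ni_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "ni_scenario"))
  lines <- c(
    sprintf("n_schools_per_arm: %d", scenario$n_schools_per_arm),
    sprintf("teachers_per_school: %s",
            paste(scenario$teachers_per_school, collapse = " ")),
    sprintf("baseline_mean: %.10g", scenario$baseline_mean),
    sprintf("baseline_sd: %.10g", scenario$baseline_sd),
    sprintf("followup_mean: %.10g", scenario$followup_mean),
    sprintf("arm_effect: %.10g", scenario$arm_effect),
    sprintf("baseline_slope: %.10g", scenario$baseline_slope),
    sprintf("school_sd: %.10g", scenario$school_sd),
    sprintf("residual_sd: %.10g", scenario$residual_sd),
    sprintf("missing_rate_baseline: %.10g", scenario$missing_rate_baseline),
    sprintf("missing_rate_followup: %.10g", scenario$missing_rate_followup),
    sprintf("invalid_rate: %.10g", scenario$invalid_rate),
    sprintf("seed: %d", scenario$seed)
  )
  for (i in seq_len(nrow(scenario$strata))) {
    s <- scenario$strata[i, ]
    lines <- c(lines, sprintf("stratum.%s.%s: %.10g",
                              s$region, s$geolocation, s$prop))
  }
  for (comp in names(scenario$component_params)) {
    cp <- scenario$component_params[[comp]]
    for (tp in c("baseline", "followup")) {
      for (arm in c("original", "adapted")) {
        lines <- c(lines,
                   sprintf("%s.zero_prob.%s.%s: %.10g", comp, tp, arm,
                           cp$zero_prob[tp, arm]),
                   sprintf("%s.gamma_mean.%s.%s: %.10g", comp, tp, arm,
                           cp$gamma_mean[tp, arm]))
      }
    }
    lines <- c(lines, sprintf("%s.gamma_shape: %.10g", comp, cp$gamma_shape))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":\\s*")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = ":"), "")
  get1 <- function(k) as.numeric(vals[keys == k][1L])
  comp_names <- c("energisers", "active_lessons", "pe")
  cps <- lapply(comp_names, function(comp) {
    zp <- gm <- matrix(NA_real_, 2, 2,
                       dimnames = list(c("baseline", "followup"),
                                       c("original", "adapted")))
    for (tp in rownames(zp)) {
      for (arm in colnames(zp)) {
        zp[tp, arm] <- get1(sprintf("%s.zero_prob.%s.%s", comp, tp, arm))
        gm[tp, arm] <- get1(sprintf("%s.gamma_mean.%s.%s", comp, tp, arm))
      }
    }
    component_params(zp, gm, get1(sprintf("%s.gamma_shape", comp)))
  })
  names(cps) <- comp_names
  sk <- grepl("^stratum\\.", keys)
  sparts <- strsplit(keys[sk], ".", fixed = TRUE)
  strata <- tibble::tibble(
    region = vapply(sparts, `[[`, "", 2L),
    geolocation = vapply(sparts, `[[`, "", 3L),
    prop = as.numeric(vals[sk])
  )
  trial_scenario(
    n_schools_per_arm = get1("n_schools_per_arm"),
    teachers_per_school =
      as.numeric(strsplit(vals[keys == "teachers_per_school"], " ")[[1L]]),
    strata = strata,
    baseline_mean = get1("baseline_mean"),
    baseline_sd = get1("baseline_sd"),
    followup_mean = get1("followup_mean"),
    arm_effect = get1("arm_effect"),
    baseline_slope = get1("baseline_slope"),
    school_sd = get1("school_sd"),
    residual_sd = get1("residual_sd"),
    component_params = cps,
    missing_rate_baseline = get1("missing_rate_baseline"),
    missing_rate_followup = get1("missing_rate_followup"),
    invalid_rate = get1("invalid_rate"),
    seed = get1("seed")
  )
}
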
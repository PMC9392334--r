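#' Generate a synthetic cluster-trial logbook dataset
#'
#' Simulates teacher-week activity records for a two-arm, school-randomised
#' trial under an [trial_scenario()]. Schools are allocated 1:1 to the
#' `original` and `adapted` arms within strata; each teacher contributes a
#' baseline and a follow-up record. Component minutes (energisers, active
#' lessons, PE) are drawn from per-timepoint hurdle distributions; a
#' sport/other remainder absorbs the difference between the Normal
#' total-activity model and the component sum so that total minutes follow
#' \eqn{y = \alpha + \beta\,\mathrm{arm} + \gamma b + u_{school} + \epsilon}
#' exactly (components are rescaled on the rare records where the remainder
#' would be negative). Missingness and invalid (> 250 min) records are then
#' injected at the scenario's rates via [inject_missingness()] and
#' [inject_invalid()].
#'
#' @param scenario an [trial_scenario()].
#' @return A tibble with one row per teacher-timepoint: `school_id`,
#'   `teacher_id`, `arm`, `region`, `geolocation`, `timepoint`,
#'   `minutes_pe`, `minutes_sport`, `minutes_energisers`,
#'   `minutes_active_lessons`, `total_minutes`, plus bookkeeping columns
#'   `.invalid_injected` and `.true_school_intercept` used by tests (dropped
#'   when written to CSV).
#' @examples
#' rec <- generate_trial(trial_scenario(n_schools_per_arm = 4, seed = 1))
#' dplyr::count(rec, arm, timepoint)
#' @export
generate_trial <- function(scenario) {
  if (!inherits(scenario, "ni_scenario")) {
    ni_abort("`scenario` must be created by trial_scenario().",
             "niclust_config_error")
  }
  set.seed(derive_seed(scenario$seed, "generate"))
  n_arm <- scenario$n_schools_per_arm

  # stratum allocation by largest remainder, identical in both arms
  # (allocation was stratified by region and geolocation)
  alloc <- function(props, n) {
    raw <- props * n
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    as.integer(base)
  }
  counts <- alloc(scenario$strata$prop, n_arm)
  stratum_of <- rep(seq_len(nrow(scenario$strata)), counts)

  schools <- tibble::tibble(
    school_id = sprintf("S%02d", seq_len(2L * n_arm)),
    arm = rep(c("original", "adapted"), each = n_arm),
    stratum = c(stratum_of, stratum_of)
  )
  schools$region <- scenario$strata$region[schools$stratum]
  schools$geolocation <- scenario$strata$geolocation[schools$stratum]
  rng <- range(scenario$teachers_per_school)
  schools$n_teachers <- if (rng[1L] == rng[2L]) {
    rep(rng[1L], nrow(schools))
  } else {
    sample(seq(rng[1L], rng[2L]), nrow(schools), replace = TRUE)
  }
  schools$u <- rnorm(nrow(schools), 0, scenario$school_sd)

  teachers <- tidyr::uncount(schools, .data$n_teachers, .id = "t_i")
  teachers$teacher_id <- sprintf("%sT%02d", teachers$school_id, teachers$t_i)
  n <- nrow(teachers)

  rtruncnorm0 <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < 0)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  arm01 <- as.integer(teachers$arm == "adapted")
  t_base <- rtruncnorm0(n, scenario$baseline_mean, scenario$baseline_sd)
  alpha <- scenario$followup_mean -
    scenario$baseline_slope * scenario$baseline_mean
  t_fup <- alpha + scenario$baseline_slope * t_base +
    scenario$arm_effect * arm01 + teachers$u +
    rnorm(n, 0, scenario$residual_sd)
  t_fup <- pmax(t_fup, 0)

  draw_component <- function(cp, tp, arm) {
    zp <- cp$zero_prob[cbind(tp, arm)]
    gm <- cp$gamma_mean[cbind(tp, arm)]
    pos <- rbinom(length(zp), 1L, 1 - zp)
    pos * rgamma(length(zp), shape = cp$gamma_shape,
                 rate = cp$gamma_shape / gm)
  }

  build_tp <- function(tp, total) {
    comp <- lapply(scenario$component_params, draw_component,
                   tp = rep(tp, n), arm = teachers$arm)
    csum <- comp$energisers + comp$active_lessons + comp$pe
    sport <- total - csum
    # where components exceed the modelled total, rescale them so the total
    # is preserved; sport takes the slack otherwise
    over <- sport < 0
    if (any(over)) {
      sc <- total[over] / csum[over]
      comp <- lapply(comp, function(x) {
        x[over] <- x[over] * sc
        x
      })
      sport[over] <- 0
    }
    # minutes are recorded to 2 decimals, as a logbook would hold them
    pe <- round(comp$pe, 2)
    sp <- round(sport, 2)
    en <- round(comp$energisers, 2)
    al <- round(comp$active_lessons, 2)
    tibble::tibble(
      school_id = teachers$school_id,
      teacher_id = teachers$teacher_id,
      arm = teachers$arm,
      region = teachers$region,
      geolocation = teachers$geolocation,
      timepoint = tp,
      minutes_pe = pe,
      minutes_sport = sp,
      minutes_energisers = en,
      minutes_active_lessons = al,
      total_minutes = rowSums(cbind(pe, sp, en, al)),
      .invalid_injected = FALSE,
      .true_school_intercept = teachers$u
    )
  }

  records <- dplyr::bind_rows(build_tp("baseline", t_base),
                              build_tp("followup", t_fup))
  records <- dplyr::arrange(records, .data$teacher_id, .data$timepoint)
  records <- inject_invalid(records, scenario$invalid_rate,
                            seed = derive_seed(scenario$seed, "invalid"))
  inject_missingness(records,
                     scenario$missing_rate_baseline,
                     scenario$missing_rate_followup,
                     seed = derive_seed(scenario$seed, "missing"))
}

minute_cols <- function() {
  c("minutes_pe", "minutes_sport", "minutes_energisers",
    "minutes_active_lessons", "total_minutes")
}

#' Mask outcomes completely at random
#'
#' Sets all minute fields of selected teacher-timepoint records to `NA`,
#' independently at the given rate per timepoint. Identifiers, arm and
#' stratum labels are retained so masked teachers still enter the analysis
#' dataset (their outcomes are later imputed by the primary model).
#'
#' @param records a logbook tibble as from [generate_trial()].
#' @param missing_rate_baseline,missing_rate_followup masking probabilities
#'   in `[0, 1]`.
#' @param seed integer seed.
#' @return `records` with masked outcome fields.
#' @export
inject_missingness <- function(records, missing_rate_baseline,
                               missing_rate_followup, seed = 1L) {
  check_prob(missing_rate_baseline, "missing_rate_baseline")
  check_prob(missing_rate_followup, "missing_rate_followup")
  if (missing_rate_baseline == 0 && missing_rate_followup == 0) {
    return(records)
  }
  set.seed(seed)
  rate <- ifelse(records$timepoint == "baseline",
                 missing_rate_baseline, missing_rate_followup)
  mask <- runif(nrow(records)) < rate
  records[mask, minute_cols()] <- NA_real_
  records
}

#' Inject invalid over-threshold records
#'
#' Emulates schools whose logbook process broke down: schools are selected
#' independently at `invalid_rate`, and every follow-up record in a
#' selected school has its sport minutes inflated so the weekly total
#' exceeds 250 minutes. Because such a school contributes no valid
#' follow-up data it drops out of the analysed-school tally, mirroring how
#' invalid-data schools leave a trial's flow diagram. Injected records are
#' flagged in the internal `.invalid_injected` column so tests can verify
#' downstream exclusion counts.
#'
#' @param records a logbook tibble.
#' @param invalid_rate per-school selection probability in `[0, 1]`.
#' @param seed integer seed.
#' @return `records`, with inflated and flagged rows.
#' @export
inject_invalid <- function(records, invalid_rate, seed = 1L) {
  check_prob(invalid_rate, "invalid_rate")
  if (invalid_rate == 0) return(records)
  set.seed(seed)
  schools <- unique(records$school_id)
  hit <- schools[runif(length(schools)) < invalid_rate]
  idx <- which(records$school_id %in% hit &
                 records$timepoint == "followup" &
                 !is.na(records$total_minutes))
  if (length(idx)) {
    excess <- pmax(250 - records$total_minutes[idx], 0) + 10 +
      rexp(length(idx), 1 / 30)
    records$minutes_sport[idx] <- round(records$minutes_sport[idx] + excess,
                                        2)
    records$total_minutes[idx] <- rowSums(cbind(
      records$minutes_pe[idx], records$minutes_sport[idx],
      records$minutes_energisers[idx],
      records$minutes_active_lessons[idx]))
    records$.invalid_injected[idx] <- TRUE
  }
  records
}
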
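#' Posterior mean and equal-tailed 95% credible interval
#'
#' @param draws numeric vector of posterior draws (at least 1000; fewer
#'   would make the 2.5/97.5 percentile bounds unstable).
#' @return A tibble with columns `mean`, `lower`, `upper`.
#' @examples
#' summarize_difference(rnorm(4000, -7.5, 6))
#' @export
summarize_difference <- function(draws) {
  if (!is.numeric(draws) || length(draws) < 1000L) {
    ni_abort("At least 1000 posterior draws are required to summarise.",
             "niclust_summary_error")
  }
  q <- quantile(draws, c(0.025, 0.975), names = FALSE)
  tibble::tibble(mean = mean(draws), lower = q[1L], upper = q[2L])
}

#' Posterior probability of noninferiority
#'
#' The fraction of posterior difference draws on the non-inferior side of
#' the margin (\eqn{\ge \Delta} when higher outcomes are better); its
#' complement is the fraction of draws crossing the margin.
#'
#' @param draws numeric vector of difference draws (new minus reference,
#'   outcome units).
#' @param margin an `ni_margin` or a signed numeric delta.
#' @return A fraction in `[0, 1]`.
#' @examples
#' prob_noninferiority(c(-20, -10), compute_margin(0.5, 32.8))  # 0.5
#' @export
prob_noninferiority <- function(draws, margin) {
  delta <- margin_delta(margin)
  mean(draws >= delta)
}

#' Posterior-predictive variance ratio (Bayesian ICC analogue)
#'
#' The proportion of posterior-predictive outcome variance attributable to
#' clustering. Per posterior draw, the predictive variance over the
#' observed design is computed twice: marginally (school intercepts
#' integrated over their \eqn{N(0, \sigma_u^2)} distribution) and
#' conditionally (intercepts fixed at their drawn values); the reported
#' ratio is \eqn{(V_m - V_c) / V_m}, summarised by its posterior mean and
#' equal-tailed 95% interval. Because the conditional variance uses the
#' finitely many drawn intercepts, individual draws of the ratio can be
#' negative when clustering is weak.
#'
#' @param samples an `ni_lmm` or `ni_hurdle` fit.
#' @param ... passed to methods.
#' @return A list of class `ni_variance_ratio` with `mean`, `lower`,
#'   `upper` and the per-draw `draws`.
#' @export
variance_ratio <- function(samples, ...) {
  UseMethod("variance_ratio")
}

finalise_variance_ratio <- function(ratio_draws) {
  q <- quantile(ratio_draws, c(0.025, 0.975), names = FALSE)
  structure(list(mean = mean(ratio_draws), lower = q[1L], upper = q[2L],
                 draws = ratio_draws),
            class = "ni_variance_ratio")
}

#' @export
print.ni_variance_ratio <- function(x, ...) {
  cat(sprintf("<ni_variance_ratio> %.2f (%.2f, %.2f)\n",
              x$mean, x$lower, x$upper))
  invisible(x)
}

# deterministic thinning to at most `max_draws` pooled draws
thin_index <- function(n, max_draws = 2000L) {
  if (n <= max_draws) seq_len(n)
  else round(seq(1L, n, length.out = max_draws))
}

#' @rdname variance_ratio
#' @param max_draws cap on the number of posterior draws evaluated
#'   (deterministically thinned).
#' @export
variance_ratio.ni_lmm <- function(samples, max_draws = 2000L, ...) {
  td <- samples$data$teachers
  dr <- samples$draws
  g <- function(p) extract_draws(dr, p)
  keep <- thin_index(length(g("sigma_u")), max_draws)
  sigma_u <- g("sigma_u")[keep]
  sigma_e <- g("sigma_e")[keep]
  n <- nrow(td)
  J <- samples$data$n_schools
  sch <- td$school_index
  set.seed(derive_seed(samples$config$seed, "mcmc") + 7L)
  ratio <- vapply(seq_along(keep), function(t) {
    eps <- rnorm(n, 0, sigma_e[t])
    u_new <- rnorm(J, 0, sigma_u[t])
    v_cond <- var(eps)                    # within-school spread only
    v_marg <- var(u_new[sch] + eps)       # plus fresh between-school spread
    (v_marg - v_cond) / v_marg
  }, numeric(1L))
  finalise_variance_ratio(ratio)
}

#' @rdname variance_ratio
#' @export
variance_ratio.ni_hurdle <- function(samples, max_draws = 1000L, ...) {
  cc <- samples$data$components
  cc <- cc[cc$component == samples$component & !is.na(cc$minutes), ]
  dr <- samples$draws
  g <- function(p) extract_draws(dr, p)
  keep <- thin_index(length(g("a0")), max_draws)
  J <- samples$data$n_schools
  uz_mat <- vapply(sprintf("uz[%d]", seq_len(J)), function(p) g(p)[keep],
                   numeric(length(keep)))
  up_mat <- vapply(sprintf("up[%d]", seq_len(J)), function(p) g(p)[keep],
                   numeric(length(keep)))
  par_names <- c("a0", "a_time", "a_group", "a_tg", "sigma_uz",
                 "b0", "b_time", "b_group", "b_tg", "shape", "sigma_up")
  pars <- lapply(par_names, function(p) g(p)[keep])
  names(pars) <- par_names
  t01 <- cc$timepoint01
  g01 <- cc$arm_indicator
  sch <- cc$school_index
  n <- nrow(cc)
  set.seed(derive_seed(samples$config$seed, "mcmc") + 7L)
  cell <- function(t, uz, up) {
    p <- stats::plogis(pars$a0[t] + pars$a_time[t] * t01 +
                         pars$a_group[t] * g01 +
                         pars$a_tg[t] * t01 * g01 + uz[sch])
    mu <- exp(pars$b0[t] + pars$b_time[t] * t01 + pars$b_group[t] * g01 +
                pars$b_tg[t] * t01 * g01 + up[sch])
    list(p = p, mu = mu)
  }
  ratio <- vapply(seq_along(keep), function(t) {
    # common random numbers so zero clustering SDs give exactly zero
    uu <- runif(n)
    gg <- rgamma(n, shape = pars$shape[t], rate = pars$shape[t])
    cond <- cell(t, uz_mat[t, ], up_mat[t, ])
    y_cond <- (uu < cond$p) * cond$mu * gg
    v_cond <- var(y_cond - cond$p * cond$mu)
    uz_new <- rnorm(J, 0, pars$sigma_uz[t])
    up_new <- rnorm(J, 0, pars$sigma_up[t])
    marg <- cell(t, uz_new, up_new)
    fixed <- cell(t, rep(0, J), rep(0, J))
    y_marg <- (uu < marg$p) * marg$mu * gg
    v_marg <- var(y_marg - fixed$p * fixed$mu)
    (v_marg - v_cond) / v_marg
  }, numeric(1L))
  finalise_variance_ratio(ratio)
}

#' Assemble a noninferiority result for one outcome
#'
#' Bundles the minutes-scale difference draws, the margin, the posterior
#' probability of noninferiority, the interval decision rule, and (for
#' hurdle outcomes) the ratio-scale estimate into one record. The interval
#' decision and the posterior probability are computed independently and
#' reported side by side; neither implies the other.
#'
#' @param outcome outcome label.
#' @param minutes_draws numeric vector of minutes-scale difference draws.
#' @param margin an `ni_margin`.
#' @param ratio_draws optional ratio-scale draws (hurdle outcomes); when
#'   supplied the reported estimate is the ratio, flagged `exponentiated`.
#' @param variance_ratio optional `ni_variance_ratio`.
#' @param descriptives optional tibble of arm-by-timepoint observed means
#'   and SDs (see [outcome_descriptives()]).
#' @return An object of class `ni_result`.
#' @export
noninferiority_result <- function(outcome, minutes_draws, margin,
                                  ratio_draws = NULL, variance_ratio = NULL,
                                  descriptives = NULL) {
  minutes_summary <- summarize_difference(minutes_draws)
  est <- if (is.null(ratio_draws)) minutes_summary
         else summarize_difference(ratio_draws)
  structure(
    list(outcome = outcome,
         estimate = est,
         estimate_scale = if (is.null(ratio_draws)) "minutes" else "ratio",
         minutes_summary = minutes_summary,
         minutes_draws = minutes_draws,
         margin = margin,
         prob_noninferior = prob_noninferiority(minutes_draws, margin),
         interval_decision =
           noninferior_by_interval(minutes_summary$lower, margin),
         variance_ratio = variance_ratio,
         descriptives = descriptives),
    class = "ni_result"
  )
}

#' @export
print.ni_result <- function(x, ...) {
  cat(sprintf("<ni_result> %s\n", x$outcome))
  cat(sprintf("  estimate (%s): %.2f (%.2f, %.2f)\n", x$estimate_scale,
              x$estimate$mean, x$estimate$lower, x$estimate$upper))
  cat(sprintf("  margin %.2f; P(noninferior) = %.1f%%; interval rule: %s\n",
              margin_delta(x$margin), 100 * x$prob_noninferior,
              if (x$interval_decision) "noninferior" else "inconclusive"))
  if (!is.null(x$variance_ratio)) {
    cat(sprintf("  variance ratio %.2f (%.2f, %.2f)\n",
                x$variance_ratio$mean, x$variance_ratio$lower,
                x$variance_ratio$upper))
  }
  invisible(x)
}

#' @export
tidy.ni_result <- function(x, ...) {
  build_results_table(list(x))
}

#' Observed arm-by-timepoint descriptives for one outcome
#'
#' @param data an `ni_data`.
#' @param outcome `"total"` or a component name.
#' @return Tibble with arm, timepoint, n, mean, sd of observed minutes.
#' @export
outcome_descriptives <- function(data, outcome = "total") {
  stopifnot(inherits(data, "ni_data"))
  if (outcome == "total") {
    long <- tidyr::pivot_longer(
      data$teachers[, c("arm", "baseline", "followup")],
      cols = c("baseline", "followup"),
      names_to = "timepoint", values_to = "minutes")
  } else {
    long <- data$components[data$components$component == outcome,
                            c("arm", "timepoint", "minutes")]
  }
  out <- dplyr::summarise(
    dplyr::group_by(long[!is.na(long$minutes), ], .data$arm,
                    .data$timepoint),
    n = dplyr::n(), mean = mean(.data$minutes), sd = sd(.data$minutes),
    .groups = "drop")
  out$outcome <- outcome
  out
}

#' Combine per-outcome results into the trial results table
#'
#' One row per outcome: observed baseline/follow-up descriptives by arm,
#' the posterior estimate with 95% credible interval (minutes scale for the
#' primary outcome, exponentiated ratio scale for hurdle outcomes, flagged
#' in `exponentiated`), the pre-specified margin, the probability of
#' noninferiority, and the variance ratio.
#'
#' @param results list of `ni_result` objects (possibly empty).
#' @return A tibble with one row per result.
#' @export
build_results_table <- function(results) {
  template <- tibble::tibble(
    outcome = character(0),
    baseline_mean_original = numeric(0), followup_mean_original = numeric(0),
    baseline_mean_adapted = numeric(0), followup_mean_adapted = numeric(0),
    estimate = numeric(0), lower = numeric(0), upper = numeric(0),
    exponentiated = logical(0), margin = numeric(0),
    prob_noninferior = numeric(0), interval_noninferior = logical(0),
    variance_ratio = numeric(0), variance_ratio_lower = numeric(0),
    variance_ratio_upper = numeric(0)
  )
  if (!length(results)) return(template)
  rows <- purrr::map_dfr(results, function(r) {
    desc <- r$descriptives
    dget <- function(arm, tp) {
      if (is.null(desc)) return(NA_real_)
      v <- desc$mean[desc$arm == arm & desc$timepoint == tp]
      if (length(v)) v else NA_real_
    }
    tibble::tibble(
      outcome = r$outcome,
      baseline_mean_original = dget("original", "baseline"),
      followup_mean_original = dget("original", "followup"),
      baseline_mean_adapted = dget("adapted", "baseline"),
      followup_mean_adapted = dget("adapted", "followup"),
      estimate = r$estimate$mean,
      lower = r$estimate$lower,
      upper = r$estimate$upper,
      exponentiated = r$estimate_scale == "ratio",
      margin = margin_delta(r$margin),
      prob_noninferior = r$prob_noninferior,
      interval_noninferior = r$interval_decision,
      variance_ratio =
        if (is.null(r$variance_ratio)) NA_real_ else r$variance_ratio$mean,
      variance_ratio_lower =
        if (is.null(r$variance_ratio)) NA_real_ else r$variance_ratio$lower,
      variance_ratio_upper =
        if (is.null(r$variance_ratio)) NA_real_ else r$variance_ratio$upper
    )
  })
  rows
}
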
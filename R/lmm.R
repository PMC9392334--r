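# Baseline-adjusted Bayesian linear mixed model for total weekly minutes.
#
# follow-up_ij = alpha + beta_group * arm_j + gamma * baseline_ij + u_j + e_ij
#   u_j ~ N(0, sigma_u^2), e_ij ~ N(0, sigma_e^2)
# baseline_ij ~ N(mu_b, sigma_b^2) is a sub-model with vague priors so that
# missing baselines and follow-ups are drawn from their posterior predictive
# distribution jointly with the parameters at every iteration (one-step
# imputation). Sampling is delegated to JAGS.

lmm_model_string <- function(beta_prior_mean, beta_prior_prec) {
  sprintf("
model {
  for (i in 1:N) {
    yb[i] ~ dnorm(mu_b, tau_b)
    mu_f[i] <- m[school[i]] + gamma * (yb[i] - b_center)
    yf[i] ~ dnorm(mu_f[i], tau_e)
  }
  # hierarchically centred school means: the group effect updates from the
  # school-level regression, which mixes well across the whole sigma_u range
  for (j in 1:J) {
    m[j] ~ dnorm(alpha_c + beta_group * armj[j], tau_u)
    u[j] <- m[j] - alpha_c - beta_group * armj[j]
  }
  alpha_c ~ dnorm(0, 1.0E-4)
  alpha <- alpha_c - gamma * b_center
  beta_group ~ dnorm(%.10g, %.10g)
  gamma ~ dnorm(0, 1.0E-4)
  mu_b ~ dnorm(0, 1.0E-4)
  sigma_u ~ dnorm(0, 4.0E-4) T(0,)
  sigma_e ~ dnorm(0, 4.0E-4) T(0,)
  sigma_b ~ dnorm(0, 4.0E-4) T(0,)
  tau_u <- 1 / (sigma_u * sigma_u)
  tau_e <- 1 / (sigma_e * sigma_e)
  tau_b <- 1 / (sigma_b * sigma_b)
}", beta_prior_mean, beta_prior_prec)
}

run_jags <- function(model_string, data, monitor, config, inits_fn = NULL) {
  inits <- lapply(seq_len(config$n_chains), function(ch) {
    base <- list(.RNG.name = "base::Mersenne-Twister",
                 .RNG.seed = derive_seed(config$seed, "chain") + ch)
    if (!is.null(inits_fn)) c(base, inits_fn(ch)) else base
  })
  n_adapt <- max(100L, floor(config$n_burnin / 2L))
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = config$n_chains,
                             n.adapt = n_adapt, quiet = TRUE)
  extra_burn <- max(0L, config$n_burnin - n_adapt)
  if (extra_burn > 0) stats::update(model, extra_burn, progress.bar = "none")
  sims <- rjags::coda.samples(model, variable.names = monitor,
                              n.iter = config$n_samples,
                              progress.bar = "none")
  params <- colnames(sims[[1L]])
  draws <- array(NA_real_,
                 dim = c(config$n_chains, config$n_samples, length(params)),
                 dimnames = list(NULL, NULL, params))
  for (ch in seq_along(sims)) {
    draws[ch, , ] <- as.matrix(sims[[ch]])
  }
  new_ni_draws(draws, config = config)
}

#' Fit the primary-outcome linear mixed model
#'
#' Bayesian baseline-adjusted linear mixed model for total weekly activity
#' minutes, with a school random intercept and one-step posterior-predictive
#' imputation of missing baseline and follow-up outcomes: missing values are
#' stochastic nodes updated jointly with the parameters at every MCMC
#' iteration. `beta_group` is the between-arm difference at follow-up
#' (adapted minus original), controlling for baseline.
#'
#' Uninformative priors are Normal(0, 100^2) on location parameters and
#' Half-Normal(0, 50) on the SDs (vague on the minutes scale). The
#' informative mode replaces the `beta_group` prior with user-supplied
#' Normal hyperparameters.
#'
#' @param data an `ni_data` from [build_analysis_dataset()].
#' @param config an [mcmc_config()].
#' @param prior_mode `"uninformative"` (default) or `"informative"`.
#' @param beta_prior length-2 numeric `c(mean, sd)` for the `beta_group`
#'   prior; required when `prior_mode = "informative"`.
#' @param monitor_imputations if `TRUE` (default), draws of the imputed
#'   outcomes are retained alongside the model parameters.
#' @return An object of class `ni_lmm` wrapping an `ni_draws` (access with
#'   `$draws`), the data, and fit metadata. Parameters: `alpha`,
#'   `beta_group`, `gamma`, `sigma_u`, `sigma_e`, `mu_b`, `sigma_b`,
#'   `u[j]`, plus `yb[i]`/`yf[i]` nodes for imputed outcomes.
#' @export
fit_lmm <- function(data, config = mcmc_config(),
                    prior_mode = c("uninformative", "informative"),
                    beta_prior = NULL, monitor_imputations = TRUE) {
  stopifnot(inherits(data, "ni_data"))
  prior_mode <- match.arg(prior_mode)
  if (prior_mode == "informative") {
    if (is.null(beta_prior) || length(beta_prior) != 2L ||
        beta_prior[2L] <= 0) {
      ni_abort(
        "Informative prior mode requires `beta_prior = c(mean, sd)`, sd > 0.",
        "niclust_config_error")
    }
    bp_mean <- beta_prior[1L]
    bp_prec <- 1 / beta_prior[2L]^2
  } else {
    bp_mean <- 0
    bp_prec <- 1e-4
  }

  td <- data$teachers
  arm_n <- table(data$schools$arm)
  if (length(arm_n) < 2L || any(arm_n < 2L)) {
    ni_abort("At least 2 schools per arm are required.",
             "niclust_model_error")
  }
  observed <- !is.na(td$baseline) | !is.na(td$followup)
  by_arm <- tapply(observed, td$arm, any)
  if (!all(by_arm)) {
    ni_abort("An arm has no observed outcomes at either timepoint.",
             "niclust_model_error")
  }
  no_obs_school <- setdiff(td$school_index, td$school_index[observed])
  if (length(no_obs_school)) {
    ni_abort(sprintf("School(s) %s have no observed outcomes.",
                     paste(no_obs_school, collapse = ", ")),
             "niclust_model_error")
  }

  schools <- dplyr::arrange(data$schools, .data$school_index)
  b_center <- mean(td$baseline, na.rm = TRUE)
  if (!is.finite(b_center)) b_center <- 0
  jd <- list(N = nrow(td), J = data$n_schools,
             yb = td$baseline, yf = td$followup,
             school = td$school_index,
             armj = as.integer(schools$arm == "adapted"),
             b_center = b_center)
  monitor <- c("alpha", "beta_group", "gamma", "sigma_u", "sigma_e",
               "mu_b", "sigma_b", "u")
  if (monitor_imputations) {
    imp <- c(sprintf("yb[%d]", which(is.na(td$baseline))),
             sprintf("yf[%d]", which(is.na(td$followup))))
    monitor <- c(monitor, imp)
  }
  # data-based initial values (jittered per chain) keep the chains out of
  # the alpha-versus-mean(u) ridge that traps default inits when the
  # residual variance is very small
  cc <- !is.na(td$baseline) & !is.na(td$followup)
  init_gamma <- if (sum(cc) > 3 && sd(td$baseline[cc]) > 0) {
    cov(td$baseline[cc], td$followup[cc]) / var(td$baseline[cc])
  } else 0
  yf_bar <- mean(td$followup, na.rm = TRUE)
  resid_sd <- if (sum(cc) > 3) {
    sd(td$followup[cc] - init_gamma * td$baseline[cc])
  } else sd(td$followup, na.rm = TRUE)
  school_means <- tapply(td$followup, td$school_index, mean, na.rm = TRUE)
  school_means <- school_means[as.character(seq_len(data$n_schools))]
  school_means[!is.finite(school_means)] <- yf_bar
  inits_fn <- function(ch) {
    jit <- function(x, f = 0.05 * (ch - 1)) x * (1 + f)
    list(alpha_c = jit(yf_bar), beta_group = 0, gamma = jit(init_gamma),
         m = as.numeric(school_means),
         mu_b = jit(mean(td$baseline, na.rm = TRUE)),
         sigma_b = jit(max(sd(td$baseline, na.rm = TRUE), 0.1)),
         sigma_e = jit(max(resid_sd, 0.1)),
         sigma_u = jit(max(resid_sd / 4, 0.05)))
  }
  draws <- run_jags(lmm_model_string(bp_mean, bp_prec), jd, monitor, config,
                    inits_fn = inits_fn)
  structure(
    list(draws = draws, data = data, prior_mode = prior_mode,
         beta_prior = beta_prior, config = config,
         n_imputed_baseline = sum(is.na(td$baseline)),
         n_imputed_followup = sum(is.na(td$followup))),
    class = "ni_lmm"
  )
}

#' @export
print.ni_lmm <- function(x, ...) {
  cat("<ni_lmm> baseline-adjusted linear mixed model, school random intercept\n")
  cat(sprintf("  %d teachers in %d schools; %d + %d outcomes imputed (%s prior)\n",
              nrow(x$data$teachers), x$data$n_schools,
              x$n_imputed_baseline, x$n_imputed_followup, x$prior_mode))
  print(tidy(x))
  invisible(x)
}

core_lmm_params <- function() {
  c("alpha", "beta_group", "gamma", "sigma_u", "sigma_e", "mu_b", "sigma_b")
}

#' @rdname fit_lmm
#' @param x an `ni_lmm`.
#' @param ... unused.
#' @export
tidy.ni_lmm <- function(x, ...) {
  dg <- x$draws$diagnostics
  dg[dg$parameter %in% core_lmm_params(), ]
}

#' @export
glance.ni_lmm <- function(x, ...) {
  dg <- tidy(x)
  tibble::tibble(
    n_teachers = nrow(x$data$teachers),
    n_schools = x$data$n_schools,
    n_imputed = x$n_imputed_baseline + x$n_imputed_followup,
    prior_mode = x$prior_mode,
    max_rhat = max(dg$rhat), min_ess = min(dg$ess)
  )
}
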
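#' MCMC configuration
#'
#' Defaults mirror the trial analysis: 4 chains, 10,000 burn-in iterations
#' and 10,000 retained post-burn-in draws per chain. Tests and examples use
#' far smaller runs.
#'
#' @param n_chains number of chains.
#' @param n_burnin burn-in (adaptation) iterations per chain, discarded.
#' @param n_samples retained post-burn-in iterations per chain.
#' @param seed integer seed; every chain derives its own stream from it.
#' @param target_accept target acceptance rate for the adaptive
#'   random-walk proposal used by [sample_posterior()].
#' @return A list of class `ni_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_burnin = 10000L,
                        n_samples = 10000L, seed = 1L,
                        target_accept = 0.234) {
  check_count(n_chains, "n_chains")
  check_count(n_burnin, "n_burnin", min = 0L)
  check_count(n_samples, "n_samples")
  check_prob(target_accept, "target_accept")
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed),
                 target_accept = target_accept),
            class = "ni_mcmc_config")
}

# Wrap a (chain, iteration, parameter) array as posterior samples with
# diagnostics computed over the post-burn-in draws.
new_ni_draws <- function(draws, config = NULL, divergences = 0L) {
  stopifnot(is.array(draws), length(dim(draws)) == 3L)
  diagnostics <- compute_diagnostics(draws)
  structure(list(draws = draws, diagnostics = diagnostics,
                 divergences = divergences, config = config),
            class = "ni_draws")
}

compute_diagnostics <- function(draws) {
  params <- dimnames(draws)[[3L]]
  if (is.null(params)) params <- paste0("par", seq_len(dim(draws)[3L]))
  multi <- dim(draws)[1L] >= 2L && dim(draws)[2L] >= 10L
  tibble::tibble(
    parameter = params,
    mean = apply(draws, 3L, mean),
    sd = apply(draws, 3L, sd),
    q2.5 = apply(draws, 3L, quantile, probs = 0.025, names = FALSE),
    q97.5 = apply(draws, 3L, quantile, probs = 0.975, names = FALSE),
    rhat = if (multi) gelman_rubin(draws) else NA_real_,
    ess = if (multi) effective_sample_size(draws) else NA_real_
  )
}

#' Extract draws of one parameter
#'
#' @param x an `ni_draws` object.
#' @param parameter parameter name.
#' @param collapse if `TRUE` (default) return one vector pooling all
#'   chains; otherwise an iterations-by-chains matrix.
#' @return Numeric vector or matrix of posterior draws.
#' @export
extract_draws <- function(x, parameter, collapse = TRUE) {
  stopifnot(inherits(x, "ni_draws"))
  if (!parameter %in% dimnames(x$draws)[[3L]]) {
    ni_abort(sprintf("No parameter named '%s' in draws.", parameter),
             "niclust_summary_error")
  }
  m <- t(x$draws[, , parameter, drop = TRUE])
  if (dim(x$draws)[1L] == 1L) m <- matrix(x$draws[1L, , parameter], ncol = 1L)
  if (collapse) as.vector(m) else m
}

#' @export
print.ni_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<ni_draws> %d chains x %d iterations x %d parameters\n",
              d[1L], d[2L], d[3L]))
  if (x$divergences > 0) {
    cat(sprintf("  %d divergent/undefined proposals flagged\n",
                x$divergences))
  }
  print(x$diagnostics, n = min(nrow(x$diagnostics), 12L))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries
#'
#' One row per parameter with posterior mean, SD, equal-tailed 95% interval
#' and convergence diagnostics.
#'
#' @param x an `ni_draws` object.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.ni_draws <- function(x, ...) {
  x$diagnostics
}

#' @export
glance.ni_draws <- function(x, ...) {
  d <- dim(x$draws)
  tibble::tibble(n_chains = d[1L], n_samples = d[2L], n_parameters = d[3L],
                 max_rhat = max(x$diagnostics$rhat),
                 min_ess = min(x$diagnostics$ess),
                 divergences = x$divergences)
}

#' Convert posterior draws to a long tibble
#'
#' @param x an `ni_draws`.
#' @param ... unused.
#' @return Tibble with columns `chain`, `iteration`, `parameter`, `value`.
#' @export
as_tibble.ni_draws <- function(x, ...) {
  d <- dim(x$draws)
  params <- dimnames(x$draws)[[3L]]
  tibble::tibble(
    chain = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    iteration = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    parameter = rep(params, each = d[1L] * d[2L]),
    value = as.vector(x$draws)
  )
}

#' Export draws to CSV
#'
#' Writes the long (chain, iteration, parameter, value) form for external
#' inspection.
#'
#' @param x an `ni_draws`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(x, path) {
  readr::write_csv(as_tibble.ni_draws(x), path)
  invisible(path)
}

#' Sample a posterior by adaptive random-walk Metropolis
#'
#' General-purpose posterior sampler over an unnormalised log-density.
#' During burn-in the multivariate normal proposal adapts its global scale
#' towards the target acceptance rate (Robbins-Monro) and its covariance to
#' the running covariance of the chain history; adaptation is frozen after
#' burn-in so retained draws form a valid Markov chain. The sampler's
#' contract is distributional correctness, enforced by a conjugate-model
#' oracle suite in the package tests.
#'
#' @param log_density function taking a parameter vector, returning the
#'   unnormalised log posterior density. Must be finite at `init`.
#' @param init numeric initial parameter vector (named names are kept).
#' @param config an [mcmc_config()].
#' @return An `ni_draws` with dimensions
#'   `(n_chains, n_samples, length(init))`; proposals where the density
#'   evaluated non-finite are counted in `$divergences`.
#' @examples
#' post <- sample_posterior(function(th) -0.5 * th^2, init = c(theta = 0),
#'                          mcmc_config(2, 200, 500, seed = 1))
#' tidy(post)
#' @export
sample_posterior <- function(log_density, init, config = mcmc_config()) {
  stopifnot(inherits(config, "ni_mcmc_config"))
  init_num <- as.numeric(unlist(init))
  d <- length(init_num)
  nm <- names(unlist(init))
  if (is.null(nm) || any(!nzchar(nm))) nm <- paste0("par", seq_len(d))
  lp0 <- log_density(init_num)
  if (!is.finite(lp0)) {
    ni_abort("log_density is not finite at `init`.", "niclust_init_error")
  }

  n_total <- config$n_burnin + config$n_samples
  draws <- array(NA_real_,
                 dim = c(config$n_chains, config$n_samples, d),
                 dimnames = list(NULL, NULL, nm))
  divergences <- 0L

  for (ch in seq_len(config$n_chains)) {
    set.seed(derive_seed(config$seed, "chain") + ch)
    x <- init_num + rnorm(d, 0, 0.01 * pmax(abs(init_num), 1))
    lp <- log_density(x)
    if (!is.finite(lp)) {
      x <- init_num
      lp <- lp0
    }
    log_scale <- log(2.38 / sqrt(d))
    chol_cov <- diag(pmax(abs(init_num) * 0.1, 0.1), d)
    run_mean <- x
    run_m2 <- matrix(0, d, d)
    kept <- 0L
    for (i in seq_len(n_total)) {
      prop <- x + exp(log_scale) * as.vector(chol_cov %*% rnorm(d))
      lp_prop <- log_density(prop)
      if (!is.finite(lp_prop)) {
        divergences <- divergences + 1L
        acc_prob <- 0
      } else {
        acc_prob <- min(1, exp(lp_prop - lp))
        if (runif(1L) < acc_prob) {
          x <- prop
          lp <- lp_prop
        }
      }
      if (i <= config$n_burnin) {
        # Robbins-Monro scale adaptation + running covariance update
        log_scale <- log_scale +
          (acc_prob - config$target_accept) / max(i, 10)^0.6
        delta <- x - run_mean
        run_mean <- run_mean + delta / (i + 1)
        run_m2 <- run_m2 + tcrossprod(delta, x - run_mean)
        if (i >= max(50L, 5L * d) && i %% 25L == 0L) {
          emp_cov <- run_m2 / i + diag(1e-8, d)
          ch_try <- tryCatch(chol(emp_cov), error = function(e) NULL)
          if (!is.null(ch_try)) chol_cov <- t(ch_try)
        }
      } else {
        kept <- kept + 1L
        draws[ch, kept, ] <- x
      }
    }
  }
  new_ni_draws(draws, config = config, divergences = divergences)
}
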
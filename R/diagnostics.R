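# Convergence diagnostics for multi-chain posterior samples.
#
# Inputs are normalised to an iterations x chains matrix per parameter;
# ni_draws objects, 3-d (chain, iteration, parameter) arrays, and plain
# iteration x chain matrices are all accepted.

as_chain_matrices <- function(samples) {
  if (inherits(samples, "ni_draws")) samples <- samples$draws
  if (is.matrix(samples)) {
    return(list(par = samples))
  }
  if (is.array(samples) && length(dim(samples)) == 3L) {
    params <- dimnames(samples)[[3L]]
    if (is.null(params)) params <- paste0("par", seq_len(dim(samples)[3L]))
    out <- lapply(seq_len(dim(samples)[3L]),
                  function(k) t(samples[, , k, drop = TRUE]))
    if (dim(samples)[1L] == 1L) {
      out <- lapply(seq_len(dim(samples)[3L]),
                    function(k) matrix(samples[1L, , k], ncol = 1L))
    }
    names(out) <- params
    return(out)
  }
  ni_abort("Samples must be an ni_draws, a 3-d array, or a matrix.",
           "niclust_diagnostic_error")
}

check_chain_dims <- function(m) {
  if (ncol(m) < 2L) {
    ni_abort("At least 2 chains are required for this diagnostic.",
             "niclust_diagnostic_error")
  }
  if (nrow(m) < 10L) {
    ni_abort("At least 10 draws per chain are required.",
             "niclust_diagnostic_error")
  }
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic multi-chain convergence statistic: the square root of the
#' ratio of the pooled-variance estimate
#' \eqn{\widehat{var}^+ = \frac{n-1}{n} W + \frac{B}{n}} to the mean
#' within-chain variance \eqn{W}, where \eqn{B/n} is the variance of the
#' chain means. Values near 1 indicate the chains have mixed over the same
#' distribution. The statistic is floored at 1 (the raw ratio falls just
#' below 1 when between-chain variance is zero).
#'
#' @param samples an `ni_draws`, a `(chain, iteration, parameter)` array,
#'   or an iterations-by-chains matrix for a single parameter.
#' @return Named numeric vector, one statistic per parameter.
#' @examples
#' x <- array(rnorm(4000), dim = c(4, 1000, 1),
#'            dimnames = list(NULL, NULL, "theta"))
#' gelman_rubin(x) < 1.01
#' @export
gelman_rubin <- function(samples) {
  mats <- as_chain_matrices(samples)
  vapply(mats, function(m) {
    check_chain_dims(m)
    n <- nrow(m)
    W <- mean(apply(m, 2L, var))
    B_over_n <- var(colMeans(m))
    if (W == 0) {
      # all chains constant: identical constants have converged trivially
      return(if (B_over_n == 0) 1 else Inf)
    }
    var_plus <- (n - 1) / n * W + B_over_n
    max(1, sqrt(var_plus / W))
  }, numeric(1L))
}

#' Effective sample size
#'
#' Autocorrelation-adjusted number of independent draws, combined across
#' chains: \eqn{ESS = mn / (1 + 2\sum_t \rho_t)} with the combined-chain
#' autocorrelations \eqn{\rho_t} truncated by Geyer's initial monotone
#' positive sequence. Capped at the total number of draws. Chains with zero
#' variance are degenerate; they yield `ESS = 1` with a warning rather than
#' an error.
#'
#' @inheritParams gelman_rubin
#' @return Named numeric vector, one ESS per parameter.
#' @export
effective_sample_size <- function(samples) {
  mats <- as_chain_matrices(samples)
  vapply(mats, function(m) {
    check_chain_dims(m)
    n <- nrow(m)
    n_chain <- ncol(m)
    chain_vars <- apply(m, 2L, var)
    W <- mean(chain_vars)
    if (W == 0 || !is.finite(W)) {
      warn("Degenerate (constant) chain: effective sample size set to 1.",
           class = "niclust_degenerate_ess")
      return(1)
    }
    var_plus <- (n - 1) / n * W + var(colMeans(m))
    lag_max <- min(n - 1L, max(100L, floor(10 * sqrt(n))))
    acov <- vapply(seq_len(n_chain), function(c) {
      a <- acf(m[, c], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)
      as.vector(a$acf)
    }, numeric(lag_max + 1L))
    mean_acov <- rowMeans(acov)
    rho <- 1 - (W - mean_acov) / var_plus  # rho[t + 1] is lag t
    # Geyer initial monotone positive pair sums: P_k = rho_{2k} + rho_{2k+1}
    max_pairs <- floor(length(rho) / 2L)
    prev <- Inf
    sum_pairs <- 0
    for (k in seq_len(max_pairs)) {
      p <- rho[2L * k - 1L] + rho[2L * k]
      if (p < 0 && k > 1L) break
      p <- min(p, prev)
      prev <- p
      sum_pairs <- sum_pairs + p
    }
    tau <- max(-1 + 2 * sum_pairs, 1 / (n_chain * n))
    min(n_chain * n, n_chain * n / tau)
  }, numeric(1L))
}

#' Monte-Carlo standard error of a posterior mean
#'
#' `sd / sqrt(ESS)` per parameter; the yardstick used throughout the test
#' suite's "within k Monte-Carlo SEs" checks.
#'
#' @inheritParams gelman_rubin
#' @return Named numeric vector.
#' @export
mcse_mean <- function(samples) {
  mats <- as_chain_matrices(samples)
  ess <- effective_sample_size(samples)
  sds <- vapply(mats, function(m) sd(as.vector(m)), numeric(1L))
  sds / sqrt(ess)
}

#' Convergence gate used in reports
#'
#' Flags a run whose worst Gelman-Rubin statistic exceeds `rhat_max` or
#' whose smallest effective sample size falls below `ess_min`. Results are
#' still produced; the flag is surfaced prominently in pipeline logs.
#'
#' @param draws an `ni_draws`.
#' @param rhat_max,ess_min gate thresholds.
#' @return Logical scalar, `TRUE` when the gate trips, with a warning.
#' @export
convergence_warning <- function(draws, rhat_max = 1.05, ess_min = 400) {
  stopifnot(inherits(draws, "ni_draws"))
  dg <- draws$diagnostics
  bad <- dg$rhat > rhat_max | dg$ess < ess_min
  if (any(bad, na.rm = TRUE)) {
    warn(sprintf(
      "Convergence gate: %d parameter(s) with Rhat > %.2f or ESS < %d (worst: %s).",
      sum(bad, na.rm = TRUE), rhat_max, ess_min,
      paste(head(dg$parameter[which(bad)], 3L), collapse = ", ")),
      class = "niclust_convergence_warning")
    return(TRUE)
  }
  FALSE
}
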
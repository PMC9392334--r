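#' @importFrom rlang abort warn .data
#' @importFrom tibble as_tibble
#' @importFrom stats rnorm rgamma rbinom runif quantile var sd setNames
#'   rexp acf dnorm qnorm median cov
#' @importFrom utils head tail
NULL

# internal: consistent error with a class so tests can assert on it
ni_abort <- function(msg, class) {
  abort(msg, class = c(class, "niclust_error"))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    ni_abort(sprintf("`%s` must be a probability in [0, 1].", name),
             "niclust_config_error")
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(!is.finite(x) | x <= 0) else any(!is.finite(x) | x < 0)
  if (!is.numeric(x) || bad) {
    ni_abort(sprintf("`%s` must be %s.", name,
                     if (strict) "strictly positive" else "non-negative"),
             "niclust_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    ni_abort(sprintf("`%s` must be an integer >= %d.", name, min),
             "niclust_config_error")
  }
  invisible(as.integer(x))
}

# Derive a stage-specific seed from a master seed so that independent
# pipeline stages (generation, MCMC, bootstrap) use distinct, reproducible
# streams. Kept within 32-bit integer range.
derive_seed <- function(seed, stage) {
  offsets <- c(generate = 10007L, missing = 20011L, invalid = 30011L,
               mcmc = 40009L, bootstrap = 50021L, chain = 60013L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483587)
}
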
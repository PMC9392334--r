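#' @importFrom ggplot2 autoplot ggplot aes geom_density geom_vline geom_line
#'   facet_wrap labs theme_minimal geom_histogram
#' @export
ggplot2::autoplot

#' Posterior density of a difference with its noninferiority margin
#'
#' @param draws numeric vector of minutes-scale difference draws, or an
#'   `ni_result`.
#' @param margin an `ni_margin` or numeric delta (taken from the result if
#'   one is supplied).
#' @return A ggplot.
#' @export
plot_posterior <- function(draws, margin = NULL) {
  if (inherits(draws, "ni_result")) {
    margin <- draws$margin
    draws <- draws$minutes_draws
  }
  df <- tibble::tibble(difference = draws)
  p <- ggplot(df, aes(x = .data$difference)) +
    geom_density(fill = "grey80", colour = "grey30") +
    labs(x = "Between-group difference (minutes/week)", y = "Density") +
    theme_minimal()
  if (!is.null(margin)) {
    p <- p + geom_vline(xintercept = margin_delta(margin),
                        linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @export
autoplot.ni_result <- function(object, ...) {
  plot_posterior(object) +
    labs(title = sprintf("%s: P(noninferior) = %.1f%%", object$outcome,
                         100 * object$prob_noninferior))
}

#' Trace plot of posterior draws
#'
#' @param x an `ni_draws` (or a fit carrying one).
#' @param parameters parameter names to show (default: first 4).
#' @return A ggplot with one panel per parameter.
#' @export
plot_trace <- function(x, parameters = NULL) {
  if (inherits(x, "ni_lmm") || inherits(x, "ni_hurdle")) x <- x$draws
  stopifnot(inherits(x, "ni_draws"))
  all_pars <- dimnames(x$draws)[[3L]]
  if (is.null(parameters)) parameters <- head(all_pars, 4L)
  long <- as_tibble.ni_draws(x)
  long <- long[long$parameter %in% parameters, ]
  ggplot(long, aes(x = .data$iteration, y = .data$value,
                   colour = factor(.data$chain))) +
    geom_line(alpha = 0.7, linewidth = 0.3) +
    facet_wrap(~parameter, scales = "free_y") +
    labs(colour = "chain", x = "Iteration", y = "Value") +
    theme_minimal()
}

#' @export
autoplot.ni_draws <- function(object, parameters = NULL, ...) {
  plot_trace(object, parameters)
}

#' Bootstrap distribution of a cost quantity
#'
#' @param x an `ni_cost_bootstrap`.
#' @param quantity one of the rows of `x$intervals`.
#' @return A ggplot histogram with the 95% interval bounds marked.
#' @export
plot_cost_bootstrap <- function(x, quantity = "per_school_difference") {
  stopifnot(inherits(x, "ni_cost_bootstrap"))
  df <- tibble::tibble(value = x$replicates[, quantity])
  iv <- x$intervals[x$intervals$quantity == quantity, ]
  ggplot(df, aes(x = .data$value)) +
    geom_histogram(bins = 40, fill = "grey80", colour = "grey30") +
    geom_vline(xintercept = c(iv$lower, iv$upper), linetype = "dashed") +
    labs(x = sprintf("%s (AUD)", quantity), y = "Replicates") +
    theme_minimal()
}
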
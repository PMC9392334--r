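#' Derive a noninferiority margin from a reference-trial bound
#'
#' The margin is the largest acceptable loss of effect, derived as
#' \deqn{|\Delta| = (1 - \text{retained proportion}) \times
#'   \text{reference lower bound},}
#' where the reference lower bound is the lower confidence limit of the
#' comparator's effect in the trial that established it, and the retained
#' proportion is the fraction of that effect the new delivery model must
#' preserve (commonly 0.5). When a higher outcome is better the margin is
#' negative: the new model must not fall below the comparator by more than
#' \eqn{|\Delta|}.
#'
#' @param retained_proportion fraction of the reference effect retained,
#'   in `[0, 1]`.
#' @param reference_lower_bound positive lower confidence bound of the
#'   reference effect (outcome units, here minutes/week).
#' @param direction `"higher_is_better"` (default) or `"lower_is_better"`.
#' @return A list of class `ni_margin` with fields `retained_proportion`,
#'   `reference_lower_bound`, `delta` (signed) and `direction`.
#' @examples
#' compute_margin(0.50, 32.8)$delta  # -16.4
#' @export
compute_margin <- function(retained_proportion, reference_lower_bound,
                           direction = c("higher_is_better",
                                         "lower_is_better")) {
  direction <- match.arg(direction)
  check_prob(retained_proportion, "retained_proportion")
  check_positive(reference_lower_bound, "reference_lower_bound")
  magnitude <- (1 - retained_proportion) * reference_lower_bound
  delta <- if (direction == "higher_is_better") -magnitude else magnitude
  structure(
    list(retained_proportion = retained_proportion,
         reference_lower_bound = reference_lower_bound,
         delta = delta,
         direction = direction),
    class = "ni_margin"
  )
}

#' Construct a margin directly from its value
#'
#' For outcomes whose margin is given as a constant rather than derived
#' (the component outcomes' margins here), wrap the signed value in an
#' `ni_margin` without a derivation trail.
#'
#' @param delta signed margin value.
#' @param direction as in [compute_margin()].
#' @return An `ni_margin`.
#' @export
margin_from_delta <- function(delta,
                              direction = c("higher_is_better",
                                            "lower_is_better")) {
  direction <- match.arg(direction)
  if (direction == "higher_is_better" && delta > 0) {
    ni_abort("delta must be <= 0 when higher outcomes are better.",
             "niclust_config_error")
  }
  structure(list(retained_proportion = NA_real_,
                 reference_lower_bound = NA_real_,
                 delta = delta, direction = direction),
            class = "ni_margin")
}

#' Default per-outcome noninferiority margins
#'
#' Total activity uses the derived margin (retained proportion 0.50,
#' reference lower bound 32.8 min/week, hence -16.4); the component
#' outcomes use the pre-specified constants -8.25 (energisers), -1.58
#' (active lessons) and -0.95 (PE) minutes/week.
#'
#' @return Named list of `ni_margin` objects.
#' @export
default_margins <- function() {
  list(
    total = compute_margin(0.50, 32.8),
    energisers = margin_from_delta(-8.25),
    active_lessons = margin_from_delta(-1.58),
    pe = margin_from_delta(-0.95)
  )
}

#' Interval-based noninferiority decision
#'
#' Noninferiority is declared when the lower bound of the 95% credible
#' interval for the between-arm difference does not cross the margin; a
#' lower bound exactly at the margin counts as non-crossing.
#'
#' @param credible_interval_lower lower 95% credible bound of the
#'   difference (new minus reference, outcome units).
#' @param margin an `ni_margin` (direction must be `higher_is_better`) or a
#'   signed numeric delta.
#' @return `TRUE` iff `credible_interval_lower >= delta`.
#' @examples
#' noninferior_by_interval(-19.18, compute_margin(0.5, 32.8))  # FALSE
#' @export
noninferior_by_interval <- function(credible_interval_lower, margin) {
  delta <- margin_delta(margin)
  credible_interval_lower >= delta
}

margin_delta <- function(margin) {
  if (inherits(margin, "ni_margin")) {
    if (margin$direction != "higher_is_better") {
      ni_abort("Decision rules here assume higher outcomes are better.",
               "niclust_config_error")
    }
    margin$delta
  } else if (is.numeric(margin) && length(margin) == 1L) {
    margin
  } else {
    ni_abort("`margin` must be an ni_margin or a single number.",
             "niclust_config_error")
  }
}

#' @export
print.ni_margin <- function(x, ...) {
  if (is.na(x$retained_proportion)) {
    cat(sprintf("<ni_margin> delta = %g (%s; given constant)\n",
                x$delta, x$direction))
  } else {
    cat(sprintf(
      "<ni_margin> delta = %g = %s(1 - %g) x %g (%s)\n",
      x$delta, if (x$direction == "higher_is_better") "-" else "",
      x$retained_proportion, x$reference_lower_bound, x$direction))
  }
  invisible(x)
}
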
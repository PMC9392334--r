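#' Strategy codes recognised in cost ledgers
#'
#' Delivery costs are coded by implementation strategy: the staff
#' educational session (original-model only), the in-school champion
#' training workshop, ongoing project-officer support, the physical
#' activity equipment pack, and a salaries/distribution item covering
#' project-officer time and resource distribution not itemised per school.
#'
#' @return Character vector of valid strategy codes.
#' @export
cost_strategy_vocabulary <- function() {
  c("staff_session", "champion_training", "ongoing_support",
    "equipment_pack", "salaries_distribution")
}

#' Read an itemised cost ledger
#'
#' CSV with header `arm,strategy_code,school_id,amount`; amounts are AUD
#' (2019 base year), non-negative. Items with `school_id = "shared"` are
#' arm-level; when `n_schools` is supplied they are apportioned equally
#' across that arm's schools.
#'
#' @param path ledger CSV path.
#' @param n_schools optional named vector `c(original = , adapted = )`; when
#'   given, shared items are split into per-school rows of
#'   `amount / n_schools`.
#' @param vocabulary allowed strategy codes.
#' @return A tibble of cost items.
#' @export
read_ledger <- function(path, n_schools = NULL,
                        vocabulary = cost_strategy_vocabulary()) {
  if (!file.exists(path)) {
    ni_abort(sprintf("Ledger file not found: %s", path), "niclust_io_error")
  }
  items <- readr::read_csv(
    path,
    col_types = readr::cols(arm = readr::col_character(),
                            strategy_code = readr::col_character(),
                            school_id = readr::col_character(),
                            amount = readr::col_double()),
    progress = FALSE)
  bad_arm <- setdiff(unique(items$arm), c("original", "adapted"))
  if (length(bad_arm)) {
    ni_abort(sprintf("Unknown arm label(s) in ledger: %s.",
                     paste(bad_arm, collapse = ", ")),
             "niclust_validation_error")
  }
  if (any(is.na(items$amount)) || any(items$amount < 0)) {
    ni_abort("Ledger amounts must be non-negative.",
             "niclust_validation_error")
  }
  bad_code <- setdiff(unique(items$strategy_code), vocabulary)
  if (length(bad_code)) {
    ni_abort(sprintf("Strategy code(s) outside the declared vocabulary: %s.",
                     paste(bad_code, collapse = ", ")),
             "niclust_validation_error")
  }
  if (!is.null(n_schools)) {
    items <- apportion_shared(items, n_schools)
  }
  items
}

#' @rdname read_ledger
#' @param items a tibble of cost items.
#' @export
apportion_shared <- function(items, n_schools) {
  out <- purrr::map_dfr(c("original", "adapted"), function(a) {
    arm_items <- items[items$arm == a, ]
    shared <- arm_items[arm_items$school_id == "shared", ]
    direct <- arm_items[arm_items$school_id != "shared", ]
    if (!nrow(shared)) return(direct)
    n <- n_schools[[a]]
    ids <- unique(direct$school_id)
    if (length(ids) < n) {
      ids <- c(ids, sprintf("%s_school_%02d", a,
                            seq_len(n - length(ids)) + length(ids)))
    }
    ids <- sort(ids)[seq_len(n)]
    split_rows <- tidyr::crossing(shared[, c("arm", "strategy_code")],
                                  school_id = ids)
    split_rows <- dplyr::left_join(
      split_rows, shared[, c("arm", "strategy_code", "amount")],
      by = c("arm", "strategy_code"))
    split_rows$amount <- split_rows$amount / n
    dplyr::bind_rows(direct, split_rows)
  })
  out
}

#' Write a cost ledger to CSV
#'
#' @param items tibble of cost items.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(items, path) {
  readr::write_csv(items[, c("arm", "strategy_code", "school_id", "amount")],
                   path)
  invisible(path)
}

#' Summarise delivery costs by arm
#'
#' Point estimates for the cost-minimisation comparison: per-arm totals,
#' per-school means (total / schools), per-strategy subtotals, and
#' original-minus-adapted differences. Per-school means are rounded to
#' whole AUD for reporting; all arithmetic is unrounded.
#'
#' @param items tibble of cost items.
#' @param n_schools named vector `c(original = , adapted = )` of schools
#'   per arm.
#' @return A list of class `ni_cost_summary` with tibbles `by_arm` and
#'   `by_strategy` plus scalar `total_difference` and
#'   `per_school_difference` (original minus adapted).
#' @export
summarise_costs <- function(items, n_schools = c(original = 24,
                                                 adapted = 24)) {
  if (any(n_schools <= 0)) {
    ni_abort("`n_schools` must be positive for both arms.",
             "niclust_config_error")
  }
  if (!all(c("original", "adapted") %in% unique(items$arm))) {
    ni_abort("Ledger must contain items for both arms.",
             "niclust_validation_error")
  }
  by_arm <- dplyr::summarise(dplyr::group_by(items, .data$arm),
                             total = sum(.data$amount), .groups = "drop")
  by_arm$n_schools <- as.numeric(n_schools[by_arm$arm])
  by_arm$per_school = by_arm$total / by_arm$n_schools
  by_arm$per_school_reported <- round(by_arm$per_school)
  by_strategy <- dplyr::summarise(
    dplyr::group_by(items, .data$arm, .data$strategy_code),
    total = sum(.data$amount), .groups = "drop")
  by_strategy$per_school <- by_strategy$total /
    as.numeric(n_schools[by_strategy$arm])
  tot <- setNames(by_arm$total, by_arm$arm)
  ps <- setNames(by_arm$per_school, by_arm$arm)
  structure(
    list(by_arm = by_arm, by_strategy = by_strategy,
         total_difference = tot[["original"]] - tot[["adapted"]],
         per_school_difference = ps[["original"]] - ps[["adapted"]],
         n_schools = n_schools),
    class = "ni_cost_summary"
  )
}

#' @export
print.ni_cost_summary <- function(x, ...) {
  cat("<ni_cost_summary> (AUD, 2019 base year)\n")
  for (i in seq_len(nrow(x$by_arm))) {
    r <- x$by_arm[i, ]
    cat(sprintf("  %-8s total $%s, $%d per school (n = %d)\n", r$arm,
                format(round(r$total), big.mark = ","),
                r$per_school_reported, r$n_schools))
  }
  cat(sprintf("  saving (original - adapted): $%s total, $%d per school\n",
              format(round(x$total_difference), big.mark = ","),
              round(x$per_school_difference)))
  invisible(x)
}

#' @export
tidy.ni_cost_summary <- function(x, ...) {
  x$by_arm
}

#' Per-school delivery costs
#'
#' School-level cost totals per arm, with shared items spread equally; the
#' resampling unit for [bootstrap_uncertainty()].
#'
#' @inheritParams summarise_costs
#' @return Tibble with `arm`, `school_id`, `cost`.
#' @export
per_school_costs <- function(items, n_schools = c(original = 24,
                                                  adapted = 24)) {
  items <- apportion_shared(items, n_schools)
  dplyr::summarise(dplyr::group_by(items, .data$arm, .data$school_id),
                   cost = sum(.data$amount), .groups = "drop")
}

#' Bootstrap uncertainty intervals for delivery costs
#'
#' Non-parametric bootstrap over schools (the costing unit), resampled with
#' replacement within arm. Each replicate recomputes per-arm totals,
#' per-school means, and original-minus-adapted differences; 95% intervals
#' are the 2.5/97.5 percentiles over replicates.
#'
#' @param school_costs tibble from [per_school_costs()] (columns `arm`,
#'   `school_id`, `cost`), with at least 2 schools per arm.
#' @param n_reps bootstrap replications (default 1000).
#' @param seed integer seed; identical seed and reps give identical
#'   intervals.
#' @return A list of class `ni_cost_bootstrap`: tibble `intervals` with one
#'   row per quantity (`total_original`, `total_adapted`, `mean_original`,
#'   `mean_adapted`, `total_difference`, `per_school_difference`) and the
#'   replicate draws.
#' @export
bootstrap_uncertainty <- function(school_costs, n_reps = 1000L, seed = 1L) {
  check_count(n_reps, "n_reps")
  co <- school_costs$cost[school_costs$arm == "original"]
  ca <- school_costs$cost[school_costs$arm == "adapted"]
  if (length(co) < 2L || length(ca) < 2L) {
    ni_abort("Bootstrap needs at least 2 schools per arm.",
             "niclust_bootstrap_error")
  }
  set.seed(derive_seed(seed, "bootstrap"))
  no <- length(co)
  na <- length(ca)
  reps <- vapply(seq_len(n_reps), function(r) {
    ro <- co[sample.int(no, no, replace = TRUE)]
    ra <- ca[sample.int(na, na, replace = TRUE)]
    c(total_original = sum(ro), total_adapted = sum(ra),
      mean_original = mean(ro), mean_adapted = mean(ra),
      total_difference = sum(ro) - sum(ra),
      per_school_difference = mean(ro) - mean(ra))
  }, numeric(6L))
  point <- c(total_original = sum(co), total_adapted = sum(ca),
             mean_original = mean(co), mean_adapted = mean(ca),
             total_difference = sum(co) - sum(ca),
             per_school_difference = mean(co) - mean(ca))
  intervals <- tibble::tibble(
    quantity = rownames(reps),
    estimate = as.numeric(point[rownames(reps)]),
    lower = apply(reps, 1L, quantile, probs = 0.025, names = FALSE),
    upper = apply(reps, 1L, quantile, probs = 0.975, names = FALSE)
  )
  structure(list(intervals = intervals, replicates = t(reps),
                 n_reps = n_reps, seed = seed),
            class = "ni_cost_bootstrap")
}

#' @export
print.ni_cost_bootstrap <- function(x, ...) {
  cat(sprintf("<ni_cost_bootstrap> %d replications\n", x$n_reps))
  print(x$intervals)
  invisible(x)
}

#' @export
tidy.ni_cost_bootstrap <- function(x, ...) {
  x$intervals
}

#' Project per-school savings to a scale-up target
#'
#' @param per_school_saving saving per school (AUD, >= 0).
#' @param n_target_schools number of schools in the scale-up target; when
#'   the target is a "400+"-style floor the product is a lower bound.
#' @return Projected saving in AUD.
#' @examples
#' scaleup_projection(373, 400)   # 149200
#' scaleup_projection(373, 1600)  # 596800
#' @export
scaleup_projection <- function(per_school_saving, n_target_schools) {
  check_positive(per_school_saving, "per_school_saving", strict = FALSE)
  check_positive(n_target_schools, "n_target_schools", strict = FALSE)
  per_school_saving * n_target_schools
}

#' Relative per-school cost reduction
#'
#' `100 * (original - adapted) / original`, the percentage by which the
#' adapted delivery model reduces per-school cost. Note this equals the
#' extra schools reachable per fixed budget only approximately; the exact
#' schools-per-budget increase is `100 * (original / adapted - 1)`, also
#' returned.
#'
#' @param per_school_original,per_school_adapted per-school costs (AUD);
#'   `per_school_original` must be positive.
#' @return A list with `reduction_pct` and `schools_per_budget_pct`.
#' @examples
#' relative_cost_reduction(1057, 684)$reduction_pct  # 35.29...
#' @export
relative_cost_reduction <- function(per_school_original,
                                    per_school_adapted) {
  if (per_school_original <= 0) {
    ni_abort("`per_school_original` must be positive.",
             "niclust_config_error")
  }
  list(
    reduction_pct =
      100 * (per_school_original - per_school_adapted) / per_school_original,
    schools_per_budget_pct =
      100 * (per_school_original / per_school_adapted - 1)
  )
}

#' Path to the packaged synthetic cost ledger
#'
#' A synthetic reconstruction of a two-arm delivery-cost ledger: per-school
#' strategy costs (staff session $287/school in the original arm only;
#' champion training $484, ongoing support $86, equipment pack $85 per
#' school in both arms) with a fixed zero-sum spread across schools, plus a
#' shared salaries/distribution balancing item per arm, so that arm totals
#' are exactly $25,375 (original) and $16,421 (adapted) over 24 schools
#' each. The itemised strategy costs do not sum to the arm totals on their
#' own; the balancing item carries the non-itemised remainder.
#'
#' @return File path of the CSV within the installed package.
#' @export
example_ledger_path <- function() {
  system.file("extdata", "pace_costs_synthetic.csv", package = "niclust",
              mustWork = TRUE)
}
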
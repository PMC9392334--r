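logbook_header <- function() {
  c("school_id", "teacher_id", "arm", "region", "geolocation", "timepoint",
    "minutes_pe", "minutes_sport", "minutes_energisers",
    "minutes_active_lessons")
}

#' Write teacher logbook records to CSV
#'
#' Writes the logbook dialect: UTF-8 CSV with header
#' `school_id,teacher_id,arm,region,geolocation,timepoint,minutes_pe,
#' minutes_sport,minutes_energisers,minutes_active_lessons`, one row per
#' teacher-timepoint, empty cell meaning missing. The derived
#' `total_minutes` and any internal bookkeeping columns are not written.
#'
#' @param records a logbook tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_logbooks <- function(records, path) {
  readr::write_csv(records[, logbook_header()], path, na = "")
  invisible(path)
}

#' Read teacher logbook records from CSV
#'
#' Parses the logbook CSV dialect (see [write_logbooks()]). Blank outcome
#' cells become `NA` (missing), never zero. `total_minutes` is recomputed as
#' the sum over the components that are present; it is `NA` only when every
#' component is missing.
#'
#' @param path path to a logbook CSV.
#' @return A tibble of teacher-week records.
#' @export
read_logbooks <- function(path) {
  if (!file.exists(path)) {
    ni_abort(sprintf("Logbook file not found: %s", path), "niclust_io_error")
  }
  spec <- readr::cols(
    school_id = readr::col_character(),
    teacher_id = readr::col_character(),
    arm = readr::col_character(),
    region = readr::col_character(),
    geolocation = readr::col_character(),
    timepoint = readr::col_character(),
    minutes_pe = readr::col_double(),
    minutes_sport = readr::col_double(),
    minutes_energisers = readr::col_double(),
    minutes_active_lessons = readr::col_double()
  )
  records <- suppressWarnings(
    readr::read_csv(path, col_types = spec, na = "", progress = FALSE))
  probs <- readr::problems(records)
  if (nrow(probs) > 0) {
    ni_abort(sprintf("Malformed logbook row(s) at line(s) %s of %s.",
                     paste(unique(probs$row), collapse = ", "), path),
             "niclust_parse_error")
  }
  missing_cols <- setdiff(logbook_header(), names(records))
  if (length(missing_cols)) {
    ni_abort(sprintf("Logbook file lacks column(s): %s.",
                     paste(missing_cols, collapse = ", ")),
             "niclust_parse_error")
  }
  bad_arm <- setdiff(unique(records$arm), c("original", "adapted"))
  if (length(bad_arm)) {
    ni_abort(sprintf("Unknown arm label(s): %s.",
                     paste(bad_arm, collapse = ", ")),
             "niclust_validation_error")
  }
  bad_tp <- setdiff(unique(records$timepoint), c("baseline", "followup"))
  if (length(bad_tp)) {
    ni_abort(sprintf("Unknown timepoint label(s): %s.",
                     paste(bad_tp, collapse = ", ")),
             "niclust_validation_error")
  }
  comp <- records[, c("minutes_pe", "minutes_sport", "minutes_energisers",
                      "minutes_active_lessons")]
  any_present <- rowSums(!is.na(comp)) > 0
  total <- rowSums(comp, na.rm = TRUE)
  total[!any_present] <- NA_real_
  records$total_minutes <- total
  records
}

#' Apply the weekly-minutes validity filter
#'
#' Teacher logbook totals above the validity threshold (by default more than
#' 250 minutes of scheduled activity across the five-day school week) are
#' implausible and excluded from analysis. Records whose total is missing
#' pass through as missing-outcome records, not as invalid.
#'
#' @param records a logbook tibble with `total_minutes`.
#' @param threshold validity threshold in minutes/week (default 250).
#' @param inclusive if `TRUE` (default) a total exactly at the threshold is
#'   valid ("no more than 250 minutes"); if `FALSE`, it is excluded.
#' @return A list with tibbles `valid` and `excluded` (the latter with a
#'   `reason` column, `"invalid_total"`), and counts `n_valid`/`n_excluded`.
#' @examples
#' rec <- generate_trial(trial_scenario(n_schools_per_arm = 4, seed = 2))
#' validity_filter(rec)$n_excluded
#' @export
validity_filter <- function(records, threshold = 250, inclusive = TRUE) {
  bad <- if (inclusive) {
    !is.na(records$total_minutes) & records$total_minutes > threshold
  } else {
    !is.na(records$total_minutes) & records$total_minutes >= threshold
  }
  excluded <- records[bad, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "invalid_total"
  else excluded$reason <- character(0)
  list(valid = records[!bad, , drop = FALSE],
       excluded = excluded,
       n_valid = sum(!bad),
       n_excluded = sum(bad))
}

#' Assemble the intention-to-treat analysis dataset
#'
#' Pivots valid teacher-week records into the structures the outcome models
#' consume: a wide teacher table (one row per teacher with baseline and
#' follow-up totals, either possibly missing), a long component table, and
#' dense integer school codes. Teachers observed at only one timepoint are
#' retained with the other timepoint missing, in keeping with
#' intention-to-treat analysis of all available valid data.
#'
#' @param valid_records valid records, e.g. `validity_filter(...)$valid`.
#' @param exclusion_log optional tibble of excluded records (carried
#'   through for flow summaries).
#' @return An object of class `ni_data`: a list with tibbles `teachers`
#'   (columns `teacher_id`, `school_id`, `school_index`, `arm`,
#'   `arm_indicator`, `baseline`, `followup`), `components` (long, with
#'   `component`, `timepoint01`, `minutes`), `schools`, and `exclusion_log`.
#' @export
build_analysis_dataset <- function(valid_records, exclusion_log = NULL) {
  rec <- valid_records
  chk <- dplyr::distinct(rec, .data$teacher_id, .data$school_id, .data$arm)
  dup <- chk$teacher_id[duplicated(chk$teacher_id)]
  if (length(dup)) {
    ni_abort(sprintf(
      "Teacher(s) %s appear in more than one school or arm.",
      paste(unique(dup), collapse = ", ")), "niclust_consistency_error")
  }
  if (anyDuplicated(rec[, c("teacher_id", "timepoint")])) {
    ni_abort("Duplicate teacher-timepoint records.",
             "niclust_consistency_error")
  }

  schools <- dplyr::distinct(rec, .data$school_id, .data$arm)
  schools <- dplyr::arrange(schools, .data$school_id)
  schools$school_index <- seq_len(nrow(schools))

  teachers <- tidyr::pivot_wider(
    rec[, c("teacher_id", "school_id", "arm", "timepoint", "total_minutes")],
    names_from = "timepoint", values_from = "total_minutes"
  )
  for (tp in c("baseline", "followup")) {
    if (!tp %in% names(teachers)) teachers[[tp]] <- NA_real_
  }
  teachers <- dplyr::left_join(teachers,
                               schools[, c("school_id", "school_index")],
                               by = "school_id")
  teachers$arm_indicator <- as.integer(teachers$arm == "adapted")
  teachers <- dplyr::arrange(teachers, .data$school_index, .data$teacher_id)
  teachers <- teachers[, c("teacher_id", "school_id", "school_index", "arm",
                           "arm_indicator", "baseline", "followup")]

  components <- tidyr::pivot_longer(
    rec[, c("teacher_id", "school_id", "arm", "timepoint",
            "minutes_energisers", "minutes_active_lessons", "minutes_pe")],
    cols = dplyr::starts_with("minutes_"),
    names_to = "component", names_prefix = "minutes_",
    values_to = "minutes"
  )
  components <- dplyr::left_join(components,
                                 schools[, c("school_id", "school_index")],
                                 by = "school_id")
  components$arm_indicator <- as.integer(components$arm == "adapted")
  components$timepoint01 <- as.integer(components$timepoint == "followup")

  if (is.null(exclusion_log)) {
    exclusion_log <- rec[0, , drop = FALSE]
    exclusion_log$reason <- character(0)
  }
  structure(
    list(teachers = teachers, components = components, schools = schools,
         exclusion_log = tibble::as_tibble(exclusion_log),
         n_schools = nrow(schools)),
    class = "ni_data"
  )
}

#' @export
print.ni_data <- function(x, ...) {
  cat("<ni_data>\n")
  arm_n <- table(x$schools$arm)
  cat(sprintf("  %d schools (%s), %d teachers, %d excluded records\n",
              x$n_schools,
              paste(sprintf("%s: %d", names(arm_n), arm_n), collapse = ", "),
              nrow(x$teachers), nrow(x$exclusion_log)))
  cat(sprintf("  baseline observed %d/%d, follow-up observed %d/%d\n",
              sum(!is.na(x$teachers$baseline)), nrow(x$teachers),
              sum(!is.na(x$teachers$followup)), nrow(x$teachers)))
  invisible(x)
}
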
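test_that("logbook CSV parsing handles complete rows and blank cells", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "school_id,teacher_id,arm,region,geolocation,timepoint,minutes_pe,minutes_sport,minutes_energisers,minutes_active_lessons",
    "S01,S01T01,original,CC,major_city,baseline,40,60,10,5",
    "S01,S01T01,original,CC,major_city,followup,50,70,,5"
  ), tf)
  rec <- read_logbooks(tf)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$total_minutes[1L], 115)
  # blank energiser cell: missing, not zero; total over present components
  expect_true(is.na(rec$minutes_energisers[2L]))
  expect_equal(rec$total_minutes[2L], 125)
})

test_that("logbook parsing rejects bad labels and malformed rows", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "school_id,teacher_id,arm,region,geolocation,timepoint,minutes_pe,minutes_sport,minutes_energisers,minutes_active_lessons",
    "S01,S01T01,control,CC,major_city,baseline,40,60,10,5"
  ), tf)
  expect_error(read_logbooks(tf), class = "niclust_validation_error")
  writeLines(c(
    "school_id,teacher_id,arm,region,geolocation,timepoint,minutes_pe,minutes_sport,minutes_energisers,minutes_active_lessons",
    "S01,S01T01,original,CC,major_city,midpoint,40,60,10,5"
  ), tf)
  expect_error(read_logbooks(tf), class = "niclust_validation_error")
  writeLines(c(
    "school_id,teacher_id,arm,region,geolocation,timepoint,minutes_pe,minutes_sport,minutes_energisers,minutes_active_lessons",
    "S01,S01T01,original,CC,major_city,baseline,forty,60,10,5"
  ), tf)
  expect_error(read_logbooks(tf), class = "niclust_parse_error")
  expect_error(read_logbooks(file.path(tempdir(), "nope.csv")),
               class = "niclust_io_error")
})

test_that("synthetic logbooks round-trip through CSV exactly", {
  rec <- generate_trial(trial_scenario(n_schools_per_arm = 4, seed = 5))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_logbooks(rec, tf)
  back <- read_logbooks(tf)
  for (cn in c("school_id", "teacher_id", "arm", "timepoint", "minutes_pe",
               "minutes_sport", "minutes_energisers",
               "minutes_active_lessons", "total_minutes")) {
    expect_identical(back[[cn]], rec[[cn]])
  }
})

test_that("validity filter excludes strictly above threshold, keeps boundary", {
  rec <- tibble::tibble(
    school_id = "S01", teacher_id = paste0("T", 1:4), arm = "original",
    region = "CC", geolocation = "major_city", timepoint = "baseline",
    minutes_pe = c(260, 150, 250, NA), minutes_sport = 0,
    minutes_energisers = 0, minutes_active_lessons = 0,
    total_minutes = c(260, 150, 250, NA)
  )
  out <- validity_filter(rec)
  expect_equal(out$n_excluded, 1L)
  expect_equal(out$excluded$total_minutes, 260)
  expect_equal(out$excluded$reason, "invalid_total")
  # 250 exactly is valid ("no more than 250"); NA passes as missing-outcome
  expect_setequal(out$valid$total_minutes[!is.na(out$valid$total_minutes)],
                  c(150, 250))
  expect_equal(nrow(out$valid), 3L)
  strict <- validity_filter(rec, inclusive = FALSE)
  expect_equal(strict$n_excluded, 2L)
})

test_that("validity filter is idempotent and conserves records", {
  rec <- generate_trial(trial_scenario(seed = 6))
  out <- validity_filter(rec)
  expect_equal(out$n_valid + out$n_excluded, nrow(rec))
  again <- validity_filter(out$valid)
  expect_equal(again$n_excluded, 0L)
  expect_identical(again$valid, out$valid)
})

test_that("analysis dataset keeps single-timepoint teachers and dense codes", {
  rec <- generate_trial(trial_scenario(seed = 7))
  filt <- validity_filter(rec)
  ds <- build_analysis_dataset(filt$valid, filt$excluded)
  expect_s3_class(ds$teachers, "tbl_df")
  expect_equal(sort(unique(ds$teachers$school_index)), 1:48)
  expect_equal(ds$n_schools, 48L)
  # teachers with only one observed timepoint retained, other masked
  one_sided <- ds$teachers[is.na(ds$teachers$followup) &
                             !is.na(ds$teachers$baseline), ]
  expect_gt(nrow(one_sided), 0L)
  # every teacher in exactly one school, every school in exactly one arm
  expect_equal(anyDuplicated(ds$teachers$teacher_id), 0L)
  expect_equal(nrow(dplyr::distinct(ds$schools, school_id, arm)),
               dplyr::n_distinct(ds$schools$school_id))
})

test_that("analysable teacher count equals generated minus excluded", {
  rec <- generate_trial(trial_scenario(seed = 8, missing_rate_baseline = 0,
                                       missing_rate_followup = 0))
  filt <- validity_filter(rec)
  # every injected record is excluded (a few naturally high totals may
  # accompany them, as in real logbooks)
  expect_equal(sum(filt$excluded$.invalid_injected),
               sum(rec$.invalid_injected))
  expect_gte(filt$n_excluded, sum(rec$.invalid_injected))
  ds <- build_analysis_dataset(filt$valid, filt$excluded)
  n_teachers_generated <- dplyr::n_distinct(rec$teacher_id)
  # exclusions hit single records; those teachers keep the other timepoint
  expect_equal(nrow(ds$teachers), n_teachers_generated)
  n_fup_excluded <- sum(filt$excluded$timepoint == "followup")
  expect_equal(sum(!is.na(ds$teachers$followup)),
               n_teachers_generated - n_fup_excluded)
})

test_that("a teacher in two schools or arms is a consistency error", {
  rec <- generate_trial(trial_scenario(n_schools_per_arm = 2, seed = 9))
  rec$school_id[rec$teacher_id == rec$teacher_id[1L]] <-
    c("S01", "S02")[seq_len(sum(rec$teacher_id == rec$teacher_id[1L])) %% 2 + 1]
  expect_error(build_analysis_dataset(rec),
               class = "niclust_consistency_error")
})
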
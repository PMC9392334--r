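write_mini_ledger <- function(lines, path) {
  writeLines(c("arm,strategy_code,school_id,amount", lines), path)
}

test_that("ledger parsing validates and apportions shared items", {
  tf <- withr::local_tempfile(fileext = ".csv")
  write_mini_ledger(c("original,champion_training,O01,484",
                      "original,equipment_pack,O01,85",
                      "adapted,champion_training,A01,484"), tf)
  items <- read_ledger(tf)
  expect_equal(nrow(items), 3L)

  write_mini_ledger(c("original,salaries_distribution,shared,2400",
                      "adapted,champion_training,A01,484"), tf)
  app <- read_ledger(tf, n_schools = c(original = 24, adapted = 24))
  shared_rows <- app[app$strategy_code == "salaries_distribution", ]
  expect_equal(nrow(shared_rows), 24L)
  expect_true(all(shared_rows$amount == 100))

  write_mini_ledger("original,champion_training,O01,-5", tf)
  expect_error(read_ledger(tf), class = "niclust_validation_error")
  write_mini_ledger("placebo,champion_training,O01,5", tf)
  expect_error(read_ledger(tf), class = "niclust_validation_error")
  write_mini_ledger("original,helicopter_rides,O01,5", tf)
  expect_error(read_ledger(tf), class = "niclust_validation_error")
})

test_that("the packaged ledger round-trips and reproduces the arm totals", {
  items <- read_ledger(example_ledger_path())
  tf <- withr::local_tempfile(fileext = ".csv")
  write_ledger(items, tf)
  expect_identical(read_ledger(tf), items)

  cs <- summarise_costs(items, c(original = 24, adapted = 24))
  by_arm <- cs$by_arm
  expect_equal(by_arm$total[by_arm$arm == "original"], 25375)
  expect_equal(by_arm$total[by_arm$arm == "adapted"], 16421)
  expect_equal(by_arm$per_school_reported[by_arm$arm == "original"], 1057)
  expect_equal(by_arm$per_school_reported[by_arm$arm == "adapted"], 684)
  expect_equal(cs$total_difference, 8954)
  expect_equal(round(cs$per_school_difference), 373)
  # conservation: strategy subtotals sum to the arm totals exactly
  strat <- tapply(cs$by_strategy$total, cs$by_strategy$arm, sum)
  expect_equal(as.numeric(strat[c("original", "adapted")]), c(25375, 16421))
})

test_that("equal ledgers in both arms give zero differences", {
  rows <- c(sprintf("original,champion_training,O%02d,500", 1:4),
            sprintf("adapted,champion_training,A%02d,500", 1:4))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_mini_ledger(rows, tf)
  cs <- summarise_costs(read_ledger(tf), c(original = 4, adapted = 4))
  expect_equal(cs$total_difference, 0)
  expect_equal(cs$per_school_difference, 0)
  expect_error(summarise_costs(read_ledger(tf), c(original = 0, adapted = 4)),
               class = "niclust_config_error")
})

test_that("bootstrap collapses to the point for degenerate cost data", {
  sc <- tibble::tibble(arm = rep(c("original", "adapted"), each = 6),
                       school_id = paste0("S", 1:12),
                       cost = rep(c(700, 700), each = 6))
  bt <- bootstrap_uncertainty(sc, n_reps = 200, seed = 4)
  iv <- bt$intervals
  m_o <- iv[iv$quantity == "mean_original", ]
  expect_equal(unname(c(m_o$lower, m_o$upper)), c(700, 700))
  d <- iv[iv$quantity == "per_school_difference", ]
  expect_equal(unname(c(d$lower, d$upper)), c(0, 0))
})

test_that("bootstrap is deterministic in the seed and covers its point
           estimate", {
  set.seed(10)
  sc <- tibble::tibble(arm = rep(c("original", "adapted"), each = 24),
                       school_id = paste0("S", 1:48),
                       cost = c(rgamma(24, 20, 1 / 50), rgamma(24, 20, 1 / 35)))
  a <- bootstrap_uncertainty(sc, n_reps = 500, seed = 11)
  b <- bootstrap_uncertainty(sc, n_reps = 500, seed = 11)
  expect_identical(a$intervals, b$intervals)
  c2 <- bootstrap_uncertainty(sc, n_reps = 500, seed = 12)
  expect_false(identical(a$intervals, c2$intervals))
  with(a$intervals, {
    expect_true(all(lower <= estimate & estimate <= upper))
  })
  one <- sc[c(1, 25), ]
  expect_error(bootstrap_uncertainty(one, 100, 1),
               class = "niclust_bootstrap_error")
})

test_that("scale-up projections and relative reduction match direct
           arithmetic", {
  expect_equal(scaleup_projection(373, 400), 149200)
  expect_equal(scaleup_projection(373, 1600), 596800)
  expect_equal(scaleup_projection(0, 1000), 0)
  rr <- relative_cost_reduction(1057, 684)
  expect_equal(round(rr$reduction_pct), 35)
  expect_equal(rr$reduction_pct, 100 * 373 / 1057)
  # the schools-per-budget increase is a different quantity
  expect_equal(rr$schools_per_budget_pct, 100 * (1057 / 684 - 1))
  expect_gt(rr$schools_per_budget_pct, rr$reduction_pct)
  expect_equal(relative_cost_reduction(500, 500)$reduction_pct, 0)
  expect_equal(relative_cost_reduction(100, 50)$reduction_pct, 50)
  expect_error(relative_cost_reduction(0, 10),
               class = "niclust_config_error")
})
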
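#' Configuration for an end-to-end analysis run
#'
#' Bundles the inputs of one run: either a synthetic [trial_scenario()] or a
#' logbook CSV path, the per-outcome margins, prior settings, MCMC and
#' bootstrap sizes, and a single master seed from which every stage
#' (generation, sampling, bootstrap) deterministically derives its own
#' stream.
#'
#' @param scenario an [trial_scenario()], or `NULL` when reading logbooks.
#' @param logbook_path path to a logbook CSV (ignored when `scenario` is
#'   given).
#' @param ledger_path path to a cost ledger CSV; defaults to the packaged
#'   synthetic ledger. Set `include_cost = FALSE` to skip costing.
#' @param margins named list of `ni_margin` objects for `total`,
#'   `energisers`, `active_lessons`, `pe`.
#' @param prior_mode,beta_prior see [fit_lmm()].
#' @param n_chains,n_burnin,n_samples MCMC sizes per chain.
#' @param n_bootstrap bootstrap replications for cost intervals.
#' @param n_schools_per_arm schools per arm for cost denominators (used
#'   when costing without a trial dataset).
#' @param validity_threshold,validity_inclusive see [validity_filter()].
#' @param include_cost run the cost-minimisation stage.
#' @param components which hurdle outcomes to fit.
#' @param seed master seed.
#' @param verbose print stage progress.
#' @return A list of class `ni_run_config`.
#' @export
run_config <- function(scenario = trial_scenario(),
                       logbook_path = NULL,
                       ledger_path = example_ledger_path(),
                       margins = default_margins(),
                       prior_mode = "uninformative",
                       beta_prior = NULL,
                       n_chains = 4L, n_burnin = 1000L, n_samples = 1000L,
                       n_bootstrap = 1000L,
                       n_schools_per_arm = 24L,
                       validity_threshold = 250,
                       validity_inclusive = TRUE,
                       include_cost = TRUE,
                       components = c("energisers", "active_lessons", "pe"),
                       seed = 1L,
                       verbose = FALSE) {
  if (is.null(scenario) && is.null(logbook_path)) {
    ni_abort("Provide either `scenario` or `logbook_path`.",
             "niclust_config_error")
  }
  if (!is.null(logbook_path) && is.null(scenario) &&
      !file.exists(logbook_path)) {
    ni_abort(sprintf("Logbook path does not exist: %s", logbook_path),
             "niclust_config_error")
  }
  if (include_cost && !file.exists(ledger_path)) {
    ni_abort(sprintf("Ledger path does not exist: %s", ledger_path),
             "niclust_config_error")
  }
  structure(
    list(scenario = scenario, logbook_path = logbook_path,
         ledger_path = ledger_path, margins = margins,
         prior_mode = prior_mode, beta_prior = beta_prior,
         n_chains = as.integer(n_chains), n_burnin = as.integer(n_burnin),
         n_samples = as.integer(n_samples),
         n_bootstrap = as.integer(n_bootstrap),
         n_schools_per_arm = as.integer(n_schools_per_arm),
         validity_threshold = validity_threshold,
         validity_inclusive = validity_inclusive,
         include_cost = include_cost, components = components,
         seed = as.integer(seed), verbose = verbose),
    class = "ni_run_config"
  )
}

stage_msg <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data ingest (synthetic generation or logbook CSV),
#' the weekly-minutes validity filter, the intention-to-treat dataset
#' build, the primary-outcome linear mixed model, the component gamma-hurdle
#' models, per-outcome noninferiority summaries, and (optionally) the
#' bootstrap cost-minimisation — then assembles a report bundle. Every
#' stage derives its seed from the master seed, so a rerun with the same
#' configuration reproduces the results tables byte for byte.
#'
#' @param config an [run_config()].
#' @param out_dir optional directory; when given, writes
#'   `results_table.csv`, `diagnostics.csv`, `flow_summary.csv`,
#'   `cost_summary.csv` + `cost_intervals.csv` (if costing ran), and
#'   `run_log.txt`.
#' @return A list of class `ni_report`: `results_table`, `results` (list of
#'   `ni_result`), `fits`, `flow`, `cost` (summary, bootstrap), `dataset`,
#'   `convergence_flags`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "ni_run_config"))

  stage <- "ingest"
  report <- tryCatch({
    if (!is.null(config$scenario)) {
      scenario <- config$scenario
      scenario$seed <- config$seed
      stage_msg(config, "[ingest] generating synthetic trial (seed %d)",
                scenario$seed)
      records <- generate_trial(scenario)
    } else {
      stage_msg(config, "[ingest] reading logbooks from %s",
                config$logbook_path)
      records <- read_logbooks(config$logbook_path)
    }

    stage <- "validity_filter"
    filt <- validity_filter(records, threshold = config$validity_threshold,
                            inclusive = config$validity_inclusive)
    stage_msg(config, "[filter] %d valid, %d invalid records",
              filt$n_valid, filt$n_excluded)

    stage <- "dataset"
    dataset <- build_analysis_dataset(filt$valid,
                                      exclusion_log = filt$excluded)
    flow <- make_flow_summary(dataset)

    stage <- "primary_lmm"
    mcmc <- mcmc_config(config$n_chains, config$n_burnin, config$n_samples,
                        seed = derive_seed(config$seed, "mcmc"))
    stage_msg(config, "[lmm] %d chains x (%d + %d)", mcmc$n_chains,
              mcmc$n_burnin, mcmc$n_samples)
    convergence_flags <- character(0)
    note_convergence <- function(fit, label) {
      tripped <- withCallingHandlers(
        suppressWarnings(convergence_warning(fit$draws)),
        warning = function(w) invokeRestart("muffleWarning"))
      if (tripped) {
        convergence_flags <<- c(convergence_flags, label)
      }
    }
    lmm <- fit_lmm(dataset, config = mcmc, prior_mode = config$prior_mode,
                   beta_prior = config$beta_prior)
    note_convergence(lmm, "total")
    results <- list(
      total = noninferiority_result(
        "total", extract_draws(lmm$draws, "beta_group"),
        config$margins$total,
        variance_ratio = variance_ratio(lmm),
        descriptives = outcome_descriptives(dataset, "total"))
    )

    stage <- "hurdle_models"
    hurdles <- list()
    for (comp in config$components) {
      stage_msg(config, "[hurdle] %s", comp)
      fit <- fit_gamma_hurdle(dataset, comp, config = mcmc)
      note_convergence(fit, comp)
      hurdles[[comp]] <- fit
      results[[comp]] <- noninferiority_result(
        comp, hurdle_minutes_difference(fit), config$margins[[comp]],
        ratio_draws = exponentiate_interaction(fit),
        variance_ratio = variance_ratio(fit),
        descriptives = outcome_descriptives(dataset, comp))
    }

    stage <- "ni_summary"
    results_table <- build_results_table(results)

    stage <- "costing"
    cost <- NULL
    if (config$include_cost) {
      n_schools <- c(original = config$n_schools_per_arm,
                     adapted = config$n_schools_per_arm)
      items <- read_ledger(config$ledger_path)
      summary <- summarise_costs(items, n_schools)
      school_costs <- per_school_costs(items, n_schools)
      boot <- bootstrap_uncertainty(school_costs,
                                    n_reps = config$n_bootstrap,
                                    seed = config$seed)
      cost <- list(summary = summary, bootstrap = boot,
                   school_costs = school_costs)
    }

    structure(
      list(results_table = results_table, results = results,
           fits = c(list(total = lmm), hurdles),
           flow = flow, cost = cost, dataset = dataset,
           convergence_flags = convergence_flags, config = config),
      class = "ni_report")
  }, niclust_error = function(e) {
    ni_abort(sprintf("Pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)),
             "niclust_pipeline_error")
  })

  if (!is.null(out_dir)) {
    write_report(report, out_dir)
  }
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- report$config
  readr::write_csv(report$results_table,
                   file.path(out_dir, "results_table.csv"))
  diagnostics <- purrr::map_dfr(names(report$fits), function(nm) {
    dg <- tidy(report$fits[[nm]])
    dg$outcome <- nm
    dg
  })
  readr::write_csv(diagnostics, file.path(out_dir, "diagnostics.csv"))
  readr::write_csv(report$flow, file.path(out_dir, "flow_summary.csv"))
  if (!is.null(report$cost)) {
    readr::write_csv(report$cost$summary$by_arm,
                     file.path(out_dir, "cost_summary.csv"))
    readr::write_csv(report$cost$bootstrap$intervals,
                     file.path(out_dir, "cost_intervals.csv"))
  }
  m <- config$margins$total
  log_lines <- c(
    "niclust run log",
    sprintf("master seed: %d", config$seed),
    sprintf("stage seeds: generate %d, mcmc %d, bootstrap %d",
            derive_seed(config$seed, "generate"),
            derive_seed(config$seed, "mcmc"),
            derive_seed(config$seed, "bootstrap")),
    sprintf("mcmc: %d chains x (%d burn-in + %d samples)",
            config$n_chains, config$n_burnin, config$n_samples),
    sprintf(
      "primary margin: delta %.4g (retained proportion %.3g, reference lower bound %.4g)",
      m$delta, m$retained_proportion, m$reference_lower_bound),
    sprintf("records excluded as invalid: %d",
            nrow(report$dataset$exclusion_log)),
    if (length(report$convergence_flags)) {
      sprintf("WARNING convergence gate tripped for: %s",
              paste(report$convergence_flags, collapse = ", "))
    } else "convergence gate: passed"
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.ni_report <- function(x, ...) {
  cat("<ni_report>\n")
  print(x$results_table)
  if (!is.null(x$cost)) print(x$cost$summary)
  if (length(x$convergence_flags)) {
    cat(sprintf("  !! convergence gate tripped: %s\n",
                paste(x$convergence_flags, collapse = ", ")))
  }
  invisible(x)
}

#' Participant-flow summary
#'
#' Counts, per arm and timepoint, the schools and teachers enrolled, the
#' records excluded as invalid, and the teachers and schools contributing
#' analysable (valid, non-missing) data.
#'
#' @param dataset an `ni_data`.
#' @param exclusion_log excluded-record tibble; defaults to the one carried
#'   by `dataset`.
#' @return A tibble with one row per arm-by-timepoint.
#' @export
make_flow_summary <- function(dataset, exclusion_log = dataset$exclusion_log) {
  stopifnot(inherits(dataset, "ni_data"))
  td <- dataset$teachers
  ex <- exclusion_log
  grid <- tidyr::crossing(arm = c("original", "adapted"),
                          timepoint = c("baseline", "followup"))
  purrr::pmap_dfr(grid, function(arm, timepoint) {
    td_a <- td[td$arm == arm, ]
    ex_a <- ex[ex$arm == arm & ex$timepoint == timepoint, , drop = FALSE]
    enrolled_schools <- unique(c(td_a$school_id, ex$school_id[ex$arm == arm]))
    enrolled_teachers <- unique(c(td_a$teacher_id,
                                  ex$teacher_id[ex$arm == arm]))
    y <- if (timepoint == "baseline") td_a$baseline else td_a$followup
    analysed_teachers <- td_a$teacher_id[!is.na(y)]
    tibble::tibble(
      arm = arm, timepoint = timepoint,
      n_schools_enrolled = length(enrolled_schools),
      n_teachers_enrolled = length(enrolled_teachers),
      n_records_invalid = nrow(ex_a),
      n_teachers_analysed = length(analysed_teachers),
      n_schools_analysed =
        length(unique(td_a$school_id[!is.na(y)]))
    )
  })
}
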
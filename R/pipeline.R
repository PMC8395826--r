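#' Pipeline configuration
#'
#' Assembles the stage configurations for an end-to-end run: cohort
#' generation, screening policy, plate/measurement parameters, and
#' evaluation settings. The single `seed` propagates to every stochastic
#' stage.
#'
#' @param cohort A [cohort_config()].
#' @param policy A [screening_policy()].
#' @param mode Measurement mode for [run_programme()] (`"truth"` or
#'   `"plate"`).
#' @param noise_sd Ct noise (plate mode).
#' @param sweep_cutoffs Candidate cut-offs for the post hoc sweep.
#' @param level Confidence level for all intervals.
#' @param seed Integer master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            policy = screening_policy(),
                            mode = "truth",
                            noise_sd = 0.15,
                            sweep_cutoffs = seq(6, 0, by = -1),
                            level = 0.95,
                            seed = 1L) {
  cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, policy = policy, mode = mode,
                 noise_sd = noise_sd, sweep_cutoffs = sweep_cutoffs,
                 level = level, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Chains cohort simulation, the screening programme, performance
#' evaluation, and the post hoc cut-off sweep. When `out_dir` is given, the
#' cohort and outcome tables (CSV), the sweep table (CSV), the metrics
#' report (JSON), and a manifest with seed and package version are written
#' there.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return A list of class `pipeline_result`: `cohort`, `run`
#'   ([run_programme()] result), `performance`
#'   ([evaluate_performance()] report), `sweep` ([cutoff_sweep()] table),
#'   and `config`.
#' @examples
#' cfg <- pipeline_config(cohort = cohort_config(n_newborns = 500,
#'                                               n_non_newborns = 0),
#'                        seed = 7)
#' res <- run_pipeline(cfg)
#' res$run$log$referral_rate
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- simulate_cohort(config$cohort)
  run <- run_programme(cohort, config$policy, mode = config$mode,
                       seed = config$seed + 1L, noise_sd = config$noise_sd)
  perf <- evaluate_performance(run, cohort, level = config$level)
  sweep <- if (nrow(perf$referred) > 0) {
    cutoff_sweep(perf$referred, config$sweep_cutoffs, config$level)
  } else {
    NULL
  }
  res <- structure(list(cohort = cohort, run = run, performance = perf,
                        sweep = sweep, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    write_outcomes_csv(run$outcomes, file.path(out_dir, "outcomes.csv"))
    if (!is.null(sweep)) {
      utils::write.csv(sweep, file.path(out_dir, "sweep.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(report_as_list(res),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(seed = config$seed,
           package = "trecscreen",
           version = as.character(utils::packageVersion("trecscreen")),
           n_newborns = config$cohort$n_newborns,
           n_non_newborns = config$cohort$n_non_newborns,
           mode = config$mode,
           created = format(Sys.time(), tz = "UTC")),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

# flatten a pipeline result into plain lists for JSON serialisation
report_as_list <- function(res) {
  perf <- res$performance
  conf <- lapply(perf$confusion, function(tb) {
    tb[c("outcome", "tp", "fp", "tn", "fn", "n_excluded", "n_total")]
  })
  inc <- perf$incidence
  list(
    log = res$run$log,
    confusion = conf,
    metrics = perf$metrics,
    rates = perf$rates,
    incidence = inc[c("cases", "denominator", "rate", "lower", "upper",
                      "one_in", "one_in_lower", "one_in_upper")],
    sweep = res$sweep
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$run)
  cat("\n")
  print(x$performance)
  invisible(x)
}
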
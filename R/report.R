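#' Pipeline commands: base case, PSA and cohort simulation
#'
#' Thin report-generating front ends over the analysis functions, also
#' exposed through the \code{ceatree} command-line script installed under
#' \code{inst/exec}. Each command loads and validates the model, runs its
#' stage, writes plain CSV/JSON outputs stamped with the model checksum
#' and seed, and narrates progress via \code{message()} so a failure is
#' attributable to a stage.
#'
#' @param model_path path to a YAML model file.
#' @param output_dir directory for report files (created if absent).
#' @param wtp willingness-to-pay thresholds for base-case verdicts.
#' @param quiet suppress progress messages.
#' @return invisibly, the analysis object of the stage (\code{"cea"},
#'   \code{"cea_psa"}, or a list of cohort summaries).
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmd_basecase <- function(model_path, output_dir = "cea_output",
                         wtp = c(1032, 2666), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("[load] reading model from %s", model_path)
  model <- read_cea_model(model_path)
  say("[validate] model '%s' OK (%d parameters, 2 strategies)",
      model$name, length(model$parameters))
  say("[rollback] evaluating base case")
  fit <- cea(model, wtp = wtp)
  say("[incremental] %s vs %s: status %s", fit$incremental$intervention,
      fit$incremental$comparator, fit$incremental$status)
  write_cea_results(fit, output_dir)
  say("[write] base-case report in %s", output_dir)
  if (!quiet) print(summary(fit))
  invisible(fit)
}

#' @rdname pipeline-commands
#' @param n_iter,seed Monte Carlo size and RNG seed.
#' @param wtp_grid thresholds for the acceptability curve.
#' @param selection_wtp threshold for selection frequencies.
#' @export
cmd_psa <- function(model_path, output_dir = "cea_output",
                    n_iter = 10000, seed = 1L,
                    wtp_grid = default_wtp_grid(),
                    selection_wtp = 2666, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("[load] reading model from %s", model_path)
  model <- read_cea_model(model_path)
  say("[psa] %d iterations, seed %d", n_iter, seed)
  psa <- run_psa(model, n_iter = n_iter, seed = seed)
  write_psa_results(psa, output_dir, wtp_grid = wtp_grid,
                    selection_wtp = selection_wtp)
  say("[write] CE plane, CEAC and selection files in %s", output_dir)
  if (!quiet) print(psa)
  invisible(psa)
}

#' @rdname pipeline-commands
#' @param n cohort size per arm.
#' @param arm arms to simulate (one or both).
#' @param adherence supplement-receipt probability for the
#'   supplementation arm; values below 1 are exploratory scenarios
#'   beyond the idealized model and are flagged in the summary file.
#' @export
cmd_simulate <- function(model_path, output_dir = "cea_output",
                         n = 100000, arm = c("supplementation",
                                             "no_intervention"),
                         adherence = 1, seed = 1L, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  arm <- match.arg(arm, several.ok = TRUE)
  say("[load] reading model from %s", model_path)
  model <- read_cea_model(model_path)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list()
  for (a in arm) {
    say("[simulate] arm '%s': n = %d, adherence = %g, seed = %d",
        a, n, adherence, seed)
    students <- generate_cohort(model, n = n, arm = a,
                                adherence = adherence, seed = seed)
    write_cohort(students, file.path(output_dir,
                                     sprintf("cohort_%s.csv", a)))
    sm <- summarize_cohort(students)
    sm$adherence_scenario <- adherence
    summaries[[a]] <- sm
  }
  all <- do.call(rbind, summaries)
  write_csv_with_metadata(all,
                          file.path(output_dir, "cohort_summary.csv"),
                          model, seed)
  say("[write] cohort tables and summary in %s", output_dir)
  if (!quiet) print(as.data.frame(all), row.names = FALSE, digits = 5)
  invisible(summaries)
}
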
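#' Deterministic base-case cost-effectiveness analysis
#'
#' Evaluates a model at its base-case parameter values: rolls back both
#' strategies to expected cost (USD) and expected effect (QALYs),
#' performs the incremental analysis and issues cost-effectiveness
#' verdicts over a willingness-to-pay grid.
#'
#' @param model a \code{\link{cea_model}}.
#' @param wtp willingness-to-pay thresholds, USD/QALY. Default is the
#'   Iranian WTP-per-QALY range used by the bundled model.
#' @return an object of class \code{"cea"}: list with \code{model_name},
#'   \code{results} (named list of \code{strategy_result}),
#'   \code{incremental} (\code{\link{incremental_analysis}} output),
#'   \code{verdicts} (\code{\link{threshold_verdicts}} output) and
#'   \code{depression_risk} per arm when the trees label outcomes.
#' @examples
#' fit <- cea(read_cea_model(example_model_path()))
#' fit
#' summary(fit)
#' @export
cea <- function(model, wtp = c(1032, 2666)) {
  stopifnot(inherits(model, "cea_model"))
  base <- base_case_values(model)
  results <- lapply(model$strategies, rollback, params = base)
  int <- results[[model$intervention]]
  comp <- results[[model$comparator]]
  inc <- incremental_analysis(int, comp)
  risks <- tryCatch(
    vapply(model$strategies, outcome_probability, numeric(1),
           params = base),
    error = function(e) NULL)
  structure(list(model_name = model$name, model = model,
                 results = results, incremental = inc,
                 verdicts = threshold_verdicts(int, comp, wtp),
                 outcome_risk = risks),
            class = "cea")
}

#' @export
print.cea <- function(x, ...) {
  cat(sprintf("Base-case cost-effectiveness analysis: %s\n\n",
              x$model_name))
  print(as.data.frame(x), row.names = FALSE, digits = 6)
  cat(sprintf("\nstatus: %s", x$incremental$status))
  if (x$incremental$status == "dominant")
    cat(sprintf(" (|ΔC|/|ΔE| = %.4f USD/QALY)",
                x$incremental$icer_magnitude))
  cat("\n")
  invisible(x)
}

#' @describeIn cea tabular rendition: one row per strategy with expected
#'   cost, incremental cost, effect, incremental effect, ICER and status.
#' @param x,object a \code{"cea"} object.
#' @param row.names,optional,... passed on / ignored (S3 conformance).
#' @export
as.data.frame.cea <- function(x, row.names = NULL, optional = FALSE, ...) {
  inc <- x$incremental
  ref <- x$results[[inc$intervention]]
  com <- x$results[[inc$comparator]]
  data.frame(
    strategy = c(com$name, ref$name),
    cost = c(com$expected_cost, ref$expected_cost),
    incr_cost = c(NA, inc$delta_cost),
    effect = c(com$expected_effect, ref$expected_effect),
    incr_effect = c(NA, inc$delta_effect),
    icer = c(NA, inc$icer),
    status = c("(comparator)", inc$status),
    stringsAsFactors = FALSE)
}

#' @export
summary.cea <- function(object, ...) {
  structure(list(fit = object), class = "summary.cea")
}

#' @export
print.summary.cea <- function(x, ...) {
  fit <- x$fit
  print(fit)
  if (!is.null(fit$outcome_risk)) {
    cat("\nOutcome risk per arm:\n")
    for (nm in names(fit$outcome_risk))
      cat(sprintf("  %-28s %.6f\n", nm, fit$outcome_risk[[nm]]))
  }
  cat("\nWillingness-to-pay verdicts:\n")
  v <- fit$verdicts
  for (i in seq_len(nrow(v)))
    cat(sprintf("  WTP %8.0f USD/QALY: %s (NMB %s = %.2f vs %s = %.2f)\n",
                v$wtp[i],
                if (v$cost_effective[i]) "cost-effective"
                else "not cost-effective",
                fit$incremental$intervention, v$nmb_intervention[i],
                fit$incremental$comparator, v$nmb_comparator[i]))
  invisible(x)
}

# Metadata header lines stamped at the top of every CSV the package
# writes (comment.char = "#" on read).
metadata_header <- function(model, seed = NA) {
  c(sprintf("# tool: ceatree %s",
            as.character(utils::packageVersion("ceatree"))),
    sprintf("# model: %s", model$name),
    sprintf("# model_checksum: %s",
            if (is.na(model$checksum %||% NA)) "unavailable"
            else model$checksum),
    sprintf("# seed: %s", if (is.na(seed)) "none" else seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_csv_with_metadata <- function(df, path, model, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(metadata_header(model, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write base-case results to CSV and JSON
#'
#' Emits the strategy/incremental table in both formats, stamped with
#' the tool version, model name and model-file checksum.
#'
#' @param fit a \code{"cea"} object.
#' @param dir output directory (created if absent).
#' @param formats subset of \code{c("csv", "json")}.
#' @return invisibly, the paths written.
#' @export
write_cea_results <- function(fit, dir, formats = c("csv", "json")) {
  stopifnot(inherits(fit, "cea"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  tab <- as.data.frame(fit)
  if ("csv" %in% formats) {
    p <- file.path(dir, "basecase.csv")
    write_csv_with_metadata(tab, p, fit$model)
    paths <- c(paths, p)
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "basecase.json")
    jsonlite::write_json(list(
      metadata = list(
        tool = paste("ceatree",
                     as.character(utils::packageVersion("ceatree"))),
        model = fit$model_name,
        model_checksum = fit$model$checksum %||% NA),
      table = tab,
      incremental = unclass(fit$incremental),
      verdicts = fit$verdicts), p,
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
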
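#' Simulate a synthetic student cohort
#'
#' Individual-level (first-order) microsimulation of the supplementation
#' program: each student's vitamin D status and depression outcome are
#' Bernoulli draws following the model's branch probabilities, and
#' payoffs are the base-case cost/utility values. Cohort means therefore
#' converge to the deterministic rollback expectations, which makes the
#' generator an independent check on the tree arithmetic. Parameter
#' (second-order) uncertainty is deliberately excluded here — it lives in
#' \code{\link{run_psa}}.
#'
#' In the supplementation arm, supplement receipt is Bernoulli with the
#' \code{adherence} probability (1 reproduces the idealized model; 0.785
#' is the national program's observed uptake, offered as an exploratory
#' scenario). Non-receivers follow the no-intervention deficiency risk
#' and are not charged the supplement cost — whether they would incur
#' program costs anyway is unknown, so the generator charges receivers
#' only.
#'
#' @param model a \code{\link{cea_model}} whose parameters include
#'   \code{p_deficient_pre}, \code{p_deficient_post},
#'   \code{p_depression_deficient}, \code{p_depression_sufficient},
#'   \code{cost_depression}, \code{cost_supplement},
#'   \code{utility_healthy}, \code{utility_depressed} (the bundled model
#'   does).
#' @param n cohort size (>= 1).
#' @param arm \code{"supplementation"} or \code{"no_intervention"}.
#' @param adherence probability of supplement receipt in the
#'   supplementation arm, in [0, 1].
#' @param seed integer RNG seed.
#' @return data frame, one row per student, with columns \code{id},
#'   \code{arm}, \code{received_supplement}, \code{deficient},
#'   \code{depressed} (logicals encoded TRUE/FALSE), \code{cost} (USD),
#'   \code{utility} (QALY).
#' @examples
#' model <- read_cea_model(example_model_path())
#' students <- generate_cohort(model, n = 1000,
#'                             arm = "no_intervention", seed = 7)
#' summarize_cohort(students)
#' @export
generate_cohort <- function(model, n,
                            arm = c("supplementation", "no_intervention"),
                            adherence = 1, seed = NULL) {
  arm <- match.arg(arm)
  stopifnot(inherits(model, "cea_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count", call. = FALSE)
  n <- as.integer(n)
  if (!is.numeric(adherence) || adherence < 0 || adherence > 1)
    stop("adherence must lie in [0, 1]", call. = FALSE)
  base <- base_case_values(model)
  need <- c("p_deficient_pre", "p_deficient_post",
            "p_depression_deficient", "p_depression_sufficient",
            "cost_depression", "cost_supplement",
            "utility_healthy", "utility_depressed")
  missing <- setdiff(need, names(base))
  if (length(missing))
    stop("model lacks cohort parameters: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pr <- as.list(base[need])
  for (pn in grep("^p_", need, value = TRUE))
    if (pr[[pn]] < 0 || pr[[pn]] > 1)
      stop(sprintf("parameter '%s' = %g is not a probability",
                   pn, pr[[pn]]), call. = FALSE)

  if (!is.null(seed)) set.seed(seed)
  received <- if (arm == "supplementation")
    stats::runif(n) < adherence else rep(FALSE, n)
  p_def <- ifelse(received, pr$p_deficient_post, pr$p_deficient_pre)
  deficient <- stats::runif(n) < p_def
  p_dep <- ifelse(deficient, pr$p_depression_deficient,
                  pr$p_depression_sufficient)
  depressed <- stats::runif(n) < p_dep
  data.frame(
    id = seq_len(n),
    arm = arm,
    received_supplement = received,
    deficient = deficient,
    depressed = depressed,
    cost = ifelse(depressed, pr$cost_depression, 0) +
      ifelse(received, pr$cost_supplement, 0),
    utility = ifelse(depressed, pr$utility_depressed,
                     pr$utility_healthy),
    stringsAsFactors = FALSE)
}

#' @describeIn generate_cohort \code{\link[stats]{simulate}} method:
#'   draws one cohort per arm requested via \code{arm}.
#' @param object a \code{cea_model} (simulate method).
#' @param nsim cohort size (simulate method's name for \code{n}).
#' @param ... unused.
#' @export
simulate.cea_model <- function(object, nsim = 1, seed = NULL,
                               arm = c("supplementation",
                                       "no_intervention"),
                               adherence = 1, ...) {
  generate_cohort(object, n = nsim, arm = match.arg(arm),
                  adherence = adherence, seed = seed)
}

#' Summarize a single-arm student cohort
#'
#' Arithmetic means of cost and utility, the depression rate, and the
#' standard error of each mean (sample SD over the square root of n; the
#' depression rate uses the binomial SE).
#'
#' @param records data frame from \code{\link{generate_cohort}}, all
#'   rows from one arm.
#' @return one-row data frame of class \code{"cohort_summary"} with
#'   columns \code{arm}, \code{n}, \code{mean_cost}, \code{se_cost},
#'   \code{mean_utility}, \code{se_utility}, \code{depression_rate},
#'   \code{se_depression}, \code{adherence_observed}.
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty cohort data frame", call. = FALSE)
  if (length(unique(records$arm)) != 1L)
    stop("mixed arms: summarize one arm at a time", call. = FALSE)
  n <- nrow(records)
  rate <- mean(records$depressed)
  out <- data.frame(
    arm = records$arm[1],
    n = n,
    mean_cost = mean(records$cost),
    se_cost = stats::sd(records$cost) / sqrt(n),
    mean_utility = mean(records$utility),
    se_utility = stats::sd(records$utility) / sqrt(n),
    depression_rate = rate,
    se_depression = sqrt(rate * (1 - rate) / n),
    adherence_observed = mean(records$received_supplement),
    stringsAsFactors = FALSE)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Read and write student-cohort tables
#'
#' Plain CSV with the documented column order (\code{id, arm,
#' received_supplement, deficient, depressed, cost, utility}); logical
#' columns are encoded as the literals \code{TRUE}/\code{FALSE}.
#'
#' @param records cohort data frame.
#' @param path CSV file path.
#' @return \code{write_cohort} returns \code{path} invisibly;
#'   \code{read_cohort} returns the cohort data frame.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         comment.char = "#")
  for (cn in c("received_supplement", "deficient", "depressed"))
    out[[cn]] <- as.logical(out[[cn]])
  out
}
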
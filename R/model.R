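#' Construct a cost-effectiveness model
#'
#' A \code{cea_model} bundles a set of named, typed parameters with the
#' decision trees of exactly two strategies and records which strategy is
#' the intervention and which the comparator. Parameters carry a role
#' (\code{probability}, \code{utility} or \code{cost}) and an uncertainty
#' specification (\code{\link{dist_spec}}); probabilities are always
#' fixed, mirroring the usual situation where branch probabilities are
#' point estimates while payoffs carry sampling distributions.
#'
#' @param parameters named list; each element a list with \code{role}
#'   (one of \code{"probability"}, \code{"utility"}, \code{"cost"}),
#'   \code{spec} (a \code{\link{dist_spec}}) and optional \code{units}.
#' @param strategies list of two \code{\link{strategy}} objects.
#' @param intervention,comparator strategy names.
#' @param name model name; \code{description} free text.
#' @param description optional free-text description.
#' @param source_path optional path the model was loaded from (recorded
#'   in output metadata together with its checksum).
#' @return an object of class \code{"cea_model"}.
#' @seealso \code{\link{read_cea_model}} for the YAML front end,
#'   \code{\link{cea}} for base-case evaluation, \code{\link{run_psa}}.
#' @export
cea_model <- function(parameters, strategies, intervention, comparator,
                      name = "model", description = "",
                      source_path = NULL) {
  stopifnot(is.list(parameters), length(names(parameters)) ==
              length(parameters))
  roles <- c("probability", "utility", "cost")
  for (pn in names(parameters)) {
    p <- parameters[[pn]]
    if (!is.list(p) || is.null(p$role) || is.null(p$spec) ||
        !p$role %in% roles || !inherits(p$spec, "dist_spec"))
      stop(sprintf("parameter '%s': need a role in {%s} and a dist_spec",
                   pn, paste(roles, collapse = ", ")), call. = FALSE)
    m <- p$spec$mean
    if (p$role == "probability") {
      if (p$spec$family != "fixed")
        stop(sprintf(
          "parameter '%s': probabilities carry no sampling distribution",
          pn), call. = FALSE)
      if (m < 0 || m > 1)
        stop(sprintf("parameter '%s': probability %g outside [0, 1]",
                     pn, m), call. = FALSE)
    }
    if (p$role == "utility" && (m < 0 || m > 1))
      stop(sprintf("parameter '%s': utility %g outside [0, 1]", pn, m),
           call. = FALSE)
    if (p$role == "cost" && m < 0)
      stop(sprintf("parameter '%s': cost %g is negative", pn, m),
           call. = FALSE)
  }
  snames <- vapply(strategies, `[[`, character(1), "name")
  if (length(strategies) != 2L || anyDuplicated(snames))
    stop("a model needs exactly two uniquely named strategies",
         call. = FALSE)
  if (!intervention %in% snames || !comparator %in% snames ||
      intervention == comparator)
    stop("intervention and comparator must name the two strategies",
         call. = FALSE)
  names(strategies) <- snames
  model <- structure(list(
    name = name, description = description,
    parameters = parameters, strategies = strategies,
    intervention = intervention, comparator = comparator,
    source_path = source_path,
    checksum = if (!is.null(source_path))
      unname(tools::md5sum(source_path)) else NA_character_),
    class = "cea_model")
  base <- base_case_values(model)
  for (s in strategies) {
    viol <- validate_tree(s, base)
    if (length(viol))
      stop(sprintf("model '%s' invalid:\n  %s", name,
                   paste(viol, collapse = "\n  ")), call. = FALSE)
  }
  model
}

#' Base-case parameter values of a model
#'
#' @param model a \code{\link{cea_model}}.
#' @return named numeric vector of distribution means (the base case).
#' @export
base_case_values <- function(model) {
  stopifnot(inherits(model, "cea_model"))
  vapply(model$parameters, function(p) p$spec$mean, numeric(1))
}

#' Names of parameters carrying uncertainty
#'
#' Parameters whose family is not \code{fixed} — those sampled during
#' probabilistic sensitivity analysis.
#'
#' @param model a \code{\link{cea_model}}.
#' @return character vector of parameter names.
#' @export
uncertain_parameters <- function(model) {
  stopifnot(inherits(model, "cea_model"))
  names(model$parameters)[vapply(model$parameters,
    function(p) p$spec$family != "fixed", logical(1))]
}

#' Read a model from a YAML configuration file
#'
#' The documented schema (see the bundled
#' \code{vitd_iran_2018.yaml} for a complete example) has top-level keys
#' \code{name}, \code{description}, \code{intervention},
#' \code{comparator}, \code{parameters} and \code{strategies}:
#' \itemize{
#'   \item a parameter entry is either \code{role: probability} with a
#'     \code{value}, or a \code{role} of \code{cost}/\code{utility} with
#'     \code{family} (\code{gamma}, \code{beta} or \code{fixed}),
#'     \code{mean} and \code{sd} (omit \code{sd} for \code{fixed});
#'   \item a strategy has \code{name}, optional \code{upfront_cost}
#'     (number or parameter name) and a \code{root} node;
#'   \item a chance node has \code{label} and \code{branches}, each
#'     branch a map with \code{p} (number or parameter name) and
#'     \code{node}; a terminal node has \code{cost}, \code{utility}
#'     (numbers or parameter names) and an optional \code{outcome} label.
#' }
#' All invariants — distribution feasibility, probability normalization,
#' payoff ranges, parameter-reference resolution — are checked at load
#' time; errors name the offending parameter or node path.
#'
#' @param path path to a YAML model file.
#' @return a validated \code{\link{cea_model}}.
#' @examples
#' model <- read_cea_model(example_model_path())
#' model
#' @export
read_cea_model <- function(path) {
  if (!file.exists(path))
    stop(sprintf("model file '%s' does not exist", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (key in c("parameters", "strategies"))
    if (is.null(raw[[key]]))
      stop(sprintf("%s: missing required key '%s'", path, key),
           call. = FALSE)

  parameters <- lapply(names(raw$parameters), function(pn) {
    p <- raw$parameters[[pn]]
    if (is.null(p$role))
      stop(sprintf("%s: parameter '%s' has no role", path, pn),
           call. = FALSE)
    spec <- if (identical(p$role, "probability") || !is.null(p$value)) {
      dist_spec("fixed", p$value, name = pn)
    } else {
      if (is.null(p$family) ||
          !p$family %in% c("gamma", "beta", "fixed"))
        stop(sprintf("%s: parameter '%s' has unknown distribution family '%s'",
                     path, pn, if (is.null(p$family)) "<missing>"
                     else p$family), call. = FALSE)
      dist_spec(p$family, p$mean,
                if (is.null(p$sd)) 0 else p$sd, name = pn)
    }
    list(role = p$role, spec = spec,
         units = if (is.null(p$units)) "" else p$units)
  })
  names(parameters) <- names(raw$parameters)

  parse_node <- function(nd, where) {
    if (!is.null(nd$branches)) {
      branches <- lapply(seq_along(nd$branches), function(i) {
        b <- nd$branches[[i]]
        if (is.null(b$p) || is.null(b$node))
          stop(sprintf("%s: %s/branch[%d] needs 'p' and 'node'",
                       path, where, i), call. = FALSE)
        list(p = b$p,
             node = parse_node(b$node, sprintf("%s/branch[%d]", where, i)))
      })
      return(chance_node(branches,
                         if (is.null(nd$label)) "" else nd$label))
    }
    if (is.null(nd$cost) || is.null(nd$utility))
      stop(sprintf("%s: %s is neither a chance node (branches) nor a terminal node (cost + utility)",
                   path, where), call. = FALSE)
    terminal_node(nd$cost, nd$utility, outcome = nd$outcome)
  }
  strategies <- lapply(raw$strategies, function(s) {
    if (is.null(s$name) || is.null(s$root))
      stop(sprintf("%s: every strategy needs 'name' and 'root'", path),
           call. = FALSE)
    strategy(s$name, parse_node(s$root, s$name),
             upfront_cost = if (is.null(s$upfront_cost)) 0
                            else s$upfront_cost)
  })
  snames <- vapply(strategies, `[[`, character(1), "name")

  cea_model(parameters, strategies,
            intervention = if (is.null(raw$intervention)) snames[1]
                           else raw$intervention,
            comparator = if (is.null(raw$comparator)) snames[2]
                         else raw$comparator,
            name = if (is.null(raw$name))
                     tools::file_path_sans_ext(basename(path))
                   else raw$name,
            description = if (is.null(raw$description)) ""
                          else raw$description,
            source_path = path)
}

#' Path to the bundled vitamin D supplementation model
#'
#' @return path to \code{vitd_iran_2018.yaml} inside the installed
#'   package.
#' @export
example_model_path <- function() {
  system.file("extdata", "vitd_iran_2018.yaml", package = "ceatree",
              mustWork = TRUE)
}

#' @export
print.cea_model <- function(x, ...) {
  cat(sprintf("Cost-effectiveness model '%s'\n", x$name))
  if (nzchar(x$description)) cat(strwrap(x$description, indent = 2,
                                         exdent = 2), sep = "\n")
  cat(sprintf("  strategies : %s (intervention) vs %s (comparator)\n",
              x$intervention, x$comparator))
  nun <- length(uncertain_parameters(x))
  cat(sprintf("  parameters : %d (%d with uncertainty distributions)\n",
              length(x$parameters), nun))
  invisible(x)
}
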
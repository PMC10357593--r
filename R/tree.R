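#' Decision-tree building blocks
#'
#' A strategy is a named decision-tree arm: an optional strategy-level
#' upfront cost (incurred by everyone in the arm, e.g. a supplementation
#' program cost) and a root node. Nodes are either chance nodes, whose
#' branches carry probabilities summing to 1, or terminal nodes carrying a
#' (cost, utility) payoff. Probabilities and payoffs may be numeric
#' literals or character names referencing model parameters, resolved at
#' evaluation time, so the same tree can be rolled back under base-case
#' values or per-draw sampled values.
#'
#' @param cost,utility terminal payoffs: cost in USD (>= 0), utility in
#'   [0, 1]; numeric or a parameter name.
#' @param outcome optional character label tagging the leaf with a health
#'   outcome (e.g. \code{"depression"}), used by
#'   \code{\link{outcome_probability}}.
#' @return \code{terminal_node} and \code{chance_node} return node objects
#'   of class \code{"tree_node"}; \code{strategy} returns a
#'   \code{"cea_strategy"}.
#' @name tree-nodes
NULL

#' @rdname tree-nodes
#' @export
terminal_node <- function(cost, utility, outcome = NULL) {
  structure(list(kind = "terminal", cost = cost, utility = utility,
                 outcome = outcome),
            class = "tree_node")
}

#' @rdname tree-nodes
#' @param branches list of branches, each a list with elements \code{p}
#'   (probability, numeric or parameter name) and \code{node} (child).
#' @param label short description of the chance event (e.g.
#'   \code{"vitamin D status"}).
#' @export
chance_node <- function(branches, label = "") {
  structure(list(kind = "chance", branches = branches, label = label),
            class = "tree_node")
}

#' @rdname tree-nodes
#' @param name unique strategy name.
#' @param root the root node (chance or terminal).
#' @param upfront_cost strategy-level cost in USD added to every path
#'   (numeric or parameter name); default 0.
#' @export
strategy <- function(name, root, upfront_cost = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(root, "tree_node"))
  structure(list(name = name, root = root, upfront_cost = upfront_cost),
            class = "cea_strategy")
}

# Resolve a probability/payoff that may be a parameter reference.
resolve_value <- function(x, params, where) {
  if (is.character(x)) {
    if (!x %in% names(params))
      stop(sprintf("unresolved parameter reference '%s' at %s", x, where),
           call. = FALSE)
    x <- params[[x]]
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("non-finite value at %s", where), call. = FALSE)
  x
}

#' Validate a strategy's tree structure
#'
#' Walks the tree collecting violations: chance-node probabilities that do
#' not sum to 1 (tolerance 1e-9), chance nodes with fewer than two
#' branches, probabilities outside [0, 1], negative costs and utilities
#' outside the unit interval. Returns the violations rather than raising,
#' so loaders can report all problems at once.
#'
#' @param strat a \code{\link{strategy}}.
#' @param params named list/vector of resolved parameter values used for
#'   parameter-referencing probabilities and payoffs.
#' @param tol probability-sum tolerance (inputs are exact decimals, so the
#'   default is tight).
#' @return character vector of violation messages; empty when valid.
#' @export
validate_tree <- function(strat, params = list(), tol = 1e-9) {
  stopifnot(inherits(strat, "cea_strategy"))
  violations <- character(0)
  note <- function(msg) violations <<- c(violations, msg)

  up <- try(resolve_value(strat$upfront_cost, params,
                          paste0(strat$name, "/upfront_cost")), silent = TRUE)
  if (inherits(up, "try-error")) {
    note(sprintf("%s: unresolvable upfront cost", strat$name))
  } else if (up < 0) {
    note(sprintf("%s: upfront cost %g is negative", strat$name, up))
  }

  walk <- function(node, path) {
    if (node$kind == "terminal") {
      cost <- try(resolve_value(node$cost, params, path), silent = TRUE)
      util <- try(resolve_value(node$utility, params, path), silent = TRUE)
      if (inherits(cost, "try-error")) {
        note(sprintf("%s: unresolvable cost", path))
      } else if (cost < 0) {
        note(sprintf("%s: cost %g is negative", path, cost))
      }
      if (inherits(util, "try-error")) {
        note(sprintf("%s: unresolvable utility", path))
      } else if (util < 0 || util > 1) {
        note(sprintf("%s: utility %g outside [0, 1]", path, util))
      }
      return(invisible())
    }
    if (length(node$branches) < 2L)
      note(sprintf("%s: chance node has %d branch(es); need at least 2",
                   path, length(node$branches)))
    ps <- vapply(seq_along(node$branches), function(i) {
      p <- try(resolve_value(node$branches[[i]]$p, params,
                             sprintf("%s/branch[%d]", path, i)),
               silent = TRUE)
      if (inherits(p, "try-error")) {
        note(sprintf("%s/branch[%d]: unresolvable probability", path, i))
        return(NA_real_)
      }
      if (p < 0 || p > 1)
        note(sprintf("%s/branch[%d]: probability %g outside [0, 1]",
                     path, i, p))
      p
    }, numeric(1))
    if (!anyNA(ps) && abs(sum(ps) - 1) > tol)
      note(sprintf("%s: branch probabilities sum to %.10g, not 1",
                   path, sum(ps)))
    for (i in seq_along(node$branches))
      walk(node$branches[[i]]$node, sprintf("%s/branch[%d]", path, i))
  }
  walk(strat$root, strat$name)
  violations
}

#' Roll back a strategy to its expected cost and effect
#'
#' Computes the probability-weighted expectation of terminal payoffs over
#' all root-to-leaf paths, by recursive expected value at each chance
#' node. The strategy's upfront cost is added to the expected cost.
#'
#' @param strat a \code{\link{strategy}} passing \code{\link{validate_tree}}.
#' @param params named list/vector of resolved parameter values.
#' @return an object of class \code{"strategy_result"}: a list with
#'   \code{name}, \code{expected_cost} (USD) and \code{expected_effect}
#'   (QALYs).
#' @examples
#' leaf_ok  <- terminal_node(0, 0.76)
#' leaf_dep <- terminal_node(335.4, 0.545, outcome = "depression")
#' arm <- strategy("no intervention",
#'   chance_node(list(
#'     list(p = 0.76, node = chance_node(list(
#'       list(p = 0.314, node = leaf_dep),
#'       list(p = 0.686, node = leaf_ok)), "deficient")),
#'     list(p = 0.24, node = chance_node(list(
#'       list(p = 0.16, node = leaf_dep),
#'       list(p = 0.84, node = leaf_ok)), "sufficient"))),
#'     "vitamin D status"))
#' rollback(arm)  # cost ~ 92.92, effect ~ 0.7004
#' @export
rollback <- function(strat, params = list()) {
  viol <- validate_tree(strat, params)
  if (length(viol))
    stop("invalid strategy tree:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  ev <- function(node, path) {
    if (node$kind == "terminal")
      return(c(cost = resolve_value(node$cost, params, path),
               effect = resolve_value(node$utility, params, path)))
    acc <- c(cost = 0, effect = 0)
    for (i in seq_along(node$branches)) {
      b <- node$branches[[i]]
      p <- resolve_value(b$p, params, sprintf("%s/branch[%d]", path, i))
      acc <- acc + p * ev(b$node, sprintf("%s/branch[%d]", path, i))
    }
    acc
  }
  v <- ev(strat$root, strat$name)
  up <- resolve_value(strat$upfront_cost, params,
                      paste0(strat$name, "/upfront_cost"))
  structure(list(name = strat$name,
                 expected_cost = up + v[["cost"]],
                 expected_effect = v[["effect"]]),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("%s: expected cost $%.4f, expected effect %.4f QALY\n",
              x$name, x$expected_cost, x$expected_effect))
  invisible(x)
}

#' Total probability of reaching outcome-labelled leaves
#'
#' Sums path probabilities into every terminal node tagged with the given
#' outcome label; with the bundled model and \code{outcome =
#' "depression"} this is the arm's one-year depression risk.
#'
#' @inheritParams rollback
#' @param outcome leaf label to accumulate (default \code{"depression"}).
#' @return a probability in [0, 1].
#' @export
outcome_probability <- function(strat, params = list(),
                                outcome = "depression") {
  stopifnot(inherits(strat, "cea_strategy"))
  found <- FALSE
  walk <- function(node, p, path) {
    if (node$kind == "terminal") {
      if (!is.null(node$outcome) && identical(node$outcome, outcome)) {
        found <<- TRUE
        return(p)
      }
      if (!is.null(node$outcome)) found <<- TRUE
      return(0)
    }
    tot <- 0
    for (i in seq_along(node$branches)) {
      b <- node$branches[[i]]
      pb <- resolve_value(b$p, params, sprintf("%s/branch[%d]", path, i))
      tot <- tot + walk(b$node, p * pb, sprintf("%s/branch[%d]", path, i))
    }
    tot
  }
  out <- walk(strat$root, 1, strat$name)
  if (!found)
    stop(sprintf("strategy '%s' has no outcome-labelled leaves",
                 strat$name), call. = FALSE)
  out
}
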
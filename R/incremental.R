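#' Incremental cost-effectiveness analysis of two strategies
#'
#' Computes the cost and effect differences of an intervention against a
#' comparator, the incremental cost-effectiveness ratio (ICER) and a
#' dominance classification:
#' \describe{
#'   \item{dominant}{the intervention costs less and yields more effect;
#'     it is preferred at any willingness to pay}
#'   \item{dominated}{costs more, yields less}
#'   \item{tradeoff}{more effect at more cost (or less at less); the
#'     ICER must be weighed against a willingness-to-pay threshold}
#'   \item{equivalent}{both differences are (numerically) zero}
#' }
#' The signed conventional ICER (\code{delta_cost / delta_effect}) is
#' negative under dominance; because cost-effectiveness reports often
#' print the magnitude \code{|delta_cost| / |delta_effect|} in that case,
#' it is returned alongside as \code{icer_magnitude}.
#'
#' @param intervention,comparator \code{strategy_result} objects from
#'   \code{\link{rollback}}.
#' @param tol effect difference below which the ICER is reported as
#'   undefined (\code{NA}); avoids division blow-up for identical arms.
#' @return an object of class \code{"incremental_result"}: list with
#'   \code{intervention}, \code{comparator} (names), \code{delta_cost},
#'   \code{delta_effect}, \code{icer}, \code{icer_magnitude},
#'   \code{status}.
#' @export
incremental_analysis <- function(intervention, comparator, tol = 1e-12) {
  stopifnot(inherits(intervention, "strategy_result"),
            inherits(comparator, "strategy_result"))
  dc <- intervention$expected_cost - comparator$expected_cost
  de <- intervention$expected_effect - comparator$expected_effect
  undefined <- abs(de) < tol
  icer <- if (undefined) NA_real_ else dc / de
  status <- if (undefined && abs(dc) < tol) "equivalent"
    else if (dc < 0 && de > 0) "dominant"
    else if (dc > 0 && de < 0) "dominated"
    else "tradeoff"
  structure(list(
    intervention = intervention$name, comparator = comparator$name,
    delta_cost = dc, delta_effect = de, icer = icer,
    icer_magnitude = if (undefined) NA_real_ else abs(dc) / abs(de),
    status = status), class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("%s vs %s\n", x$intervention, x$comparator))
  cat(sprintf("  incremental cost   : %+.4f USD\n", x$delta_cost))
  cat(sprintf("  incremental effect : %+.6f QALY\n", x$delta_effect))
  if (is.na(x$icer)) {
    cat("  ICER               : undefined (effects equal)\n")
  } else {
    cat(sprintf("  ICER               : %.4f USD/QALY", x$icer))
    if (x$status == "dominant")
      cat(sprintf("  (magnitude %.4f)", x$icer_magnitude))
    cat("\n")
  }
  cat(sprintf("  status             : %s\n", x$status))
  invisible(x)
}

#' Net monetary benefit of a strategy
#'
#' \code{wtp * expected_effect - expected_cost}: the strategy's effect
#' valued at the willingness-to-pay threshold, less its cost. The
#' strategy with the higher NMB at a given threshold is preferred there.
#'
#' @param result a \code{strategy_result}.
#' @param wtp willingness to pay per QALY, USD (>= 0); may be a vector.
#' @return numeric NMB in USD, one value per threshold.
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(inherits(result, "strategy_result"))
  if (any(!is.finite(wtp)) || any(wtp < 0))
    stop("wtp must be non-negative", call. = FALSE)
  wtp * result$expected_effect - result$expected_cost
}

#' Cost-effectiveness verdicts over a willingness-to-pay grid
#'
#' For each threshold, the intervention is judged cost-effective when its
#' net monetary benefit exceeds the comparator's — equivalently, when
#' \code{wtp * delta_effect - delta_cost > 0}. For a dominant
#' intervention this holds at every threshold, including zero.
#'
#' @param intervention,comparator \code{strategy_result} objects.
#' @param wtp_grid non-empty vector of non-negative thresholds (USD/QALY).
#' @return data frame with columns \code{wtp}, \code{nmb_intervention},
#'   \code{nmb_comparator}, \code{cost_effective}.
#' @export
threshold_verdicts <- function(intervention, comparator, wtp_grid) {
  if (length(wtp_grid) == 0L)
    stop("wtp_grid must be non-empty", call. = FALSE)
  nmb_i <- net_monetary_benefit(intervention, wtp_grid)
  nmb_c <- net_monetary_benefit(comparator, wtp_grid)
  data.frame(wtp = wtp_grid, nmb_intervention = nmb_i,
             nmb_comparator = nmb_c, cost_effective = nmb_i > nmb_c)
}
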
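#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' Quantifies parameter (second-order) uncertainty: at each iteration
#' every uncertain parameter — those with a Beta or Gamma specification —
#' is drawn once from its fitted distribution and the draw is shared by
#' both strategies (common random parameters: the utilities and costs are
#' the same quantities in both arms, so independent per-arm draws would
#' overstate the variance of the differences). Branch probabilities,
#' which carry no distribution, stay at their base-case values. Both
#' strategies are rolled back under each draw and the incremental cost
#' and effect recorded.
#'
#' @param model a \code{\link{cea_model}}.
#' @param n_iter number of Monte Carlo iterations (default 10,000, a
#'   conventional PSA size).
#' @param seed integer RNG seed; recorded in the result and in every
#'   file written from it, so runs are reproducible.
#' @return an object of class \code{"cea_psa"}: list with \code{n_iter},
#'   \code{seed}, \code{model_name}, \code{model},
#'   \code{params} (data frame of per-draw sampled parameter values),
#'   \code{draws} (data frame with per-draw cost/effect of each arm and
#'   \code{delta_cost}, \code{delta_effect}).
#' @examples
#' model <- read_cea_model(example_model_path())
#' psa <- run_psa(model, n_iter = 200, seed = 1)
#' psa
#' @export
run_psa <- function(model, n_iter = 10000, seed = 1L) {
  stopifnot(inherits(model, "cea_model"), n_iter >= 1)
  set.seed(seed)
  base <- base_case_values(model)
  unames <- uncertain_parameters(model)
  samples <- as.data.frame(lapply(unames, function(pn)
    sample_dist(model$parameters[[pn]]$spec, n_iter)))
  names(samples) <- unames

  int_name <- model$intervention
  comp_name <- model$comparator
  cost_i <- effect_i <- cost_c <- effect_c <- numeric(n_iter)
  params <- as.list(base)
  for (it in seq_len(n_iter)) {
    for (pn in unames) params[[pn]] <- samples[[pn]][it]
    ri <- rollback_unchecked(model$strategies[[int_name]], params)
    rc <- rollback_unchecked(model$strategies[[comp_name]], params)
    cost_i[it] <- ri[["cost"]]; effect_i[it] <- ri[["effect"]]
    cost_c[it] <- rc[["cost"]]; effect_c[it] <- rc[["effect"]]
  }
  draws <- data.frame(
    cost_intervention = cost_i, effect_intervention = effect_i,
    cost_comparator = cost_c, effect_comparator = effect_c,
    delta_cost = cost_i - cost_c, delta_effect = effect_i - effect_c)
  structure(list(n_iter = n_iter, seed = seed,
                 model_name = model$name, model = model,
                 params = samples, draws = draws),
            class = "cea_psa")
}

# Expected (cost, effect) without re-validating the tree on every draw;
# validation happens once at model construction and probabilities are
# unchanged across draws.
rollback_unchecked <- function(strat, params) {
  ev <- function(node) {
    if (node$kind == "terminal")
      return(c(cost = resolve_value(node$cost, params, strat$name),
               effect = resolve_value(node$utility, params, strat$name)))
    acc <- c(cost = 0, effect = 0)
    for (b in node$branches)
      acc <- acc + resolve_value(b$p, params, strat$name) * ev(b$node)
    acc
  }
  v <- ev(strat$root)
  v[["cost"]] <- v[["cost"]] +
    resolve_value(strat$upfront_cost, params, strat$name)
  v
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("PSA of '%s': %d iterations (seed %d)\n", x$model_name,
              x$n_iter, x$seed))
  cat(sprintf("  mean Δcost   : %+.4f USD\n", mean(x$draws$delta_cost)))
  cat(sprintf("  mean Δeffect : %+.6f QALY\n",
              mean(x$draws$delta_effect)))
  q <- classify_quadrants(x)
  cat("  CE-plane quadrants:",
      paste(sprintf("%s=%d", names(q), q), collapse = " "), "\n")
  invisible(x)
}

#' Cost-effectiveness plane quadrant counts
#'
#' Classifies each draw by the signs of (incremental effect, incremental
#' cost): NE (more effect, more cost), NW (less effect, more cost), SE
#' (more effect, less cost — the dominant region), SW (less effect, less
#' cost). Zero differences are assigned to the positive side (East/North);
#' for continuous draws this is a measure-zero convention.
#'
#' @param psa a \code{"cea_psa"} object.
#' @return named integer vector with counts for NE, NW, SE, SW, summing
#'   to \code{n_iter}.
#' @export
classify_quadrants <- function(psa) {
  stopifnot(inherits(psa, "cea_psa"))
  east <- psa$draws$delta_effect >= 0
  north <- psa$draws$delta_cost >= 0
  c(NE = sum(east & north), NW = sum(!east & north),
    SE = sum(east & !north), SW = sum(!east & !north))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA draws in
#' which the intervention has positive incremental net monetary benefit,
#' \code{wtp * delta_effect - delta_cost > 0} (strict inequality; ties
#' have probability zero under continuous parameter distributions).
#'
#' @param psa a \code{"cea_psa"} object.
#' @param wtp_grid non-negative thresholds; the default spans 0-5000
#'   USD/QALY in steps of 50 and always includes the 1032 and 2666
#'   endpoints of the Iranian WTP range.
#' @return data frame with columns \code{wtp} and \code{acceptability}.
#' @export
ceac <- function(psa, wtp_grid = default_wtp_grid()) {
  stopifnot(inherits(psa, "cea_psa"))
  if (length(wtp_grid) == 0L || any(wtp_grid < 0))
    stop("wtp_grid must be non-empty and non-negative", call. = FALSE)
  acc <- vapply(wtp_grid, function(w)
    mean(w * psa$draws$delta_effect - psa$draws$delta_cost > 0),
    numeric(1))
  data.frame(wtp = wtp_grid, acceptability = acc)
}

#' @rdname ceac
#' @export
default_wtp_grid <- function() {
  sort(unique(c(seq(0, 5000, by = 50), 1032, 2666)))
}

#' Monte Carlo strategy selection frequencies
#'
#' At a given willingness to pay, the fraction of draws in which each
#' strategy is the preferred (higher-NMB) one. The intervention's
#' frequency equals the acceptability at that threshold; the two
#' frequencies sum to 1.
#'
#' @param psa a \code{"cea_psa"} object.
#' @param wtp a single non-negative threshold, USD/QALY.
#' @return named numeric vector of frequencies, one per strategy.
#' @export
strategy_selection <- function(psa, wtp) {
  stopifnot(inherits(psa, "cea_psa"), length(wtp) == 1L, wtp >= 0)
  acc <- ceac(psa, wtp)$acceptability
  out <- c(acc, 1 - acc)
  names(out) <- c(psa$model$intervention, psa$model$comparator)
  out
}

#' Plot PSA results
#'
#' Two-panel base-graphics display: the cost-effectiveness plane
#' (incremental effect vs incremental cost scatter, quadrant axes drawn)
#' and the cost-effectiveness acceptability curve.
#'
#' @param x a \code{"cea_psa"} object.
#' @param wtp_grid thresholds for the CEAC panel.
#' @param ... further arguments passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.cea_psa <- function(x, wtp_grid = default_wtp_grid(), ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(x$draws$delta_effect, x$draws$delta_cost,
                 pch = 16, cex = 0.4, col = "#00000055",
                 xlab = "incremental effect (QALY)",
                 ylab = "incremental cost (USD)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey50")
  cc <- ceac(x, wtp_grid)
  graphics::plot(cc$wtp, cc$acceptability, type = "l", ylim = c(0, 1),
                 xlab = "willingness to pay (USD/QALY)",
                 ylab = "P(cost-effective)",
                 main = "Acceptability curve", ...)
  invisible(x)
}

#' Write PSA outputs as plain-text data files
#'
#' Writes the cost-effectiveness plane draws
#' (\code{ce_plane.csv}: delta_effect, delta_cost, quadrant), the
#' acceptability curve (\code{ceac.csv}) and the strategy-selection
#' frequencies (\code{selection.json}). Every file embeds the seed,
#' iteration count, model name and model-file checksum, so rerunning
#' with the same configuration reproduces the files exactly.
#'
#' @param psa a \code{"cea_psa"} object.
#' @param dir output directory (created if absent).
#' @param wtp_grid thresholds for the CEAC file.
#' @param selection_wtp threshold at which selection frequencies are
#'   reported.
#' @return invisibly, the paths written.
#' @export
write_psa_results <- function(psa, dir, wtp_grid = default_wtp_grid(),
                              selection_wtp = 2666) {
  stopifnot(inherits(psa, "cea_psa"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  east <- psa$draws$delta_effect >= 0
  north <- psa$draws$delta_cost >= 0
  quadrant <- ifelse(north, ifelse(east, "NE", "NW"),
                     ifelse(east, "SE", "SW"))
  plane <- data.frame(delta_effect = psa$draws$delta_effect,
                      delta_cost = psa$draws$delta_cost,
                      quadrant = quadrant)
  p1 <- file.path(dir, "ce_plane.csv")
  write_csv_with_metadata(plane, p1, psa$model, psa$seed)
  p2 <- file.path(dir, "ceac.csv")
  write_csv_with_metadata(ceac(psa, wtp_grid), p2, psa$model, psa$seed)
  p3 <- file.path(dir, "selection.json")
  jsonlite::write_json(list(
    metadata = list(
      tool = paste("ceatree",
                   as.character(utils::packageVersion("ceatree"))),
      model = psa$model_name,
      model_checksum = psa$model$checksum %||% NA,
      seed = psa$seed, n_iter = psa$n_iter, wtp = selection_wtp),
    frequencies = as.list(strategy_selection(psa, selection_wtp))),
    p3, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(c(p1, p2, p3))
}
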
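#' Specify a parameter's uncertainty distribution
#'
#' A distribution specification records a parameter's uncertainty as a
#' mean and standard deviation together with a named family. Continuous
#' families are fitted by method of moments: the fitted distribution's
#' analytic mean and SD equal the stated values exactly. \code{"fixed"}
#' declares a degenerate (point-mass) parameter that is held constant
#' during probabilistic sensitivity analysis.
#'
#' Feasibility is checked at construction time:
#' \itemize{
#'   \item \code{beta}: \code{0 < mean < 1} and \code{sd^2 < mean * (1 - mean)}
#'   \item \code{gamma}: \code{mean > 0} and \code{sd > 0}
#'   \item \code{fixed}: \code{sd} must be 0 (or omitted)
#' }
#'
#' @param family one of \code{"gamma"}, \code{"beta"}, \code{"fixed"}.
#' @param mean distribution mean, in the parameter's natural units.
#' @param sd distribution standard deviation, same units; 0 only for
#'   \code{family = "fixed"}.
#' @param name optional parameter name used in error messages.
#' @return an object of class \code{"dist_spec"} with elements
#'   \code{family}, \code{mean}, \code{sd} and the fitted shape
#'   parameters (\code{shape}/\code{rate} for gamma,
#'   \code{alpha}/\code{beta} for beta).
#' @examples
#' dist_spec("gamma", 335.4, 35)    # depression management cost, USD
#' dist_spec("beta", 0.545, 0.035)  # utility of the depressed state
#' dist_spec("fixed", 0.314)        # a branch probability
#' @export
dist_spec <- function(family = c("gamma", "beta", "fixed"), mean, sd = 0,
                      name = NULL) {
  family <- match.arg(family)
  who <- if (is.null(name)) "" else sprintf(" for parameter '%s'", name)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("mean must be a finite number", who, call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("sd must be a finite non-negative number", who, call. = FALSE)

  spec <- structure(list(family = family, mean = mean, sd = sd),
                    class = "dist_spec")
  if (family == "gamma") {
    fit <- fit_gamma_moments(mean, sd, name = name)
    spec[c("shape", "rate")] <- fit[c("shape", "rate")]
  } else if (family == "beta") {
    fit <- fit_beta_moments(mean, sd, name = name)
    spec[c("alpha", "beta")] <- fit[c("alpha", "beta")]
  } else if (sd != 0) {
    stop("family 'fixed' requires sd = 0", who, call. = FALSE)
  }
  spec
}

#' Fit a Gamma distribution from its first two moments
#'
#' Solves \code{shape = mean^2 / sd^2} and \code{rate = mean / sd^2}, so
#' that the fitted Gamma's analytic mean (\code{shape / rate}) and SD
#' (\code{sqrt(shape) / rate}) equal the inputs.
#'
#' @param mean,sd positive reals.
#' @param name optional parameter name for error messages.
#' @return named list with \code{shape} and \code{rate}.
#' @examples
#' fit_gamma_moments(335.4, 35)  # shape ~ 91.83, rate ~ 0.2738
#' @export
fit_gamma_moments <- function(mean, sd, name = NULL) {
  who <- if (is.null(name)) "" else sprintf(" for parameter '%s'", name)
  if (mean <= 0) stop("gamma requires mean > 0", who, call. = FALSE)
  if (sd <= 0) stop("gamma requires sd > 0", who, call. = FALSE)
  list(shape = mean^2 / sd^2, rate = mean / sd^2)
}

#' Fit a Beta distribution from its first two moments
#'
#' With \code{k = mean * (1 - mean) / sd^2 - 1}, returns
#' \code{alpha = mean * k} and \code{beta = (1 - mean) * k}. The moment
#' constraint \code{sd^2 < mean * (1 - mean)} must hold or no Beta
#' distribution has the requested moments.
#'
#' @param mean real in (0, 1).
#' @param sd positive real with \code{sd^2 < mean * (1 - mean)}.
#' @param name optional parameter name for error messages.
#' @return named list with \code{alpha} and \code{beta}.
#' @examples
#' fit_beta_moments(0.545, 0.035)  # alpha ~ 109.78, beta ~ 91.65
#' @export
fit_beta_moments <- function(mean, sd, name = NULL) {
  who <- if (is.null(name)) "" else sprintf(" for parameter '%s'", name)
  if (mean <= 0 || mean >= 1)
    stop("beta requires 0 < mean < 1", who, call. = FALSE)
  if (sd <= 0)
    stop("beta requires sd > 0", who, call. = FALSE)
  if (sd^2 >= mean * (1 - mean))
    stop(sprintf(
      "infeasible moments%s: sd^2 = %g must be < mean*(1-mean) = %g",
      who, sd^2, mean * (1 - mean)), call. = FALSE)
  k <- mean * (1 - mean) / sd^2 - 1
  list(alpha = mean * k, beta = (1 - mean) * k)
}

#' Draw from a distribution specification
#'
#' Samples \code{n} values from the fitted distribution, or replicates the
#' mean for a fixed spec. Draws consume the session RNG stream; pass
#' \code{seed} to make an individual call reproducible in isolation.
#'
#' @param spec a \code{\link{dist_spec}}.
#' @param n number of draws.
#' @param seed optional integer; if given, \code{set.seed(seed)} is called
#'   first.
#' @return numeric vector of length \code{n}; beta draws lie in (0, 1),
#'   gamma draws are positive.
#' @export
sample_dist <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  switch(spec$family,
    fixed = rep(spec$mean, n),
    gamma = stats::rgamma(n, shape = spec$shape, rate = spec$rate),
    beta  = stats::rbeta(n, shape1 = spec$alpha, shape2 = spec$beta))
}

#' @export
print.dist_spec <- function(x, ...) {
  if (x$family == "fixed") {
    cat(sprintf("fixed(%g)\n", x$mean))
  } else if (x$family == "gamma") {
    cat(sprintf("gamma(mean = %g, sd = %g; shape = %g, rate = %g)\n",
                x$mean, x$sd, x$shape, x$rate))
  } else {
    cat(sprintf("beta(mean = %g, sd = %g; alpha = %g, beta = %g)\n",
                x$mean, x$sd, x$alpha, x$beta))
  }
  invisible(x)
}

#' Pool health-state utilities by arithmetic mean
#'
#' Utility weights for a composite health state (e.g. depression pooled
#' over moderate and severe) are combined as a plain average.
#'
#' @param values numeric vector of utilities in [0, 1].
#' @return their arithmetic mean.
#' @examples
#' pool_utilities(c(0.57, 0.52))  # 0.545
#' @export
pool_utilities <- function(values) {
  if (length(values) == 0L)
    stop("cannot pool an empty utility vector", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)) ||
      any(values < 0 | values > 1))
    stop("utilities must be finite values in [0, 1]", call. = FALSE)
  mean(values)
}

#' Adjust a local-currency cost to target-year US dollars
#'
#' Applies a cumulative inflation multiplier and divides by an exchange
#' rate: \code{base_amount * inflation_factor / exchange_rate}. Used to
#' carry historical Iranian Rial cost figures to 2018 USD.
#'
#' @param base_amount cost in the original currency (e.g. Rials).
#' @param inflation_factor cumulative inflation multiplier between base
#'   and target year (> 0); 1 if the amount is already in target-year
#'   terms.
#' @param exchange_rate units of local currency per USD (> 0).
#' @return the adjusted cost in USD.
#' @examples
#' adjust_cost(14087678, 1, 42003)  # ~ 335.4 USD
#' @export
adjust_cost <- function(base_amount, inflation_factor, exchange_rate) {
  if (!is.numeric(inflation_factor) || inflation_factor <= 0)
    stop("inflation_factor must be > 0", call. = FALSE)
  if (!is.numeric(exchange_rate) || exchange_rate <= 0)
    stop("exchange_rate must be > 0", call. = FALSE)
  out <- base_amount * inflation_factor / exchange_rate
  if (any(out <= 0)) stop("adjusted cost must be positive", call. = FALSE)
  out
}
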
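#' Tumor specification
#'
#' Volume and clonogen density determine the initial clonogen number
#' K_0 = rho * V.
#'
#' @param volume gross tumor volume, cm^3, > 0.
#' @param rho clonogen density, cm^-3.
#' @return A `tumor_spec` list with `volume`, `rho`, `K_0`.
#' @export
tumor_spec <- function(volume, rho) {
  if (volume <= 0) stop("'volume' must be positive", call. = FALSE)
  if (rho <= 0) stop("'rho' must be positive", call. = FALSE)
  K_0 <- rho * volume
  if (K_0 < 1) stop("initial clonogen number K_0 must be >= 1", call. = FALSE)
  structure(list(volume = volume, rho = rho, K_0 = K_0), class = "tumor_spec")
}

#' Gaussian tumor control probability
#'
#' Control occurs when the surviving clonogen number falls below a critical
#' number K_cr; with a Gaussian spread sigma_k of clonogen numbers across
#' patients,
#' \deqn{TCP = 1 - \Phi(x_0), \qquad x_0 = \frac{K_0\,SF - K_{cr}}{\sigma_k},}
#' evaluated via the upper normal tail so it stays accurate far into either
#' tail. No truncation is applied to x_0; the algebraic value is used.
#'
#' @param sf surviving fraction(s), >= 0.
#' @param K_0 initial clonogen number, > 0.
#' @param K_cr critical clonogen number, > 0.
#' @param sigma_k spread of the clonogen-number distribution, > 0.
#' @return Probability in \[0, 1\] (vectorized over `sf`).
#' @examples
#' tcp_gaussian(sf = 0, K_0 = 2.43e11, K_cr = 2.367e9, sigma_k = 1.03e9)
#' @export
tcp_gaussian <- function(sf, K_0, K_cr, sigma_k) {
  if (any(sf < 0)) stop("'sf' must be non-negative", call. = FALSE)
  if (K_0 <= 0 || K_cr <= 0 || sigma_k <= 0)
    stop("counts must be positive", call. = FALSE)
  x0 <- (K_0 * sf - K_cr) / sigma_k
  pmin(pmax(stats::pnorm(x0, lower.tail = FALSE), 0), 1)
}

#' Poisson / binomial tumor control probability
#'
#' Probability that no clonogen survives: Poisson approximation
#' \eqn{\exp(-K_0\,SF)} or the exact binomial \eqn{(1 - SF)^{K_0}} (which
#' requires SF <= 1).
#'
#' @param sf surviving fraction(s).
#' @param K_0 initial clonogen number, > 0.
#' @param mode `"poisson"` (default) or `"binomial"`.
#' @return Probability in \[0, 1\] (vectorized over `sf`).
#' @export
tcp_poisson <- function(sf, K_0, mode = c("poisson", "binomial")) {
  mode <- match.arg(mode)
  if (any(sf < 0)) stop("'sf' must be non-negative", call. = FALSE)
  if (K_0 <= 0) stop("'K_0' must be positive", call. = FALSE)
  if (mode == "poisson") return(exp(-K_0 * sf))
  if (any(sf > 1))
    stop("binomial mode requires sf <= 1", call. = FALSE)
  exp(K_0 * log1p(-sf))
}

#' Time-dependent tumor control probability curve
#'
#' Maps the model surviving fraction at each follow-up time to a control
#' probability: the extended model uses the Gaussian TCP with its critical
#' clonogen number, the classical baseline the Poisson TCP. Since the
#' surviving fraction grows with time after treatment, TCP(t) is
#' non-increasing and plays the role of a model-implied progression-free
#' survivor function.
#'
#' @param params an [lqrg_params()] or [lq_params()] object.
#' @param schedule a [fx_schedule()].
#' @param tumor a [tumor_spec()]; if its `rho` differs from `params$rho` the
#'   parameter value wins (K_0 = params$rho * volume).
#' @param times months since the end of radiotherapy, non-negative and
#'   non-decreasing.
#' @param mode TCP mode for the classical baseline, see [tcp_poisson()].
#' @return Numeric vector of TCP values, one per time.
#' @examples
#' tcp_time_curve(lqrg_params(), group_schedule(62.89, 2.8),
#'                tumor_spec(108.51, lqrg_params()$rho), times = c(0, 12, 24))
#' @export
tcp_time_curve <- function(params, schedule, tumor, times,
                           mode = c("poisson", "binomial")) {
  if (any(times < 0)) stop("'times' must be non-negative", call. = FALSE)
  if (is.unsorted(times)) stop("'times' must be sorted", call. = FALSE)
  K_0 <- params$rho * tumor$volume
  sf <- surviving_fraction(params, schedule, months_to_hours(times))
  if (inherits(params, "lqrg_params")) {
    tcp_gaussian(sf, K_0, params$K_cr, params$sigma_k)
  } else {
    tcp_poisson(pmin(sf, 1), K_0, mode = match.arg(mode))
  }
}
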
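#' Generalized Lea-Catcheside dose-protraction factor
#'
#' The factor G(tau) in (0, 1] rescales the quadratic (two-track) cell-kill
#' term of a linear-quadratic dose-response according to how the dose is
#' protracted in time relative to a mono-exponential recovery process with
#' time constant `tau`:
#' \deqn{G(\tau) = \frac{2}{D^2}\int_0^T R(u)\,du \int_0^u R(w)\,
#'   e^{-(u-w)/\tau}\,dw}
#' where R(u) is the dose-rate function of the schedule and D the total dose.
#'
#' Instantaneous fractions are the delta-function limit of R(u) and are
#' handled exactly by the pairwise-exponential sum
#' \deqn{G = \frac{1}{D^2}\Big[\sum_i d_i^2 +
#'   2 \sum_i \sum_{j<i} d_i d_j e^{-(t_i-t_j)/\tau}\Big].}
#' Finite-duration fractions are treated as constant-rate blocks: the
#' within-block double integral is evaluated by adaptive quadrature (absolute
#' tolerance 1e-8) and cross-block/cross-fraction terms by the exact
#' exponential integrals. Results are cached per (schedule, tau) because G
#' sits inside optimizer loops.
#'
#' @param schedule a [fx_schedule()].
#' @param tau recovery time constant, hours, > 0.
#' @return G, a dimensionless factor in (0, 1].
#' @examples
#' lea_catcheside_g(uniform_schedule(1, 2, weekday_only = FALSE), tau = 6.32) # 1
#' lea_catcheside_g(uniform_schedule(30, 2.1), tau = 6.32)
#' @seealso [g_equal_fractions()] for the closed form with equal spacing,
#'   [complete_repair_g()] for the tau -> 0 limit.
#' @export
lea_catcheside_g <- function(schedule, tau) {
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a positive finite number", call. = FALSE)
  key <- paste(c(format(schedule$start_times, digits = 15),
                 format(schedule$doses, digits = 15),
                 format(schedule$durations, digits = 15),
                 format(tau, digits = 15)), collapse = "|")
  hit <- .g_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- if (is_instantaneous(schedule)) {
    .g_acute(schedule$start_times, schedule$doses, tau)
  } else {
    .g_protracted(schedule, tau)
  }
  g <- min(max(g, 0), 1)
  if (length(.g_cache) > 4096L) rm(list = ls(.g_cache), envir = .g_cache)
  assign(key, g, envir = .g_cache)
  g
}

.g_cache <- new.env(parent = emptyenv())

# exact pairwise sum for all-instantaneous delivery
.g_acute <- function(t, d, tau) {
  D <- sum(d)
  w <- exp(-abs(outer(t, t, "-")) / tau)
  sum(outer(d, d) * w) / D^2
}

# mixed constant-rate blocks / deltas; cross terms exact, within-block
# diagonal by adaptive quadrature
.g_protracted <- function(schedule, tau, abs_tol = 1e-8) {
  t0 <- schedule$start_times
  d <- schedule$doses
  dur <- schedule$durations
  D <- sum(d)
  n <- length(d)
  acc <- 0
  for (i in seq_len(n)) {
    # diagonal
    if (dur[i] == 0) {
      acc <- acc + d[i]^2
    } else {
      r <- d[i] / dur[i]
      f <- function(u) r^2 * tau * (1 - exp(-u / tau))
      acc <- acc + 2 * stats::integrate(f, 0, dur[i], abs.tol = abs_tol,
                                        rel.tol = 1e-10)$value
    }
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      acc <- acc + 2 * .g_cross(t0[i], d[i], dur[i], t0[j], d[j], dur[j], tau)
    }
  }
  acc / D^2
}

# exact \int_i R(u) \int_j R(w) exp(-(u-w)/tau) dw du for fraction i after j
.g_cross <- function(ti, di, dui, tj, dj, duj, tau) {
  if (dui == 0 && duj == 0)
    return(di * dj * exp(-(ti - tj) / tau))
  if (dui == 0) {               # delta at ti, block j on [tj, tj + duj]
    rj <- dj / duj
    return(di * rj * tau * (exp(-(ti - tj - duj) / tau) -
                            exp(-(ti - tj) / tau)))
  }
  if (duj == 0) {               # block i on [ti, ti + dui], delta at tj
    ri <- di / dui
    return(ri * tau * (exp(-(ti - tj) / tau) -
                       exp(-(ti + dui - tj) / tau)) * dj)
  }
  ri <- di / dui
  rj <- dj / duj
  ai <- ti; bi <- ti + dui; aj <- tj; bj <- tj + duj
  ri * rj * tau^2 * (exp(-(ai - bj) / tau) - exp(-(ai - aj) / tau) -
                     exp(-(bi - bj) / tau) + exp(-(bi - aj) / tau))
}

#' Closed-form G for equally spaced acute fractions
#'
#' Standard incomplete-repair result for n equal instantaneous fractions a
#' fixed interval apart:
#' \deqn{G = \frac{1}{n} + \frac{2}{n^2}\,\frac{\varphi}{1-\varphi}
#'   \left(n - \frac{1-\varphi^n}{1-\varphi}\right), \quad
#'   \varphi = e^{-\Delta t/\tau}.}
#'
#' @param n number of fractions, >= 1.
#' @param interval inter-fraction interval, hours, > 0.
#' @param tau recovery time constant, hours, > 0.
#' @return G in (0, 1].
#' @examples
#' g_equal_fractions(30, 24, 6.32)
#' @export
g_equal_fractions <- function(n, interval, tau) {
  if (n < 1 || n != round(n)) stop("'n' must be a positive integer", call. = FALSE)
  if (interval <= 0) stop("'interval' must be positive", call. = FALSE)
  if (tau <= 0) stop("'tau' must be positive", call. = FALSE)
  x <- interval / tau
  if (x < 1e-12) return(1)  # tau >> interval: no recovery between fractions
  phi <- exp(-x)
  # expm1 keeps 1 - phi^k accurate when x is tiny (the n - (...)/(...) term
  # cancels catastrophically otherwise)
  one_minus_phi <- -expm1(-x)
  ratio <- -expm1(-n * x) / one_minus_phi
  (1 / n) + (2 / n^2) * (phi / one_minus_phi) * (n - ratio)
}

#' Complete inter-fraction repair limit of G
#'
#' The tau -> 0 limit of the Lea-Catcheside factor, in which recovery between
#' fractions is complete and only within-fraction (here: within-instant)
#' two-track action survives: G = sum(d_i^2) / D^2, i.e. 1/n for uniform
#' schedules. This is the protraction factor implied by the conventional
#' fractionated linear-quadratic model.
#'
#' @param schedule a [fx_schedule()] with instantaneous fractions.
#' @return G in (0, 1].
#' @examples
#' complete_repair_g(group_schedule(62.92, 2.1)) # 1/30
#' @export
complete_repair_g <- function(schedule) {
  sum(schedule$doses^2) / total_dose(schedule)^2
}
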
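#' Surviving fraction of clonogenic cells
#'
#' For the extended model the log surviving fraction at elapsed time t after
#' the end of treatment is
#' \deqn{\ln SF(t) = -\alpha D - \beta G(\tau_R) D^2
#'   + \tfrac{1}{2}\sigma^2 G(\tau_S) D^2
#'   + \ln 2\,\frac{\max(0, T - T_k)}{\tau_P}
#'   + \left(\ln 2\,\frac{t}{\tau_P}\right)^{\delta},}
#' with D the total dose, T the overall treatment time and both G factors
#' evaluated on the same schedule. The first two terms are one-track and
#' two-track cell kill (with repair), the third is resensitization
#' (redistribution + reoxygenation), the fourth delayed intra-treatment
#' regrowth and the fifth Gompertzian post-treatment growth. The regrowth
#' term is clamped at zero before the regrowth delay T_k has elapsed.
#'
#' The classical baseline (`lq_params`) drops resensitization and Gompertzian
#' slowing (delta = 1) and assumes complete inter-fraction repair, so its
#' quadratic term is \eqn{-\beta G D^2} with \eqn{G = \sum d_i^2 / D^2}
#' (equal to 1/n, i.e. \eqn{-\beta D d}, for uniform schedules):
#' \deqn{\ln SF(t) = -\alpha D - \beta D d
#'   + \ln 2\,\max(0, T - T_k)/\tau_P + \ln 2\, t/\tau_P.}
#'
#' Time bookkeeping: T, T_k and t are converted to days before division by
#' the doubling time tau_P (days).
#'
#' @param params an [lqrg_params()] or [lq_params()] object.
#' @param schedule a [fx_schedule()].
#' @param t elapsed time since the end of treatment, hours, >= 0 (vectorized).
#' @return Surviving fraction(s), positive; may exceed 1 once regrowth
#'   outweighs cell kill.
#' @examples
#' surviving_fraction(lqrg_params(), group_schedule(64.07, 2.4),
#'                    t = months_to_hours(12))
#' @export
surviving_fraction <- function(params, schedule, t) {
  UseMethod("surviving_fraction")
}

#' @export
surviving_fraction.lqrg_params <- function(params, schedule, t) {
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  D <- total_dose(schedule)
  G_R <- lea_catcheside_g(schedule, params$tau_R)
  G_S <- lea_catcheside_g(schedule, params$tau_S)
  T_d <- hours_to_days(overall_time(schedule))
  Tk_d <- hours_to_days(params$T_k)
  t_d <- hours_to_days(t)
  expo <- -params$alpha * D - params$beta * G_R * D^2 +
    0.5 * params$sigma2 * G_S * D^2 +
    log(2) * pmax(0, T_d - Tk_d) / params$tau_P +
    (log(2) * t_d / params$tau_P)^params$delta
  exp(expo)
}

#' @export
surviving_fraction.lq_params <- function(params, schedule, t) {
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  D <- total_dose(schedule)
  if (is.na(fraction_size(schedule, strict = FALSE)))
    message("non-uniform fraction sizes: using G = sum(d_i^2)/D^2 in the quadratic term")
  G <- complete_repair_g(schedule)
  T_d <- hours_to_days(overall_time(schedule))
  Tk_d <- hours_to_days(params$T_k)
  t_d <- hours_to_days(t)
  expo <- -params$alpha * D - params$beta * G * D^2 +
    log(2) * pmax(0, T_d - Tk_d) / params$tau_P +
    log(2) * t_d / params$tau_P
  exp(expo)
}

#' Biologically effective dose of the extended model
#'
#' \deqn{BED = D + \frac{\beta G(\tau_R) D^2}{\alpha}
#'   - \frac{\tfrac{1}{2}\sigma^2 G(\tau_S) D^2}{\alpha}
#'   - \frac{\ln 2\,\max(0, T - T_k)}{\alpha\,\tau_P}}
#' so that at the end of treatment \eqn{-\ln SF(0) = \alpha \cdot BED}.
#'
#' @inheritParams surviving_fraction
#' @return BED in Gy.
#' @export
bed_lqrg <- function(params, schedule) {
  stopifnot(inherits(params, "lqrg_params"))
  D <- total_dose(schedule)
  G_R <- lea_catcheside_g(schedule, params$tau_R)
  G_S <- lea_catcheside_g(schedule, params$tau_S)
  T_d <- hours_to_days(overall_time(schedule))
  Tk_d <- hours_to_days(params$T_k)
  D + params$beta * G_R * D^2 / params$alpha -
    0.5 * params$sigma2 * G_S * D^2 / params$alpha -
    log(2) * pmax(0, T_d - Tk_d) / (params$alpha * params$tau_P)
}

#' Effective quadratic coefficient
#'
#' Recasts the two quadratic-in-dose terms of the extended model into
#' conventional linear-quadratic form, for a uniform schedule of n fractions
#' of size d:
#' \deqn{\beta_{eff} = n\,\beta\,G(\tau_R) - \tfrac{n}{2}\sigma^2 G(\tau_S),}
#' chosen so that \eqn{-\beta_{eff} D d} equals
#' \eqn{-\beta G(\tau_R) D^2 + \tfrac{1}{2}\sigma^2 G(\tau_S) D^2}. The ratio
#' alpha/beta_eff is then comparable with the classical alpha/beta.
#'
#' @inheritParams surviving_fraction
#' @return A list with `beta_eff` (Gy^-2), `alpha_over_beta_eff` (Gy; `NA`
#'   with `valid = FALSE` when beta_eff <= 0) and `valid`.
#' @export
beta_eff <- function(params, schedule) {
  stopifnot(inherits(params, "lqrg_params"))
  fraction_size(schedule)  # errors on non-uniform schedules
  n <- n_fractions(schedule)
  G_R <- lea_catcheside_g(schedule, params$tau_R)
  G_S <- lea_catcheside_g(schedule, params$tau_S)
  be <- n * params$beta * G_R - (n / 2) * params$sigma2 * G_S
  valid <- is.finite(be) && be > 0
  list(beta_eff = be,
       alpha_over_beta_eff = if (valid) params$alpha / be else NA_real_,
       valid = valid)
}
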
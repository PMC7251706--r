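# Shared fixtures: three-group hypo-fractionation cohort summaries
# (mean GTV dose Gy, median fraction size Gy, mean GTV volume cm^3).
grp_defs <- list(
  A = list(dose = 62.92, d = 2.1, vol = 105.83),
  B = list(dose = 64.07, d = 2.4, vol = 102.21),
  C = list(dose = 62.89, d = 2.8, vol = 108.51))

grp_schedules <- function() {
  lapply(grp_defs, function(g) group_schedule(g$dose, g$d))
}

# Noise-free fitting data: samples generated from the model itself.
fitdata_from_model <- function(params, times = seq(1, 48, by = 3)) {
  groups <- lapply(grp_defs, function(g) {
    sch <- group_schedule(g$dose, g$d)
    tum <- tumor_spec(g$vol, params$rho)
    list(schedule = sch, tumor = tum,
         samples = data.frame(
           time_months = times,
           lpfs = tcp_time_curve(params, sch, tum, times)))
  })
  tcp_fit_data(groups)
}

# Independent trapezoid oracle for the protraction double integral on a
# piecewise-constant dose-rate function (finite-duration blocks only).
trapezoid_g <- function(schedule, tau, n_grid = 2e5) {
  stopifnot(all(schedule$durations > 0))
  Tend <- max(schedule$start_times + schedule$durations)
  u <- seq(0, Tend, length.out = n_grid)
  R <- numeric(n_grid)
  for (i in seq_along(schedule$doses)) {
    a <- schedule$start_times[i]
    b <- a + schedule$durations[i]
    R <- R + ifelse(u >= a & u <= b, schedule$doses[i] / schedule$durations[i],
                    0)
  }
  du <- u[2] - u[1]
  # E(u_k) = int_0^{u_k} R(w) exp(-(u_k - w)/tau) dw via the exponential
  # recursion E_k = E_{k-1} e^{-du/tau} + trapezoid increment
  decay <- exp(-du / tau)
  E <- numeric(n_grid)
  for (k in 2:n_grid)
    E[k] <- E[k - 1] * decay + du * (R[k - 1] * decay + R[k]) / 2
  D <- sum(schedule$doses)
  integ <- sum((R[-1] * E[-1] + R[-n_grid] * E[-n_grid]) / 2) * du
  2 * integ / D^2
}
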
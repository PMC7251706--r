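#' Synthetic-cohort specification
#'
#' Describes a multi-group cohort with the statistical structure the TCP
#' analysis assumes: per-group sizes, schedule summaries (mean total dose and
#' median fraction size, from which a representative weekday schedule is
#' built), a log-normal GTV-volume distribution and a censoring model
#' (uniform follow-up horizon, emulating staggered accrual with a fixed
#' analysis date). The default emulates a three-group hypo-fractionation
#' cohort: 34/34/35 patients, mean doses 62.92/64.07/62.89 Gy, median
#' fraction sizes 2.1/2.4/2.8 Gy, mean GTV volumes 105.83/102.21/108.51 cm^3,
#' follow-up spanning 5.4 to 64.3 months.
#'
#' @param groups data frame with columns `group`, `n`, `mean_dose`,
#'   `fraction_size`, `mean_volume`.
#' @param volume_cv coefficient of variation of the log-normal GTV volumes.
#' @param horizon_min,horizon_max censoring horizon, months: each patient's
#'   administrative censoring time is uniform on this range.
#' @param grid_max,grid_step time grid (months) on which group TCP curves are
#'   tabulated for event sampling.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(groups = data.frame(
                          group = c("A", "B", "C"),
                          n = c(34L, 34L, 35L),
                          mean_dose = c(62.92, 64.07, 62.89),
                          fraction_size = c(2.1, 2.4, 2.8),
                          mean_volume = c(105.83, 102.21, 108.51)),
                        volume_cv = 0.5,
                        horizon_min = 5.4, horizon_max = 64.3,
                        grid_max = 72, grid_step = 0.25) {
  stopifnot(is.data.frame(groups),
            all(c("group", "n", "mean_dose", "fraction_size",
                  "mean_volume") %in% names(groups)))
  if (any(groups$n < 0)) stop("group sizes must be >= 0", call. = FALSE)
  if (any(groups$mean_dose <= 0) || any(groups$fraction_size <= 0) ||
      any(groups$mean_volume <= 0))
    stop("doses and volumes must be positive", call. = FALSE)
  if (volume_cv < 0) stop("'volume_cv' must be >= 0", call. = FALSE)
  if (horizon_min <= 0 || horizon_max < horizon_min)
    stop("need 0 < horizon_min <= horizon_max", call. = FALSE)
  structure(list(groups = groups, volume_cv = volume_cv,
                 horizon_min = horizon_min, horizon_max = horizon_max,
                 grid_max = max(grid_max, horizon_max),
                 grid_step = grid_step),
            class = "cohort_spec")
}

#' Representative schedules for a cohort specification
#'
#' @param spec a [cohort_spec()].
#' @return Named list of [fx_schedule()], one per group.
#' @export
cohort_schedules <- function(spec) {
  sch <- lapply(seq_len(nrow(spec$groups)), function(i)
    group_schedule(spec$groups$mean_dose[i], spec$groups$fraction_size[i]))
  names(sch) <- spec$groups$group
  sch
}

#' Sample an event time from a survivor curve
#'
#' Inverse-transform sampling from a model-implied survivor function S(t)
#' tabulated on a grid (here S(t) = TCP(t)): a uniform draw u maps to the
#' first time at which S drops below u, linearly interpolated between grid
#' points. Draws with u <= S(t_max) return `Inf` (no event within the
#' tabulated horizon); draws above S(0) return 0 (the tumor is never
#' controlled).
#'
#' @param times non-decreasing grid, months.
#' @param surv survivor values on the grid: non-increasing, in \[0, 1\].
#' @param u uniform(0, 1) draw(s).
#' @return Event time(s), months (possibly 0 or `Inf`).
#' @export
sample_event_time <- function(times, surv, u) {
  if (length(times) != length(surv) || length(times) < 2L)
    stop("'times' and 'surv' must be equal length >= 2", call. = FALSE)
  if (is.unsorted(times)) stop("'times' must be sorted", call. = FALSE)
  if (any(diff(surv) > 1e-12))
    stop("'surv' must be non-increasing", call. = FALSE)
  if (any(surv < 0) || any(surv > 1))
    stop("'surv' must lie in [0, 1]", call. = FALSE)
  vapply(u, function(ui) {
    if (ui <= surv[length(surv)]) return(Inf)
    if (ui >= surv[1L]) return(times[1L])
    k <- which(surv < ui)[1L]              # first grid point below u
    s0 <- surv[k - 1L]; s1 <- surv[k]
    t0 <- times[k - 1L]; t1 <- times[k]
    if (s0 - s1 < 1e-15) return(t1)
    t0 + (s0 - ui) / (s0 - s1) * (t1 - t0)
  }, 1)
}

# stable per-patient substream: reproducible under changes to other groups
.patient_seed <- function(master, group_index, patient_index) {
  as.integer((as.numeric(master) * 13 + group_index * 1e7 + patient_index) %%
               (2^31 - 1))
}

#' Simulate a patient cohort from a TCP model
#'
#' For each group a representative weekday schedule and a group-level TCP(t)
#' curve (at the group mean GTV volume, or per-patient volumes when
#' `per_patient_k0 = TRUE`) define the survivor function of loco-regional
#' failure. Per patient: a GTV volume is drawn log-normal, a failure time by
#' inverse-transform sampling, and an administrative censoring time uniform
#' on the follow-up horizon; the record keeps the earlier of the two. Only
#' loco-regional failure is simulated — deaths and distant-only progression,
#' censored in an LPFS analysis, are not events here. A single master seed
#' fans out to per-patient substreams, so records are reproducible even when
#' other groups' sizes change.
#'
#' @param spec a [cohort_spec()].
#' @param params an [lqrg_params()] (or [lq_params()]) object driving the
#'   TCP curves.
#' @param seed integer master seed.
#' @param per_patient_k0 logical: recompute the TCP curve per patient from
#'   that patient's drawn volume (slower); default uses the group curve.
#' @return Data frame of patient records: `group`, `gtv_cm3`, `time_months`,
#'   `event`.
#' @examples
#' rec <- simulate_cohort(cohort_spec(), lqrg_params(), seed = 7)
#' table(rec$group, rec$event)
#' @export
simulate_cohort <- function(spec, params, seed = 1L,
                            per_patient_k0 = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- seq(0, spec$grid_max, by = spec$grid_step)
  sdlog <- sqrt(log(1 + spec$volume_cv^2))
  out <- vector("list", nrow(spec$groups))
  for (gi in seq_len(nrow(spec$groups))) {
    g <- spec$groups[gi, ]
    if (g$n == 0L) next
    sched <- group_schedule(g$mean_dose, g$fraction_size)
    meanlog <- log(g$mean_volume) - sdlog^2 / 2
    group_curve <- if (!per_patient_k0)
      tcp_time_curve(params, sched, tumor_spec(g$mean_volume, params$rho),
                     grid)
    rec <- lapply(seq_len(g$n), function(pi) {
      set.seed(.patient_seed(seed, gi, pi))
      vol <- if (spec$volume_cv > 0) stats::rlnorm(1, meanlog, sdlog)
             else g$mean_volume
      u <- stats::runif(1)
      censor <- stats::runif(1, spec$horizon_min, spec$horizon_max)
      surv <- if (per_patient_k0)
        tcp_time_curve(params, sched, tumor_spec(vol, params$rho), grid)
      else group_curve
      ev_time <- sample_event_time(grid, cummin(surv), u)
      data.frame(group = g$group, gtv_cm3 = vol,
                 time_months = min(ev_time, censor),
                 event = as.integer(ev_time <= censor))
    })
    out[[gi]] <- do.call(rbind, rec)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(group = character(), gtv_cm3 = numeric(),
                      time_months = numeric(), event = integer())
  rownames(out) <- NULL
  out
}
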
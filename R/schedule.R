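#' Fractionation schedules
#'
#' A `fx_schedule` describes when and how much dose is delivered: fraction
#' start times (hours from the first fraction, strictly increasing), dose per
#' fraction (Gy, positive) and fraction durations (hours, 0 = instantaneous
#' delivery). Derived quantities are the total dose D, the fraction count n
#' and the overall treatment time T (start of first fraction to end of last).
#'
#' @param start_times numeric, hours from first fraction, strictly increasing.
#' @param doses numeric, Gy per fraction, all > 0.
#' @param durations numeric, hours >= 0; recycled if length 1.
#' @param target_total_dose optional Gy: a nominal prescription the schedule
#'   approximates (kept as metadata when a schedule is built from cohort
#'   summary statistics).
#'
#' @return An object of class `fx_schedule`.
#' @seealso [uniform_schedule()], [group_schedule()]
#' @export
fx_schedule <- function(start_times, doses, durations = 0,
                        target_total_dose = NULL) {
  start_times <- as.numeric(start_times)
  doses <- as.numeric(doses)
  durations <- rep_len(as.numeric(durations), length(start_times))
  if (length(start_times) < 1L)
    stop("a schedule needs at least one fraction", call. = FALSE)
  if (length(doses) != length(start_times))
    stop("'doses' and 'start_times' must have equal length", call. = FALSE)
  if (any(!is.finite(start_times)) || any(!is.finite(doses)) ||
      any(!is.finite(durations)))
    stop("schedule fields must be finite", call. = FALSE)
  if (is.unsorted(start_times, strictly = TRUE))
    stop("fraction start times must be strictly increasing", call. = FALSE)
  if (any(doses <= 0))
    stop("all fraction doses must be positive", call. = FALSE)
  if (any(durations < 0))
    stop("fraction durations must be non-negative", call. = FALSE)
  n <- length(start_times)
  if (n > 1L && any(start_times[-n] + durations[-n] > start_times[-1L]))
    stop("fraction durations must not overlap the next fraction", call. = FALSE)
  structure(
    list(start_times = start_times, doses = doses, durations = durations,
         target_total_dose = target_total_dose),
    class = "fx_schedule")
}

#' @export
print.fx_schedule <- function(x, ...) {
  cat(sprintf("Fractionation schedule: %d fraction(s), D = %.4g Gy, T = %.4g h (%.2f weeks)\n",
              n_fractions(x), total_dose(x), overall_time(x),
              overall_time(x) / (24 * 7)))
  if (!is.null(x$target_total_dose))
    cat(sprintf("  target total dose: %.4g Gy\n", x$target_total_dose))
  d <- unique(round(x$doses, 10))
  if (length(d) == 1L)
    cat(sprintf("  uniform %.4g Gy per fraction\n", d))
  invisible(x)
}

#' Schedule accessors
#'
#' @param schedule a [fx_schedule()].
#' @return `total_dose()` the total dose D in Gy; `n_fractions()` the fraction
#'   count; `overall_time()` the overall treatment time T in hours (start of
#'   first fraction to end of last); `fraction_size()` the common dose per
#'   fraction (error if non-uniform and `strict`).
#' @name schedule-accessors
#' @export
total_dose <- function(schedule) sum(schedule$doses)

#' @rdname schedule-accessors
#' @export
n_fractions <- function(schedule) length(schedule$doses)

#' @rdname schedule-accessors
#' @export
overall_time <- function(schedule) {
  n <- length(schedule$start_times)
  schedule$start_times[n] + schedule$durations[n] - schedule$start_times[1L]
}

#' @rdname schedule-accessors
#' @param strict error (TRUE) or return NA (FALSE) for non-uniform schedules.
#' @export
fraction_size <- function(schedule, strict = TRUE) {
  d <- unique(round(schedule$doses, 12))
  if (length(d) > 1L) {
    if (strict) stop("schedule has non-uniform fraction sizes", call. = FALSE)
    return(NA_real_)
  }
  schedule$doses[1L]
}

#' Is a schedule delivered in instantaneous fractions?
#' @param schedule a [fx_schedule()].
#' @export
is_instantaneous <- function(schedule) all(schedule$durations == 0)

#' Build a uniform fractionation schedule
#'
#' Once-daily weekday delivery is the clinical default: with
#' `weekday_only = TRUE` fractions skip every 6th and 7th day so five
#' fractions fall in each 7-day week (requires a 24 h interval).
#'
#' @param n_fractions integer >= 1.
#' @param dose_per_fraction Gy, > 0.
#' @param interval hours between fraction starts (> duration).
#' @param duration hours per fraction, >= 0 (0 = instantaneous).
#' @param weekday_only logical; insert weekend gaps after every 5th fraction.
#' @return A [fx_schedule()].
#' @examples
#' uniform_schedule(30, 2.1)          # 6 calendar weeks of weekday fractions
#' uniform_schedule(1, 2.0, weekday_only = FALSE)
#' @export
uniform_schedule <- function(n_fractions, dose_per_fraction, interval = 24,
                             duration = 0, weekday_only = TRUE) {
  if (length(n_fractions) != 1L || is.na(n_fractions) || n_fractions < 1 ||
      n_fractions != round(n_fractions))
    stop("'n_fractions' must be a positive integer", call. = FALSE)
  if (dose_per_fraction <= 0)
    stop("'dose_per_fraction' must be positive", call. = FALSE)
  if (duration < 0 || interval <= duration)
    stop("need interval > duration >= 0", call. = FALSE)
  k <- seq_len(n_fractions) - 1L
  if (weekday_only) {
    if (interval != 24)
      stop("'weekday_only' assumes one fraction per 24 h day", call. = FALSE)
    day <- (k %/% 5L) * 7L + (k %% 5L)
    starts <- day * 24
  } else {
    starts <- k * interval
  }
  fx_schedule(starts, rep(dose_per_fraction, n_fractions), duration)
}

#' Group-representative schedule from cohort summary statistics
#'
#' Reconstructs a uniform weekday schedule for a treatment group described
#' only by its mean total dose and median fraction size. The fraction count
#' is the nearest integer to their ratio. The group's mean total dose is a
#' measured quantity while the integer fraction count is a reconstruction
#' artifact, so the schedule delivers the mean total dose exactly
#' (d = D/n, within a few percent of the median fraction size) rather than
#' the rounded n x median product; both the nominal fraction size and the
#' target dose are recorded.
#'
#' @param mean_total_dose Gy, > 0.
#' @param median_fraction_size Gy, > 0.
#' @param ... passed to [uniform_schedule()] (interval, duration, weekday_only).
#' @return A [fx_schedule()] with `target_total_dose` and
#'   `nominal_fraction_size` set.
#' @examples
#' group_schedule(62.92, 2.1)  # 30 fractions
#' group_schedule(64.07, 2.4)  # 27 fractions
#' group_schedule(62.89, 2.8)  # 22 fractions
#' @export
group_schedule <- function(mean_total_dose, median_fraction_size, ...) {
  if (mean_total_dose <= 0 || median_fraction_size <= 0)
    stop("doses must be positive", call. = FALSE)
  n <- round(mean_total_dose / median_fraction_size)
  if (n < 1)
    stop("fraction count rounds to zero", call. = FALSE)
  sched <- uniform_schedule(n, mean_total_dose / n, ...)
  sched$target_total_dose <- mean_total_dose
  sched$nominal_fraction_size <- median_fraction_size
  sched
}

#' @export
as.data.frame.fx_schedule <- function(x, ...) {
  data.frame(t_start_h = x$start_times, dose_gy = x$doses,
             duration_h = x$durations)
}

#' Read / write schedule JSON
#'
#' Schedules serialize as `{"fractions": [{"t_start_h":, "dose_gy":,
#' "duration_h":}, ...]}`.
#'
#' @param schedule a [fx_schedule()].
#' @param path file path.
#' @return `read_schedule()` a [fx_schedule()]; `write_schedule()` the path,
#'   invisibly.
#' @export
write_schedule <- function(schedule, path) {
  obj <- list(fractions = as.data.frame(schedule))
  if (!is.null(schedule$target_total_dose))
    obj$target_total_dose_gy <- schedule$target_total_dose
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fr <- obj$fractions
  fx_schedule(fr$t_start_h, fr$dose_gy, fr$duration_h,
              target_total_dose = obj$target_total_dose_gy)
}
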
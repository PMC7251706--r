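#' Kaplan-Meier estimate of loco-regional progression-free survival
#'
#' Product-limit estimate of LPFS(t) from patient records. Time runs from the
#' end of radiotherapy; the event is loco-regional progression, and patients
#' who die or progress only distantly are censored (event = 0 / FALSE).
#' Ties are handled in the usual way: all events at a time are processed
#' before censorings at the same time.
#'
#' Estimation is delegated to [survival::survfit()]; the result is wrapped in
#' a lightweight `lpfs_curve` step function (right-continuous, starting at 1).
#'
#' @param records data frame with columns `time_months` (>= 0) and `event`
#'   (0/1 or logical); extra columns (`group`, `gtv_cm3`) are ignored here.
#' @param conf logical; keep Greenwood 95% confidence bounds.
#' @return An `lpfs_curve` with `time`, `surv`, `n_risk`, `n_event`,
#'   `n_censor` (and `lower`/`upper` if `conf`).
#' @examples
#' rec <- data.frame(time_months = c(5, 8, 12), event = c(1, 1, 0))
#' km_curve(rec)
#' @export
km_curve <- function(records, conf = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data frame", call. = FALSE)
  if (!all(c("time_months", "event") %in% names(records)))
    stop("'records' needs columns 'time_months' and 'event'", call. = FALSE)
  if (any(records$time_months < 0))
    stop("event times must be non-negative", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(time_months, as.integer(event)) ~ 1,
    data = records,
    conf.type = if (conf) "log" else "none")
  out <- list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
              n_event = fit$n.event, n_censor = fit$n.censor,
              n = nrow(records))
  if (conf) {
    out$lower <- fit$lower
    out$upper <- fit$upper
  }
  structure(out, class = "lpfs_curve")
}

#' @export
print.lpfs_curve <- function(x, ...) {
  cat(sprintf("LPFS curve: %d subjects, %d events, follow-up to %.3g months\n",
              x$n, sum(x$n_event), max(x$time)))
  invisible(x)
}

#' @export
as.data.frame.lpfs_curve <- function(x, ...) {
  data.frame(time_months = x$time, lpfs = x$surv, at_risk = x$n_risk,
             n_event = x$n_event, n_censor = x$n_censor)
}

#' Sample a survival curve at arbitrary times
#'
#' Right-continuous step lookup: S(t) is the value at the latest observed
#' time <= t, 1 before the first observation. Times beyond the last
#' observation return the last value, with attribute `extrapolated` marking
#' them.
#'
#' @param curve an `lpfs_curve` from [km_curve()].
#' @param times months, >= 0.
#' @return Numeric vector of survival probabilities with an `extrapolated`
#'   logical attribute.
#' @export
curve_at <- function(curve, times) {
  if (any(times < 0)) stop("'times' must be non-negative", call. = FALSE)
  fun <- stats::stepfun(curve$time, c(1, curve$surv), right = FALSE)
  out <- fun(times)
  attr(out, "extrapolated") <- times > max(curve$time)
  out
}

#' Fitting samples from an LPFS curve
#'
#' One (time, LPFS) sample per patient record, taken at that record's
#' observed time on the group's Kaplan-Meier curve. With one sample per
#' record the pooled sample count across groups equals the cohort size.
#'
#' @param records patient records for one group (see [km_curve()]).
#' @param curve optional precomputed `lpfs_curve`; estimated from `records`
#'   if missing.
#' @return data frame with `time_months` and `lpfs`, sorted by time.
#' @export
lpfs_samples <- function(records, curve = km_curve(records)) {
  t <- sort(records$time_months)
  data.frame(time_months = t, lpfs = as.numeric(curve_at(curve, t)))
}

#' Read / write patient-record CSV
#'
#' Columns: `group`, `gtv_cm3`, `time_months`, `event`.
#'
#' @param records data frame of patient records.
#' @param path file path.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "gtv_cm3", "time_months", "event")
  if (!all(need %in% names(rec)))
    stop("cohort CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  rec
}
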
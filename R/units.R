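#' Time-unit conversions
#'
#' Internal bookkeeping uses hours for delivery timing (inter-fraction
#' intervals and repair/resensitization constants are naturally expressed in
#' hours) while regrowth kinetics are expressed in days (doubling times) and
#' follow-up in months. These helpers convert at the boundaries; one month is
#' taken as 365.25/12 = 30.4375 days.
#'
#' @param x numeric vector of times.
#' @return numeric vector in the target unit.
#' @examples
#' hours_to_days(533.5) # 22.2 days
#' @name units
NULL

#' @rdname units
#' @export
hours_to_days <- function(x) x / 24

#' @rdname units
#' @export
days_to_hours <- function(x) x * 24

#' @rdname units
#' @export
months_to_days <- function(x) x * 30.4375

#' @rdname units
#' @export
months_to_hours <- function(x) x * 30.4375 * 24

#' @rdname units
#' @export
hours_to_months <- function(x) x / (30.4375 * 24)

#' @rdname units
#' @export
weeks_to_days <- function(x) x * 7
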
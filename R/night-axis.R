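#' The noon-anchored night axis
#'
#' All nocturnal timestamps inside the package live on a "night axis":
#' decimal hours elapsed since 12:00 noon of the evening a night begins
#' (its anchor date). A sleep onset at 23:30 sits at 11.5 on the axis and a
#' next-morning wake at 07:17 at 19.283. Because any plausible nocturnal
#' sleep episode falls strictly inside one noon-to-noon window, onset is
#' always less than wake on this axis and no arithmetic ever has to handle
#' the midnight wrap-around; ordinary linear means of axis values are exact.
#'
#' `clock_to_axis()` and `axis_to_clock()` convert between clock hours after
#' midnight (`[0, 24)`) and the axis; they are mutual inverses modulo 24.
#'
#' @param clock Numeric vector of clock hours after midnight in `[0, 24)`.
#' @param axis Numeric vector of night-axis hours in `[0, 24)`.
#' @return Numeric vector of the converted times.
#' @examples
#' clock_to_axis(0.25) # 00:15 -> 12.25
#' axis_to_clock(19)   # -> 7 (07:00 next morning)
#' @export
clock_to_axis <- function(clock) (clock + 12) %% 24

#' @rdname clock_to_axis
#' @export
axis_to_clock <- function(axis) (axis - 12) %% 24

#' Parse "HH:MM" clock strings to decimal hours
#'
#' @param x Character vector of times in `HH:MM` (24-hour clock).
#' @return Numeric vector of clock hours after midnight; `NA` for inputs
#'   that are not well-formed times.
#' @examples
#' parse_clock(c("00:15", "23:30", "7:05"))
#' @export
parse_clock <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x)
  if (any(ok)) {
    h <- as.numeric(sub(":.*", "", x[ok]))
    m <- as.numeric(sub(".*:", "", x[ok]))
    out[ok] <- h + m / 60
  }
  out
}

#' Classify nights as work or free
#'
#' A night is labelled by the evening it begins: nights starting on Friday
#' or Saturday are free nights, nights starting Sunday through Thursday are
#' work nights.
#'
#' @param anchor_date A `Date` vector (the calendar date of the evening the
#'   night begins).
#' @return Factor with levels `work`, `free`.
#' @examples
#' classify_night(as.Date(c("2017-04-07", "2017-04-09")))
#' @export
classify_night <- function(anchor_date) {
  stopifnot(inherits(anchor_date, "Date"))
  dow <- as.integer(format(anchor_date, "%w")) # 0 = Sunday ... 6 = Saturday
  factor(ifelse(dow %in% c(5L, 6L), "free", "work"), levels = c("work", "free"))
}

#' Sunday anchoring a calendar date's week
#'
#' @param anchor_date A `Date` vector.
#' @return `Date` vector: the Sunday on or before each input date, so a week
#'   of nights anchored here holds exactly 5 work and 2 free nights.
#' @export
week_start <- function(anchor_date) {
  stopifnot(inherits(anchor_date, "Date"))
  anchor_date - as.integer(format(anchor_date, "%w"))
}

#' Mid-sleep point of a nocturnal sleep episode
#'
#' The clock time halfway between sleep onset and final awakening. Onset and
#' wake are given on the noon-anchored night axis (see [clock_to_axis()]),
#' where the midpoint is a plain arithmetic mean; the result is converted
#' back to clock hours after midnight. Wake-after-sleep-onset plays no role:
#' mid-sleep is defined purely by the onset and wake timestamps.
#'
#' @param onset_axis,wake_axis Numeric vectors on the night axis, with
#'   `0 < onset_axis < wake_axis < 24` elementwise.
#' @return Numeric vector of mid-sleep clock hours after midnight.
#' @examples
#' # onset 00:00, wake 08:00 -> mid-sleep 4:00 am
#' mid_sleep(clock_to_axis(0), clock_to_axis(8))
#' @export
mid_sleep <- function(onset_axis, wake_axis) {
  bad <- !(onset_axis > 0 & onset_axis < wake_axis & wake_axis < 24)
  if (any(bad, na.rm = TRUE)) {
    stop("mid_sleep() requires 0 < onset_axis < wake_axis < 24 on the night axis")
  }
  axis_to_clock((onset_axis + wake_axis) / 2)
}
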
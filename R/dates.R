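#' Calendar origin and preconception exposure windows
#'
#' All exposure integration starts at the accident date, 1986-04-26, treated
#' as the start of that day (whole-day resolution; sub-day detail is carried
#' only inside occupancy timelines as hour offsets).  Doses are accumulated
#' until one of two individually defined end points: 51 or 38 weeks before
#' the child's date of birth (DOB-51 and DOB-38), bracketing the 3-month
#' preconception spermatid window.
#'
#' @name windows
NULL

#' Date of the accident (integration origin)
#'
#' @return A `Date`, 1986-04-26.
#' @export
accident_date <- function() as.Date("1986-04-26")

# last legal date of cleanup activities
mission_legal_end <- function() as.Date("1990-12-31")

#' End of a preconception exposure window
#'
#' Returns the window end date `dob - 7 * weeks` days.  The window itself is
#' `[accident_date(), window_end)`, end-exclusive: exposure on the end date
#' is not counted, which makes the DOB-51 to DOB-38 difference exactly
#' 91 days for every child.  If the end precedes the accident date the
#' window has zero length and all doses over it are zero.
#'
#' @param dob Child date of birth (`Date`), on or after the accident date.
#' @param weeks Number of weeks before birth; 51 for the spermatogonial
#'   stem-cell window, 38 for the full preconception window (0 is allowed
#'   and returns `dob`).
#' @return A `Date` vector.
#' @examples
#' window_end(as.Date("1987-03-14"), 38)  # 1986-06-21
#' @export
window_end <- function(dob, weeks) {
  dob <- as.Date(dob)
  if (any(is.na(dob))) stop("invalid date of birth")
  if (any(dob < accident_date()))
    stop("date of birth precedes the accident date (1986-04-26)")
  stopifnot(is.numeric(weeks), weeks >= 0)
  dob - 7L * as.integer(weeks)
}

#' Exposure window for one child
#'
#' @param dob Child date of birth.
#' @param kind `"DOB38"` or `"DOB51"`.
#' @return A list with `start`, `end` (Dates) and `kind`.  `end` may precede
#'   `start` (zero-length window).
#' @export
exposure_window <- function(dob, kind = c("DOB38", "DOB51")) {
  kind <- match.arg(kind)
  weeks <- if (kind == "DOB38") 38L else 51L
  structure(list(start = accident_date(), end = window_end(dob, weeks),
                 kind = kind),
            class = "exposure_window")
}

#' Cutoff date for cleanup-mission dose integration
#'
#' Mission doses are accumulated until the earliest of the preconception
#' window end, the end of the parent's cleanup activity, and 31 December
#' 1990 (last legal date of cleanup activities).
#'
#' @param window_end Window end date (`Date`).
#' @param mission_end Last date of the parent's cleanup activity (`Date`).
#' @return A `Date`: `min(window_end, mission_end, 1990-12-31)`.
#' @export
mission_cutoff <- function(window_end, mission_end) {
  pmin(as.Date(window_end), as.Date(mission_end), mission_legal_end())
}

#' Cohort eligibility of a child by date of birth
#'
#' Children are eligible if born 46 weeks (322 days) or later after the
#' accident, i.e. on or after 1987-03-14.
#'
#' @param dob Date of birth (`Date`).
#' @return Logical vector.
#' @export
is_eligible <- function(dob) {
  as.Date(dob) >= accident_date() + 322L
}

# dose-category bins (mGy): left-closed, matching the printed table labels
dose_bin_breaks <- c(0, 3, 10, 30, 100, 300, 1000, Inf)
dose_bin_labels <- c("<3", "3.0-9.99", "10-29.9", "30-99.9",
                     "100-299.9", "300-999.9", "1000+")

#' Dose-interval category of a gonadal dose
#'
#' Bins doses (mGy) into the seven reporting intervals
#' `[0,3), [3,10), [10,30), [30,100), [100,300), [300,1000), [1000,Inf)`.
#' Bins are left-closed, so a dose of exactly 3 mGy falls in "3.0-9.99".
#'
#' @param dose Nonnegative dose(s) in mGy.
#' @return A factor with the seven interval labels.
#' @export
dose_category <- function(dose) {
  if (any(is.na(dose)) || any(dose < 0)) stop("doses must be nonnegative")
  cut(dose, breaks = dose_bin_breaks, labels = dose_bin_labels,
      right = FALSE, include.lowest = TRUE)
}

# days since accident for a Date (or hours offset helper)
days_since_accident <- function(date) {
  as.numeric(as.Date(date) - accident_date())
}
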
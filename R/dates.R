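#' Zero-based study day index of a calendar date
#'
#' Days are counted from the study origin, which is day 0. With the default
#' origin of 2020-01-01, the first day of the Madagascar lockdown
#' (2020-03-23) is day 82; all modules share this convention.
#'
#' @param dates a `Date` vector or character vector in ISO-8601 form.
#' @param origin study start date (day 0).
#' @return integer vector of zero-based day indices.
#' @examples
#' study_day("2020-03-23")  # 82
#' @export
study_day <- function(dates, origin = "2020-01-01") {
  d <- as.Date(dates)
  if (anyNA(d)) {
    stop("unparseable date(s): ",
         paste(utils::head(dates[is.na(d)], 5L), collapse = ", "))
  }
  as.integer(d - as.Date(origin))
}

#' Length of a closed date interval in days
#'
#' Both endpoints are included, so 2020-01-01 to 2020-08-27 spans 240 days
#' (2020 is a leap year).
#'
#' @param start,end calendar dates (`Date` or ISO-8601 character).
#' @return integer number of days.
#' @export
study_length <- function(start, end) {
  n <- as.integer(as.Date(end) - as.Date(start)) + 1L
  if (is.na(n) || n < 1L) stop("study period end precedes start")
  n
}
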
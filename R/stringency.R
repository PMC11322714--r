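# Containment-and-closure policy indicators C1..C8 with their ordinal
# codebook bounds (school closure 0-3, workplace closure 0-3, cancel public
# events 0-2, gathering restrictions 0-4, public transport closure 0-2,
# stay-at-home requirements 0-3, internal movement restrictions 0-2,
# international travel controls 0-4). Their sum spans 0..23.
OXCGRT_BOUNDS <- c(C1 = 3L, C2 = 3L, C3 = 2L, C4 = 4L,
                   C5 = 2L, C6 = 3L, C7 = 2L, C8 = 4L)

check_indicator_levels <- function(levels, where = NULL) {
  if (length(levels) != 8L) {
    stop("expected 8 containment-and-closure indicator levels, got ",
         length(levels))
  }
  lv <- as.numeric(levels)
  bad <- which(is.na(lv) | lv < 0 | lv > OXCGRT_BOUNDS | lv != round(lv))
  if (length(bad)) {
    stop("indicator ", names(OXCGRT_BOUNDS)[bad[1L]],
         if (!is.null(where)) paste0(" (", where, ")"),
         " has invalid ordinal value ", levels[bad[1L]],
         " (allowed 0..", OXCGRT_BOUNDS[bad[1L]], ")")
  }
  as.integer(lv)
}

#' Containment stringency index from eight ordinal policy indicators
#'
#' The index is the plain sum of the eight containment-and-closure indicator
#' levels, so it ranges from 0 (no restrictions) to 23 (every indicator at
#' its codebook maximum 3, 3, 2, 4, 2, 3, 2, 4).
#'
#' @param levels numeric vector of 8 ordinal levels (C1..C8), or a matrix
#'   with 8 columns (one row per day).
#' @return integer index value(s) in 0..23.
#' @examples
#' containment_index(c(3, 3, 2, 4, 2, 3, 2, 4))  # 23
#' @export
containment_index <- function(levels) {
  if (is.matrix(levels) || is.data.frame(levels)) {
    m <- as.matrix(levels)
    if (ncol(m) != 8L) stop("expected 8 indicator columns, got ", ncol(m))
    return(as.integer(rowSums(matrix(
      vapply(seq_len(nrow(m)), function(i)
        check_indicator_levels(m[i, ], where = paste("row", i)),
        integer(8L)),
      ncol = 8L, byrow = TRUE))))
  }
  sum(check_indicator_levels(levels))
}

new_stringency_series <- function(date, levels, imputed = NULL) {
  stopifnot(nrow(levels) == length(date))
  out <- data.frame(date = as.Date(date), levels)
  names(out)[2:9] <- names(OXCGRT_BOUNDS)
  out$index <- as.integer(rowSums(out[, 2:9]))
  out$imputed <- if (is.null(imputed)) FALSE else as.logical(imputed)
  class(out) <- c("stringency_series", "data.frame")
  out
}

#' Parse an OxCGRT-style national policy file into a stringency series
#'
#' Reads the "compact" national CSV dialect (columns `CountryCode`, `Date` as
#' YYYYMMDD or ISO-8601, and ordinal columns `C1`..`C8` or `C1M`..`C8M`,
#' possibly with descriptive suffixes such as `C1M_School closing`). Flag
#' sub-columns (geographic scope) are ignored; only ordinal severity levels
#' enter the index. Missing indicator values are imputed as 0 (least severe)
#' with a warning and a per-day `imputed` flag; `missing = "carry"` instead
#' carries the last observed level forward.
#'
#' @param path CSV file path.
#' @param country_code ISO country code to select (e.g. `"MDG"`).
#' @param date_range optional length-2 vector of dates; rows outside the
#'   closed range are dropped.
#' @param missing `"zero"` (default) or `"carry"`.
#' @return a `stringency_series` data frame with one row per day: `date`,
#'   `C1`..`C8`, `index`, `imputed`.
#' @export
parse_policy_file <- function(path, country_code, date_range = NULL,
                              missing = c("zero", "carry")) {
  missing <- match.arg(missing)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("CountryCode", "Date") %in% names(raw))) {
    stop("policy file must have CountryCode and Date columns")
  }
  raw <- raw[raw$CountryCode == country_code, , drop = FALSE]
  if (nrow(raw) == 0L) stop("country ", country_code, " not found in ", path)

  cols <- character(8L)
  for (k in 1:8) {
    pat <- paste0("^C", k, "M?($|_|[^0-9A-Za-z])")
    hit <- grep(pat, names(raw), value = TRUE)
    hit <- hit[!grepl("Flag", hit, ignore.case = TRUE)]
    if (length(hit) != 1L) {
      stop("could not locate a unique ordinal column for indicator C", k)
    }
    cols[k] <- hit
  }

  dt <- raw$Date
  date <- if (all(grepl("^[0-9]{8}$", as.character(dt)))) {
    as.Date(as.character(dt), format = "%Y%m%d")
  } else {
    as.Date(as.character(dt))
  }
  if (anyNA(date)) stop("unparseable Date value in row ", which(is.na(date))[1L])
  ord <- order(date)
  raw <- raw[ord, , drop = FALSE]
  date <- date[ord]
  if (!is.null(date_range)) {
    keep <- date >= as.Date(date_range[1L]) & date <= as.Date(date_range[2L])
    raw <- raw[keep, , drop = FALSE]
    date <- date[keep]
    if (length(date) == 0L) stop("no rows in requested date range")
  }
  if (anyDuplicated(date)) stop("duplicate dates for country ", country_code)
  if (length(date) > 1L && any(diff(as.integer(date)) != 1L)) {
    stop("date gap in policy file for country ", country_code)
  }

  lev <- as.matrix(raw[, cols, drop = FALSE])
  storage.mode(lev) <- "numeric"
  imputed <- rowSums(is.na(lev)) > 0L
  if (any(imputed)) {
    if (missing == "carry") {
      for (k in 1:8) {
        v <- lev[, k]
        last <- 0
        for (i in seq_along(v)) {
          if (is.na(v[i])) v[i] <- last else last <- v[i]
        }
        lev[, k] <- v
      }
    } else {
      lev[is.na(lev)] <- 0
    }
    warning(sum(imputed), " day(s) had missing indicator values (",
            missing, " imputation applied)")
  }
  for (i in seq_len(nrow(lev))) {
    check_indicator_levels(lev[i, ], where = paste0("row ", i, ", ", date[i]))
  }
  colnames(lev) <- names(OXCGRT_BOUNDS)
  new_stringency_series(date, as.data.frame(lev), imputed)
}

#' Read a tidy per-day stringency table written by [write_stringency()]
#' @param path CSV path.
#' @return a `stringency_series`.
#' @export
read_stringency <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", names(OXCGRT_BOUNDS))
  if (!all(need %in% names(raw))) stop("not a tidy stringency table: ", path)
  for (i in seq_len(nrow(raw))) {
    check_indicator_levels(unlist(raw[i, names(OXCGRT_BOUNDS)]),
                           where = paste("row", i))
  }
  new_stringency_series(as.Date(raw$date), raw[, names(OXCGRT_BOUNDS)],
                        if ("imputed" %in% names(raw)) raw$imputed else NULL)
}

#' Write a stringency series as a tidy per-day CSV
#' @param series a `stringency_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stringency <- function(series, path) {
  stopifnot(inherits(series, "stringency_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Median stringency index over a date window
#'
#' @param series a `stringency_series`.
#' @param window length-2 vector: either calendar dates or zero-based day
#'   indices relative to the series start; the window is closed.
#' @return median of the daily index values in the window.
#' @export
median_index <- function(series, window) {
  stopifnot(inherits(series, "stringency_series"))
  if (length(window) != 2L) stop("window must have two endpoints")
  if (inherits(window, "Date") || is.character(window)) {
    keep <- series$date >= as.Date(window[1L]) & series$date <= as.Date(window[2L])
  } else {
    idx <- seq_len(nrow(series)) - 1L
    keep <- idx >= window[1L] & idx <= window[2L]
  }
  if (!any(keep)) stop("empty window")
  stats::median(series$index[keep])
}

#' First day on which the stringency index reaches a threshold
#'
#' A verification aid for the analysis cutoff: the headline cutoff is fixed
#' from the known policy date, and this function checks that the index series
#' indeed jumps there.
#'
#' @param series a `stringency_series`.
#' @param threshold minimum index value counting as "restrictions in force"
#'   (must be >= 1).
#' @return zero-based day index relative to the series start of the first day
#'   with `index >= threshold`, or `NA_integer_` if the threshold is never
#'   reached ("none").
#' @export
detect_cutoff <- function(series, threshold) {
  stopifnot(inherits(series, "stringency_series"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 1) {
    stop("threshold must be a single number >= 1")
  }
  hit <- which(series$index >= threshold)
  if (length(hit) == 0L) return(NA_integer_)
  hit[1L] - 1L
}

#' @export
print.stringency_series <- function(x, ...) {
  cat("Stringency series:", nrow(x), "days,",
      format(min(x$date)), "to", format(max(x$date)),
      "| index range", min(x$index), "-", max(x$index), "\n")
  invisible(x)
}
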
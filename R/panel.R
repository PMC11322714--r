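age_group_labels <- function(boundaries = c(25L, 30L)) {
  c(paste0("<", boundaries[1L]),
    paste0(boundaries[1L], "-", boundaries[2L]),
    paste0(">", boundaries[2L]))
}

#' Assign users to age groups
#'
#' The middle group is the closed interval `[boundaries[1], boundaries[2]]`
#' so that the three labels partition the integers: with the default
#' boundaries, ages below 25 map to `"<25"`, 25 to 30 inclusive to
#' `"25-30"`, and above 30 to `">30"`.
#'
#' @param age_years vector of ages in whole years.
#' @param boundaries two cut ages.
#' @return factor of group labels.
#' @examples
#' assign_age_group(c(24, 26, 31))
#' @export
assign_age_group <- function(age_years, boundaries = c(25L, 30L)) {
  if (any(age_years <= 0)) stop("non-positive age")
  if (any(age_years < 10 | age_years > 60)) {
    warning("age(s) outside the plausible 10-60 range")
  }
  labs <- age_group_labels(boundaries)
  out <- ifelse(age_years < boundaries[1L], labs[1L],
                ifelse(age_years <= boundaries[2L], labs[2L], labs[3L]))
  factor(out, levels = labs)
}

new_person_day_panel <- function(y, users, outcome, cutoff_day,
                                 origin = "2020-01-01") {
  stopifnot(nrow(y) == nrow(users))
  structure(list(y = y, users = users, outcome = outcome,
                 cutoff_day = as.integer(cutoff_day),
                 study_days = ncol(y), n_users = nrow(y),
                 origin = as.Date(origin)),
            class = "person_day_panel")
}

#' @export
print.person_day_panel <- function(x, ...) {
  cat("Person-day panel (", x$outcome, "): ", x$n_users, " users x ",
      x$study_days, " days = ", x$n_users * x$study_days,
      " person-days; ", sum(x$y), " events; cutoff day ", x$cutoff_day,
      "\n", sep = "")
  invisible(x)
}

#' Load a transaction event log
#'
#' Reads a delimited text file with header columns `user_id`, `date`
#' (ISO-8601), `event_type` and optional `amount`. Rows with an unknown
#' event type or unparseable date abort with the offending row number.
#' Events outside the study window are dropped with a warning reporting the
#' count; parsing is otherwise non-lossy (duplicates are kept for
#' [validate_constraints()] to adjudicate).
#'
#' @param path CSV file path.
#' @param study_start,study_end closed study window; events outside are
#'   dropped.
#' @return data frame of events: `user_id`, `date`, `event_type`, `amount`.
#' @export
load_events <- function(path, study_start = "2020-01-01",
                        study_end = "2020-08-27") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("user_id", "date", "event_type")
  if (!all(need %in% names(raw))) {
    stop("event log must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(data.frame(user_id = character(), date = as.Date(character()),
                      event_type = character(), amount = numeric()))
  }
  d <- as.Date(raw$date)
  if (anyNA(d)) {
    stop("unparseable date in row ", which(is.na(d))[1L], ": ",
         raw$date[which(is.na(d))[1L]])
  }
  badtype <- which(!raw$event_type %in% OUTCOME_TYPES)
  if (length(badtype)) {
    stop("unknown event_type in row ", badtype[1L], ": ",
         raw$event_type[badtype[1L]])
  }
  if (!is.null(raw$amount) && any(!is.na(raw$amount) & raw$amount < 0)) {
    stop("negative amount in row ",
         which(!is.na(raw$amount) & raw$amount < 0)[1L])
  }
  keep <- d >= as.Date(study_start) & d <= as.Date(study_end)
  if (any(!keep)) {
    warning(sum(!keep), " event(s) outside the study window dropped")
  }
  out <- data.frame(user_id = as.character(raw$user_id)[keep], date = d[keep],
                    event_type = raw$event_type[keep],
                    amount = if ("amount" %in% names(raw))
                      as.numeric(raw$amount)[keep] else NA_real_,
                    stringsAsFactors = FALSE)
  out[order(out$date, out$user_id), , drop = FALSE]
}

#' Load a user registry
#'
#' @param path CSV with columns `user_id`, `age_years` and optionally
#'   `enrollment_date`.
#' @param boundaries age-group cut ages passed to [assign_age_group()].
#' @param origin study day-0 date, used to convert enrollment dates to day
#'   indices.
#' @return registry data frame with `user_id`, `age_years`, `age_group` and,
#'   when present in the file, `enrollment_day`.
#' @export
load_registry <- function(path, boundaries = c(25L, 30L),
                          origin = "2020-01-01") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("user_id", "age_years") %in% names(raw))) {
    stop("registry must have columns user_id, age_years")
  }
  if (anyDuplicated(raw$user_id)) {
    stop("duplicate user_id in registry: ",
         raw$user_id[anyDuplicated(raw$user_id)])
  }
  out <- data.frame(user_id = as.character(raw$user_id),
                    age_years = as.integer(raw$age_years),
                    stringsAsFactors = FALSE)
  out$age_group <- assign_age_group(out$age_years, boundaries)
  if ("enrollment_date" %in% names(raw)) {
    out$enrollment_day <- study_day(raw$enrollment_date, origin)
  }
  out
}

#' Enforce per-user service constraints on an event log
#'
#' Payments after a user's chronologically first payment are excluded
#' (keep-first; the service allowed a single delivery payment per user).
#' Same-day duplicate vouchers for a user collapse to one (the service capped
#' voucher redemptions at one per user-day). Savings are unrestricted.
#' Violations are reported, not fatal.
#'
#' @param events event data frame as from [load_events()].
#' @return list with `events` (the retained rows) and `violations` (a data
#'   frame of excluded rows with a `reason` column).
#' @export
validate_constraints <- function(events) {
  events <- events[order(events$date, events$user_id), , drop = FALSE]
  drop <- rep(FALSE, nrow(events))
  reason <- rep(NA_character_, nrow(events))

  pay <- which(events$event_type == "payment")
  if (length(pay)) {
    dup <- pay[duplicated(events$user_id[pay])]
    drop[dup] <- TRUE
    reason[dup] <- "payment after user's first payment"
  }
  vch <- which(events$event_type == "voucher")
  if (length(vch)) {
    key <- paste(events$user_id[vch], events$date[vch])
    dup <- vch[duplicated(key)]
    drop[dup] <- TRUE
    reason[dup] <- "more than one voucher per user-day"
  }

  violations <- events[drop, , drop = FALSE]
  if (nrow(violations)) violations$reason <- reason[drop]
  else violations$reason <- character(0)
  list(events = events[!drop, , drop = FALSE], violations = violations)
}

#' Build a dense binary person-day panel for one outcome
#'
#' Every user x day cell is materialized; `y(u, t) = 1` iff at least one
#' event of the outcome type was recorded for user `u` on day `t`, so days
#' with no recorded event are coded 0 and repeated same-day events collapse
#' to a single 1 (active use, not volume).
#'
#' @param events validated event data frame.
#' @param users registry data frame (all panel users, including those with
#'   no events of this outcome).
#' @param study_days panel length in days.
#' @param outcome one of `"saving"`, `"payment"`, `"voucher"`.
#' @param cutoff_day zero-based policy cutoff day stored on the panel.
#' @param origin calendar date of day 0.
#' @return a `person_day_panel`.
#' @export
binarize <- function(events, users, study_days, outcome,
                     cutoff_day = 82L, origin = "2020-01-01") {
  stopifnot(outcome %in% OUTCOME_TYPES)
  ev <- events[events$event_type == outcome, , drop = FALSE]
  unknown <- setdiff(ev$user_id, users$user_id)
  if (length(unknown)) {
    stop("event(s) for user(s) absent from registry: ",
         paste(utils::head(unknown, 10L), collapse = ", "))
  }
  y <- matrix(0L, nrow = nrow(users), ncol = study_days,
              dimnames = list(users$user_id, NULL))
  if (nrow(ev)) {
    t_idx <- study_day(ev$date, origin)
    ok <- t_idx >= 0L & t_idx < study_days
    y[cbind(match(ev$user_id[ok], users$user_id), t_idx[ok] + 1L)] <- 1L
  }
  new_person_day_panel(y, users, outcome, cutoff_day, origin)
}

#' Per-day event rate series of a panel
#'
#' @param panel a `person_day_panel`.
#' @param stratum optional age-group label restricting the cohort.
#' @return numeric vector of length `study_days`: events per person per day.
#' @export
daily_rates <- function(panel, stratum = NULL) {
  y <- panel$y
  if (!is.null(stratum)) {
    sel <- panel$users$age_group == stratum
    if (!any(sel)) stop("no users in stratum ", stratum)
    y <- y[sel, , drop = FALSE]
  }
  colSums(y) / nrow(y)
}

#' Descriptive summary of a person-day panel
#'
#' Crude pre/post accounting: event totals and mean daily per-person rates
#' on each side of the cutoff, cohort size and age distribution.
#'
#' @param panel a `person_day_panel`.
#' @return a `panel_summary` list.
#' @export
summarize_panel <- function(panel) {
  stopifnot(inherits(panel, "person_day_panel"))
  days <- seq_len(panel$study_days) - 1L
  pre <- days < panel$cutoff_day
  y <- panel$y
  s <- list(
    outcome = panel$outcome,
    n_users = panel$n_users,
    study_days = panel$study_days,
    person_days = panel$n_users * panel$study_days,
    cutoff_day = panel$cutoff_day,
    events_total = sum(y),
    events_pre = sum(y[, pre, drop = FALSE]),
    events_post = sum(y[, !pre, drop = FALSE]),
    rate_pre = sum(y[, pre, drop = FALSE]) / (panel$n_users * sum(pre)),
    rate_post = sum(y[, !pre, drop = FALSE]) / (panel$n_users * sum(!pre)),
    users_active = sum(rowSums(y) > 0L),
    age_distribution = as.list(table(panel$users$age_group)),
    age_median = stats::median(panel$users$age_years),
    age_iqr = stats::IQR(panel$users$age_years, type = 2)
  )
  class(s) <- "panel_summary"
  s
}

#' @export
print.panel_summary <- function(x, ...) {
  cat("Panel summary (", x$outcome, ")\n", sep = "")
  cat("  users: ", x$n_users, " (active: ", x$users_active, "); days: ",
      x$study_days, "; person-days: ", x$person_days, "\n", sep = "")
  cat(sprintf("  events: %d total (%d pre, %d post); daily rate %.5f pre, %.5f post\n",
              x$events_total, x$events_pre, x$events_post,
              x$rate_pre, x$rate_post))
  cat("  ages: median ", x$age_median, " (IQR ", x$age_iqr, "); groups: ",
      paste(names(x$age_distribution), unlist(x$age_distribution),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a panel summary as JSON
#' @param summary a `panel_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a panel in long format
#'
#' One row per user-day: `user_id`, `day_index`, `outcome`, `y`.
#' @param panel a `person_day_panel`.
#' @param path output CSV path.
#' @param events_only write only rows with `y = 1` (the dense panel is
#'   recoverable from the registry and study length).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, events_only = TRUE) {
  if (events_only) {
    idx <- which(panel$y == 1L, arr.ind = TRUE)
    out <- data.frame(user_id = panel$users$user_id[idx[, 1L]],
                      day_index = idx[, 2L] - 1L,
                      outcome = panel$outcome, y = 1L)
    out <- out[order(out$day_index, out$user_id), , drop = FALSE]
  } else {
    out <- data.frame(
      user_id = rep(panel$users$user_id, times = panel$study_days),
      day_index = rep(seq_len(panel$study_days) - 1L, each = panel$n_users),
      outcome = panel$outcome,
      y = as.integer(panel$y)
    )
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
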
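OUTCOME_TYPES <- c("saving", "payment", "voucher")

default_outcome_params <- function() {
  # Default generating parameters: baseline per-person-day rate at day 0,
  # daily pre-cutoff trend IRR, multiplicative level change at the cutoff,
  # daily post-cutoff trend IRR.
  list(
    saving  = list(baseline_rate = 0.0090, pre_trend_irr = 1.0124,
                   jump_irr = 0.4152, post_trend_irr = 1.0113),
    payment = list(baseline_rate = 0.0026, pre_trend_irr = 1.0111,
                   jump_irr = 0.5412, post_trend_irr = 1.0054),
    voucher = list(baseline_rate = 0.0051, pre_trend_irr = 1.0034,
                   jump_irr = 0.5047, post_trend_irr = 1.0067)
  )
}

check_outcome_params <- function(p, outcome) {
  need <- c("baseline_rate", "pre_trend_irr", "jump_irr", "post_trend_irr")
  if (!all(need %in% names(p))) {
    stop("outcome '", outcome, "' must supply ", paste(need, collapse = ", "))
  }
  if (!(p$baseline_rate > 0 && p$baseline_rate < 1)) {
    stop("baseline_rate for '", outcome, "' must be in (0,1)")
  }
  for (f in c("pre_trend_irr", "jump_irr", "post_trend_irr")) {
    if (!(p[[f]] > 0)) stop(f, " for '", outcome, "' must be > 0")
  }
  p[need]
}

#' Configuration for the synthetic person-day cohort generator
#'
#' Defaults reproduce the structure of the motivating study: a fixed cohort
#' of 3416 users observed over 240 days (2020-01-01 to 2020-08-27) with a
#' lockdown cutoff at day 82 (2020-03-23), per-outcome log-linear daily event
#' rates with a multiplicative discontinuity at the cutoff, ages with median
#' 26 years and IQR 9, and the service's usage constraints (at most one
#' payment per user over the whole period; at most one voucher per user-day).
#'
#' @param n_users number of users in the fixed cohort.
#' @param study_days number of observed days.
#' @param cutoff_day zero-based day index at which the policy takes effect;
#'   the cutoff day itself belongs to the post period.
#' @param outcomes named list (names among `saving`, `payment`, `voucher`) of
#'   parameter blocks with `baseline_rate`, `pre_trend_irr`, `jump_irr`,
#'   `post_trend_irr`.
#' @param age_model list with `median_years`, `iqr_years`,
#'   `group_boundaries` (the two ages splitting "<25" / "25-30" / ">30").
#' @param age_overrides optional named list mapping age-group label to a list
#'   with any of `jump_irr`, `post_trend_irr`, overriding the outcome block
#'   for users in that group (same overrides applied to every outcome unless
#'   the entry is itself a named list of outcome blocks).
#' @param constraints list with `max_payments_per_user` and
#'   `max_vouchers_per_user_day` (each either 1 to enforce or `Inf`).
#' @param enrollment if `TRUE`, users receive an enrollment day drawn
#'   uniformly over the pre-cutoff period and contribute structural zeros
#'   before it; the default keeps the fixed fully-enrolled cohort implied by
#'   the person-day accounting n_users x study_days.
#' @param seed single integer driving all randomness; per-outcome substreams
#'   are derived deterministically from it.
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_users = 3416L, study_days = 240L, cutoff_day = 82L,
                       outcomes = default_outcome_params(),
                       age_model = list(median_years = 26, iqr_years = 9,
                                        group_boundaries = c(25L, 30L)),
                       age_overrides = NULL,
                       constraints = list(max_payments_per_user = 1,
                                          max_vouchers_per_user_day = 1),
                       enrollment = FALSE,
                       seed = 20200101L) {
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    stop("seed must be a single integer")
  }
  stopifnot(n_users >= 1, study_days >= 1)
  if (!(cutoff_day >= 0 && cutoff_day < study_days)) {
    stop("cutoff_day must satisfy 0 <= cutoff_day < study_days")
  }
  if (!all(names(outcomes) %in% OUTCOME_TYPES)) {
    stop("unknown outcome name(s): ",
         paste(setdiff(names(outcomes), OUTCOME_TYPES), collapse = ", "))
  }
  outcomes <- mapply(check_outcome_params, outcomes, names(outcomes),
                     SIMPLIFY = FALSE)
  if (!is.null(age_overrides)) {
    labs <- age_group_labels(age_model$group_boundaries)
    if (!all(names(age_overrides) %in% labs)) {
      stop("age_overrides names must be among: ", paste(labs, collapse = ", "))
    }
  }
  structure(list(n_users = as.integer(n_users),
                 study_days = as.integer(study_days),
                 cutoff_day = as.integer(cutoff_day),
                 outcomes = outcomes, age_model = age_model,
                 age_overrides = age_overrides, constraints = constraints,
                 enrollment = isTRUE(enrollment), seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from a declarative YAML file
#'
#' Key names are exactly the [sim_config()] fields.
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(sim_config, raw)
}

#' True per-person-day event probability curve of the generator
#'
#' `p(t) = baseline * pre^t` for `t < cutoff` and
#' `p(t) = baseline * pre^cutoff * jump * post^(t - cutoff)` for
#' `t >= cutoff`, i.e. log-linear in `t` on each side with a level shift at
#' the cutoff.
#'
#' @param params outcome parameter block (see [sim_config()]).
#' @param t vector of zero-based day indices.
#' @param cutoff_day zero-based cutoff day.
#' @return numeric vector of probabilities.
#' @export
true_rate <- function(params, t, cutoff_day) {
  pre <- params$baseline_rate * params$pre_trend_irr^t
  post <- params$baseline_rate * params$pre_trend_irr^cutoff_day *
    params$jump_irr * params$post_trend_irr^(t - cutoff_day)
  ifelse(t < cutoff_day, pre, post)
}

# Ages are drawn from a log-normal calibrated so that the median and IQR of
# the continuous distribution match the requested values, then rounded to
# integer years; cohort summaries (median/IQR) pin down only these
# two quantiles, so the family is a modelling choice.
draw_ages <- function(n, median_years, iqr_years) {
  mu <- log(median_years)
  sigma <- asinh(iqr_years / (2 * median_years)) / stats::qnorm(0.75)
  age <- round(stats::rlnorm(n, meanlog = mu, sdlog = sigma))
  pmin(pmax(age, 12L), 55L)
}

resolve_group_params <- function(config, outcome, group) {
  p <- config$outcomes[[outcome]]
  ov <- config$age_overrides[[group]]
  if (!is.null(ov)) {
    if (!is.null(ov[[outcome]]) && is.list(ov[[outcome]])) ov <- ov[[outcome]]
    for (f in intersect(names(ov), c("jump_irr", "post_trend_irr"))) {
      p[[f]] <- ov[[f]]
    }
  }
  p
}

sub_seed <- function(seed, k) {
  (abs(seed) + 7919L * k) %% 2147483629L
}

#' Simulate person-day event panels with a known discontinuity
#'
#' For every user, day and outcome an independent Bernoulli indicator is
#' drawn with the user's age-group rate curve [true_rate()]. Service
#' constraints are then enforced: a user's payment events after the first are
#' suppressed (keep-first), and voucher indicators are at most one per
#' user-day by construction. The generator refuses configurations whose rate
#' curve reaches 1 on any day.
#'
#' @param config a [sim_config()].
#' @return a list with components `panels` (named list of
#'   `person_day_panel`, one per configured outcome), `truth` (a `sim_truth`
#'   data frame of the generating log-linear coefficients per outcome and age
#'   group, plus the implied counterfactual crossing day), `users` (the
#'   simulated registry) and `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  days <- seq_len(config$study_days) - 1L
  labs <- age_group_labels(config$age_model$group_boundaries)

  # refuse configurations where the Bernoulli probability would be clipped
  for (oc in names(config$outcomes)) {
    for (g in labs) {
      p <- true_rate(resolve_group_params(config, oc, g), days,
                     config$cutoff_day)
      if (any(p >= 1)) {
        stop("event probability >= 1 for outcome '", oc, "', age group ", g,
             " at day ", days[which(p >= 1)[1L]])
      }
    }
  }

  set.seed(sub_seed(config$seed, 0L))
  ages <- draw_ages(config$n_users, config$age_model$median_years,
                    config$age_model$iqr_years)
  users <- data.frame(
    user_id = sprintf("u%05d", seq_len(config$n_users)),
    age_years = ages,
    age_group = assign_age_group(ages, config$age_model$group_boundaries),
    stringsAsFactors = FALSE
  )
  if (config$enrollment) {
    users$enrollment_day <- sample.int(max(config$cutoff_day, 1L),
                                       config$n_users, replace = TRUE) - 1L
  }

  truth <- NULL
  panels <- list()
  for (k in seq_along(config$outcomes)) {
    oc <- names(config$outcomes)[k]
    set.seed(sub_seed(config$seed, k))
    pmat <- matrix(0, nrow = length(labs), ncol = config$study_days,
                   dimnames = list(labs, NULL))
    for (g in labs) {
      gp <- resolve_group_params(config, oc, g)
      pmat[g, ] <- true_rate(gp, days, config$cutoff_day)
      b2 <- log(gp$jump_irr)
      b3 <- log(gp$post_trend_irr) - log(gp$pre_trend_irr)
      cross <- if (b2 == 0) 0
               else if (b3 == 0 || sign(-b2 / b3) < 0) Inf
               else -b2 / b3
      truth <- rbind(truth, data.frame(
        outcome = oc, age_group = g,
        intercept = log(gp$baseline_rate),
        pre_slope = log(gp$pre_trend_irr),
        log_jump = b2,
        post_slope = log(gp$post_trend_irr),
        slope_change = b3,
        crossing_day = cross,
        stringsAsFactors = FALSE
      ))
    }
    pu <- pmat[match(users$age_group, labs), , drop = FALSE]
    y <- matrix(
      as.integer(stats::runif(config$n_users * config$study_days) < pu),
      nrow = config$n_users
    )
    if (oc == "payment" &&
        is.finite(config$constraints$max_payments_per_user) &&
        config$constraints$max_payments_per_user == 1) {
      cs <- t(apply(y, 1L, cumsum))
      y[cs > 1L] <- 0L
    }
    if (config$enrollment) {
      enr <- outer(users$enrollment_day, days, ">")
      y[enr] <- 0L
    }
    rownames(y) <- users$user_id
    panels[[oc]] <- new_person_day_panel(y, users, oc, config$cutoff_day)
  }
  class(truth) <- c("sim_truth", "data.frame")
  list(panels = panels, truth = truth, users = users, config = config)
}

#' Simulate a step-function stringency series
#'
#' A stand-in for a parsed policy file: every day before the cutoff carries
#' `pre_levels`, every day at or after it carries `post_levels`.
#'
#' @param cutoff_day zero-based day on which the post levels start.
#' @param study_days total number of days.
#' @param pre_levels,post_levels length-8 ordinal indicator vectors within
#'   the codebook bounds.
#' @param origin calendar date of day 0.
#' @return a `stringency_series`.
#' @examples
#' s <- simulate_stringency(82, 240)
#' detect_cutoff(s, threshold = 10)  # 82
#' @export
simulate_stringency <- function(cutoff_day, study_days,
                                pre_levels = rep(0L, 8L),
                                post_levels = c(3L, 3L, 2L, 4L, 2L, 3L, 2L, 4L),
                                origin = "2020-01-01") {
  stopifnot(cutoff_day >= 0, cutoff_day <= study_days)
  pre <- check_indicator_levels(pre_levels, where = "pre_levels")
  post <- check_indicator_levels(post_levels, where = "post_levels")
  days <- seq_len(study_days) - 1L
  lev <- matrix(rep(pre, study_days), ncol = 8L, byrow = TRUE)
  lev[days >= cutoff_day, ] <- matrix(rep(post, sum(days >= cutoff_day)),
                                      ncol = 8L, byrow = TRUE)
  new_stringency_series(as.Date(origin) + days, as.data.frame(lev))
}

#' Write simulated panels as a transaction log CSV
#'
#' Emits the delimited format consumed by [load_events()]: columns
#' `user_id`, `date` (ISO-8601), `event_type`, `amount` (left empty; the
#' analysis concerns active use, not value).
#'
#' @param panels named list of `person_day_panel` (as from
#'   [simulate_panel()]`$panels`) or a single panel.
#' @param path output CSV path.
#' @param origin calendar date of day 0.
#' @return `path`, invisibly.
#' @export
write_transactions <- function(panels, path, origin = "2020-01-01") {
  if (inherits(panels, "person_day_panel")) panels <- list(panels)
  rows <- lapply(panels, function(p) {
    idx <- which(p$y == 1L, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    data.frame(user_id = p$users$user_id[idx[, 1L]],
               date = as.Date(origin) + (idx[, 2L] - 1L),
               event_type = p$outcome,
               amount = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(user_id = character(), date = as.Date(character()),
                      event_type = character(), amount = numeric())
  }
  out <- out[order(out$date, out$user_id, out$event_type), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a simulated user registry CSV
#'
#' Columns `user_id`, `age_years`, `enrollment_date` (ISO-8601; the study
#' origin when no enrollment mechanism was simulated).
#'
#' @param users registry data frame (as from [simulate_panel()]`$users`).
#' @param path output CSV path.
#' @param origin calendar date of day 0.
#' @return `path`, invisibly.
#' @export
write_registry <- function(users, path, origin = "2020-01-01") {
  enr <- if ("enrollment_day" %in% names(users)) users$enrollment_day else 0L
  out <- data.frame(user_id = users$user_id,
                    age_years = users$age_years,
                    enrollment_date = as.Date(origin) + enr,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
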
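#' Days until the post-cutoff rate crosses the pre-cutoff counterfactual
#'
#' On the log scale the extrapolated pre-cutoff counterfactual minus the
#' post-cutoff fitted line is `-beta2 - beta3 * s` at `s` days after the
#' cutoff, so the curves cross at `s* = -beta2 / beta3` whenever the jump
#' and the slope change have opposite signs and the crossing lies within
#' the horizon; otherwise the rate never recovers. A zero jump crosses at
#' 0 days; parallel lines (`beta3 = 0`) with a non-zero jump never cross.
#' The closed form can be cross-checked with `method = "numeric"`
#' (bisection on the log-rate difference over `[0, horizon]`).
#'
#' @param beta2 log jump at the cutoff (log of the jump IRR).
#' @param beta3 slope change on the log scale (log post-trend IRR minus log
#'   pre-trend IRR).
#' @param horizon_days crossings beyond this report "never"; the default 999
#'   matches the tabular sentinel.
#' @param method `"closed_form"` (default) or `"numeric"`.
#' @return a `recovery_result` list: `crossing_days_after_cutoff` (number,
#'   or `Inf` for "never"), `recovered`, `method`, `horizon_days`.
#' @examples
#' crossing_time(log(0.5047), log(1.0067) - log(1.0034))  # about 208 days
#' @export
crossing_time <- function(beta2, beta3, horizon_days = 999,
                          method = c("closed_form", "numeric")) {
  method <- match.arg(method)
  if (!is.finite(beta2) || !is.finite(beta3)) {
    stop("coefficients must be finite")
  }
  s <- if (method == "closed_form") {
    if (beta2 == 0) 0
    else if (beta3 == 0) Inf
    else {
      cand <- -beta2 / beta3
      if (cand < 0) Inf else cand
    }
  } else {
    gap <- function(s) -beta2 - beta3 * s
    if (beta2 == 0) 0
    else if (gap(0) * gap(horizon_days) > 0) Inf
    else stats::uniroot(gap, c(0, horizon_days), tol = 1e-9)$root
  }
  if (is.finite(s) && s > horizon_days) s <- Inf
  structure(list(crossing_days_after_cutoff = s,
                 recovered = is.finite(s),
                 method = method, horizon_days = horizon_days),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  if (x$recovered) {
    cat(sprintf("Recovery: crosses the counterfactual %.1f days after the cutoff (%s)\n",
                x$crossing_days_after_cutoff, x$method))
  } else {
    cat("Recovery: never crosses the counterfactual within",
        x$horizon_days, "days\n")
  }
  invisible(x)
}

rdd_crossing <- function(rdd_fit, horizon_days = 999) {
  b <- rdd_fit$fit$beta
  crossing_time(b[["lockdown"]], b[["time_c_lockdown"]], horizon_days)
}

#' Recovery times per age group and outcome
#'
#' For each stratum and outcome the segmented model is refitted on the
#' stratum's person-days and the crossing of the extrapolated pre-cutoff
#' counterfactual is computed from the fitted coefficients of that same
#' bandwidth-restricted model (the extrapolation runs beyond the window).
#' By default every stratum reuses the outcome's whole-cohort bandwidth. A
#' stratum whose window has an event-free side is reported as inestimable
#' (distinct from "never recovered").
#'
#' @param panels a `person_day_panel` or named list of them (one per
#'   outcome).
#' @param bandwidths single bandwidth in days, or named vector keyed by
#'   outcome, or `"auto"` to select per outcome via [ik_bandwidth()] on the
#'   whole-cohort daily rates.
#' @param cutoff_day zero-based cutoff day.
#' @param horizon_days crossings beyond this report "never".
#' @param strata stratum labels (default: the panel's age-group levels,
#'   plus `"all"`).
#' @param ... passed to [fit_rdd()].
#' @return a `recovery_table` data frame: `outcome`, `stratum`,
#'   `bandwidth_days`, `crossing_days_after_cutoff` (`Inf` = never),
#'   `recovered`, `estimable`, `log_jump`, `slope_change`.
#' @export
recovery_by_age <- function(panels, bandwidths = "auto",
                            cutoff_day = NULL, horizon_days = 999,
                            strata = NULL, ...) {
  if (inherits(panels, "person_day_panel")) {
    panels <- stats::setNames(list(panels), panels$outcome)
  }
  rows <- list()
  for (oc in names(panels)) {
    panel <- panels[[oc]]
    cd <- if (is.null(cutoff_day)) panel$cutoff_day else cutoff_day
    h <- if (identical(bandwidths, "auto")) {
      ik_bandwidth(daily_rates(panel), cd)$h_opt
    } else if (!is.null(names(bandwidths))) {
      if (!oc %in% names(bandwidths)) stop("no bandwidth for outcome ", oc)
      bandwidths[[oc]]
    } else bandwidths
    st <- if (is.null(strata)) c("all", levels(panel$users$age_group))
          else strata
    for (g in st) {
      gs <- if (identical(g, "all")) NULL else g
      res <- tryCatch(fit_rdd(panel, h, cutoff_day = cd, stratum = gs, ...),
                      error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = oc, stratum = g, bandwidth_days = h,
          crossing_days_after_cutoff = NA_real_, recovered = NA,
          estimable = FALSE, log_jump = NA_real_, slope_change = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        cr <- rdd_crossing(res, horizon_days)
        b <- res$fit$beta
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = oc, stratum = g, bandwidth_days = h,
          crossing_days_after_cutoff = cr$crossing_days_after_cutoff,
          recovered = cr$recovered, estimable = TRUE,
          log_jump = b[["lockdown"]], slope_change = b[["time_c_lockdown"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("recovery_table", "data.frame")
  out
}

#' Export a recovery table with the tabular "never" sentinel
#'
#' Strata whose post-cutoff rate never reaches the counterfactual are coded
#' with the sentinel (default 999 days); inestimable strata are written as
#' `"inestimable"`, never as the sentinel.
#'
#' @param table a `recovery_table`.
#' @param path output CSV path.
#' @param sentinel value written for "never".
#' @return `path`, invisibly.
#' @export
export_recovery <- function(table, path, sentinel = 999) {
  out <- table[, c("outcome", "stratum", "bandwidth_days")]
  cr <- table$crossing_days_after_cutoff
  out$crossing_days <- ifelse(!table$estimable, "inestimable",
                              ifelse(is.finite(cr),
                                     as.character(round(cr, 1)),
                                     as.character(sentinel)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
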
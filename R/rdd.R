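# Boundary local-linear kernel constants entering the plug-in bandwidth:
# C_K = (V_K / (4 C1^2))^(1/5) where the asymptotic bias of the one-sided
# local linear estimate is C1 h^2 m'' and its variance is
# V_K sigma^2 / (N h f). For the uniform kernel on [0,1): C1 = 1/12,
# V_K = 4, so C_K = 144^(1/5); for the triangular (edge) kernel C1 = 1/20,
# V_K = 4.8, so C_K = 480^(1/5) = 3.4375. The estimation stage uses an
# unweighted hard window, i.e. a uniform kernel, so that constant is the
# default.
ik_kernel_constant <- function(kernel = c("uniform", "triangular")) {
  kernel <- match.arg(kernel)
  switch(kernel, uniform = 144^(1/5), triangular = 480^(1/5))
}

# Final plug-in step, isolated so its N^(-1/5) rate is testable on its own:
# h = C_K * (2 sigma2 / (f * (curvature_gap^2 + regularization)))^(1/5) * N^(-1/5)
ik_plugin <- function(sigma2, fhat, curvature_gap_sq, regularization, n_obs,
                      kernel = "uniform") {
  ck <- ik_kernel_constant(kernel)
  ck * (2 * sigma2 / (fhat * (curvature_gap_sq + regularization)))^(1/5) *
    n_obs^(-1/5)
}

#' Imbens-Kalyanaraman plug-in bandwidth on a daily rate series
#'
#' Implements the stepwise plug-in recipe on the day-level aggregate event
#' rates: (1) a rule-of-thumb pilot window from the spread of the running
#' variable; (2) conditional variance and density at the cutoff from that
#' window; (3) third-derivative estimate from a global cubic, giving
#' second-stage windows in which local quadratics estimate the curvature on
#' each side; (4) regularized plug-in
#' `h = C_K (2 sigma^2(c) / (f(c) ((m''_+ - m''_-)^2 + r_+ + r_-)))^(1/5) N^(-1/5)`,
#' truncated to the days available on the shorter side and rounded to whole
#' days. The uniform-kernel constant is used because the estimation stage
#' applies an unweighted hard window.
#'
#' @param daily_rates numeric vector of per-day event rates (day 0 first).
#' @param cutoff_day zero-based cutoff; the cutoff day is post-side.
#' @param kernel `"uniform"` (default) or `"triangular"`.
#' @return an `ik_bandwidth` object: `h_opt` (whole days), `h_raw`, pilot
#'   quantities (`sigma2`, `fhat`, `m2_minus`, `m2_plus`, `m3`, `r_minus`,
#'   `r_plus`, `h1`, `h2_minus`, `h2_plus`) and the kernel name.
#' @export
ik_bandwidth <- function(daily_rates, cutoff_day,
                         kernel = c("uniform", "triangular")) {
  kernel <- match.arg(kernel)
  yv <- as.numeric(daily_rates)
  n_days <- length(yv)
  xv <- (seq_len(n_days) - 1L) - cutoff_day
  n_pre <- sum(xv < 0)
  n_post <- sum(xv >= 0)
  if (n_pre < 10L || n_post < 10L) {
    stop("need at least 10 days on each side of the cutoff")
  }

  # step 1: rule-of-thumb window; variance and density at the cutoff
  h1 <- 1.84 * stats::sd(xv) * n_days^(-1/5)
  left <- xv >= -h1 & xv < 0
  right <- xv >= 0 & xv <= h1
  n1l <- sum(left); n1r <- sum(right)
  fhat <- (n1l + n1r) / (2 * n_days * h1)
  ss <- sum((yv[left] - mean(yv[left]))^2) +
    sum((yv[right] - mean(yv[right]))^2)
  sigma2 <- ss / (n1l + n1r)
  if (sigma2 <= 0) {
    stop("no rate variation near the cutoff; supply a bandwidth manually")
  }

  # step 2: third derivative from a global cubic (jump absorbed by a dummy)
  d <- as.numeric(xv >= 0)
  cub <- stats::lm(yv ~ d + xv + I(xv^2) + I(xv^3))
  m3 <- 6 * stats::coef(cub)[["I(xv^3)"]]

  h2_for <- function(n_side, span) {
    h2 <- if (m3 == 0) span else {
      3.56 * (sigma2 / (fhat * m3^2))^(1/7) * n_side^(-1/7)
    }
    min(max(h2, 10), span)      # keep enough days for a quadratic fit
  }
  span_pre <- -min(xv)
  span_post <- max(xv) + 1
  h2m <- h2_for(n_pre, span_pre)
  h2p <- h2_for(n_post, span_post)

  # step 3: curvature each side from local quadratics
  lsel <- xv >= -h2m & xv < 0
  rsel <- xv >= 0 & xv <= h2p
  n2m <- sum(lsel); n2p <- sum(rsel)
  qm <- stats::lm(yv[lsel] ~ xv[lsel] + I(xv[lsel]^2))
  qp <- stats::lm(yv[rsel] ~ xv[rsel] + I(xv[rsel]^2))
  m2m <- 2 * stats::coef(qm)[[3L]]
  m2p <- 2 * stats::coef(qp)[[3L]]

  # step 4: regularized plug-in
  rm_ <- 2160 * sigma2 / (n2m * h2m^4)
  rp_ <- 2160 * sigma2 / (n2p * h2p^4)
  gap2 <- (m2p - m2m)^2
  if (gap2 + rm_ + rp_ == 0) {
    stop("curvature and regularization are both degenerate; ",
         "supply a bandwidth manually")
  }
  h_raw <- ik_plugin(sigma2, fhat, gap2, rm_ + rp_, n_days, kernel)
  h_cap <- min(n_pre, n_post)
  h_opt <- as.integer(max(2L, min(round(h_raw), h_cap)))

  structure(list(h_opt = h_opt, h_raw = h_raw, h_cap = h_cap,
                 sigma2 = sigma2, fhat = fhat, m3 = m3,
                 m2_minus = m2m, m2_plus = m2p,
                 r_minus = rm_, r_plus = rp_,
                 h1 = h1, h2_minus = h2m, h2_plus = h2p,
                 n_obs = n_days, kernel = kernel),
            class = "ik_bandwidth")
}

#' @export
print.ik_bandwidth <- function(x, ...) {
  cat(sprintf(
    "IK plug-in bandwidth: %d days (raw %.2f, cap %d; %s kernel)\n",
    x$h_opt, x$h_raw, x$h_cap, x$kernel))
  cat(sprintf("  sigma2(c)=%.3g  f(c)=%.3g  m2-=%.3g  m2+=%.3g  r-+=%.3g/%.3g\n",
              x$sigma2, x$fhat, x$m2_minus, x$m2_plus, x$r_minus, x$r_plus))
  invisible(x)
}

# Day-level segmented design: intercept, centered running variable,
# lockdown indicator, and their interaction. The cutoff day is post-side.
rdd_design <- function(days, cutoff_day) {
  time_c <- days - cutoff_day
  lockdown <- as.numeric(days >= cutoff_day)
  cbind(intercept = 1, time_c = time_c, lockdown = lockdown,
        time_c_lockdown = time_c * lockdown)
}

# Collapse person-day binaries inside the bandwidth window into weighted
# day rows (y = 1 with weight k_t, y = 0 with weight n_t - k_t). Because
# every covariate is a function of the day alone, the weighted fit and its
# HC0 sandwich are exactly those of the expanded person-day data.
aggregate_window <- function(panel, cutoff_day, bandwidth, stratum = NULL) {
  sel <- if (is.null(stratum)) rep(TRUE, panel$n_users)
         else panel$users$age_group == stratum
  if (!any(sel)) stop("no users in stratum ", stratum)
  days <- seq_len(panel$study_days) - 1L
  keep <- days >= cutoff_day - bandwidth & days <= cutoff_day + bandwidth &
    days >= 0L & days <= panel$study_days - 1L
  wdays <- days[keep]
  k <- colSums(panel$y[sel, keep, drop = FALSE])
  n_t <- sum(sel)
  if (sum(k[wdays < cutoff_day]) == 0L) {
    stop("zero events on the pre side of the cutoff within the bandwidth")
  }
  if (sum(k[wdays >= cutoff_day]) == 0L) {
    stop("zero events on the post side of the cutoff within the bandwidth")
  }
  list(days = wdays, events = k, n_users = n_t,
       y = c(rep(1, length(wdays)), rep(0, length(wdays))),
       w = c(k, n_t - k),
       x = rbind(rdd_design(wdays, cutoff_day), rdd_design(wdays, cutoff_day)),
       sel = sel, keep = keep)
}

#' Segmented modified Poisson regression around the cutoff
#'
#' Restricts the person-day panel to `|day - cutoff| <= bandwidth` (the
#' cutoff day itself is post-side), builds the design
#' `intercept + time_c + lockdown + time_c x lockdown` with the running
#' variable centered at the cutoff, fits a Poisson log-link model with
#' robust sandwich variance via [fit_poisson()], and maps the coefficients
#' to incidence rate ratios: the level discontinuity `exp(beta2)`, the
#' pre-cutoff daily trend `exp(beta1)`, the post-cutoff daily trend
#' `exp(beta1 + beta3)`, and the baseline rate at study day 0 obtained by
#' extrapolating the pre-cutoff line back to the study start,
#' `exp(beta0 - cutoff * beta1)` (the window-local intercept `exp(beta0)`,
#' the pre line evaluated at the cutoff, is reported alongside).
#'
#' @param panel a `person_day_panel`.
#' @param bandwidth_days window half-width in days.
#' @param cutoff_day zero-based cutoff day (defaults to the panel's).
#' @param stratum optional age-group label.
#' @param variance `"HC0"` (default), `"HC1"`, or `"cluster"` (by user).
#' @return an `rdd_fit`: IRR table (`irr`), coefficient table
#'   (`coefficients`), the underlying `poisson_fit` (`fit`), and metadata.
#' @export
fit_rdd <- function(panel, bandwidth_days, cutoff_day = panel$cutoff_day,
                    stratum = NULL, variance = c("HC0", "HC1", "cluster")) {
  variance <- match.arg(variance)
  stopifnot(inherits(panel, "person_day_panel"), bandwidth_days >= 2)
  agg <- aggregate_window(panel, cutoff_day, bandwidth_days, stratum)
  fit <- fit_poisson(agg$x, agg$y, weights = agg$w)

  if (variance == "HC1") {
    fit$cov_robust <- sandwich_cov(fit, type = "HC1")
  } else if (variance == "cluster") {
    # user-level score sums computed from the panel without expansion
    xd <- rdd_design(agg$days, cutoff_day)
    mu_d <- exp(drop(xd %*% fit$beta))
    yw <- panel$y[agg$sel, agg$keep, drop = FALSE]
    scores <- yw %*% xd - matrix(drop(crossprod(mu_d, xd)),
                                 nrow(yw), ncol(xd), byrow = TRUE)
    bread <- crossprod(xd, xd * (agg$n_users * mu_d))
    binv <- solve(bread)
    v <- binv %*% crossprod(scores) %*% binv
    dimnames(v) <- dimnames(fit$cov_robust)
    fit$cov_robust <- (v + t(v)) / 2
  }

  vc <- fit$cov_robust
  zq <- stats::qnorm(0.975)
  lincom <- function(a, label) {
    est <- sum(a * fit$beta)
    se <- sqrt(drop(t(a) %*% vc %*% a))
    data.frame(term = label, irr = exp(est),
               conf_low = exp(est - zq * se), conf_high = exp(est + zq * se),
               p = 2 * stats::pnorm(-abs(est / se)), se_log = se,
               stringsAsFactors = FALSE)
  }
  irr <- rbind(
    lincom(c(1, -cutoff_day, 0, 0), "baseline_day0"),
    lincom(c(1, 0, 0, 0), "pre_rate_at_cutoff"),
    lincom(c(0, 0, 1, 0), "jump"),
    lincom(c(0, 1, 0, 0), "pre_trend"),
    lincom(c(0, 1, 0, 1), "post_trend"),
    lincom(c(0, 0, 0, 1), "trend_change")
  )

  coefs <- do.call(rbind, lapply(names(fit$beta), function(nm) {
    r <- wald(fit, nm)
    r$se_model <- sqrt(fit$cov_model[nm, nm])
    r
  }))

  structure(list(outcome = panel$outcome,
                 stratum = if (is.null(stratum)) "all" else as.character(stratum),
                 bandwidth_days = as.integer(bandwidth_days),
                 cutoff_day = as.integer(cutoff_day),
                 variance = variance,
                 irr = irr, coefficients = coefs, fit = fit,
                 n_persondays = agg$n_users * length(agg$days),
                 n_users = agg$n_users,
                 n_events = sum(agg$events),
                 window = range(agg$days)),
            class = "rdd_fit")
}

#' @export
print.rdd_fit <- function(x, ...) {
  cat(sprintf(
    "RDD fit: outcome '%s', stratum %s, bandwidth %d days (days %d-%d), %s variance\n",
    x$outcome, x$stratum, x$bandwidth_days, x$window[1L], x$window[2L],
    x$variance))
  cat(sprintf("  %d users, %d person-days, %d events\n",
              x$n_users, x$n_persondays, x$n_events))
  tab <- x$irr
  tab$irr <- signif(tab$irr, 4)
  tab$conf_low <- signif(tab$conf_low, 4)
  tab$conf_high <- signif(tab$conf_high, 4)
  tab$p <- signif(tab$p, 2)
  print(tab[, c("term", "irr", "conf_low", "conf_high", "p")],
        row.names = FALSE)
  invisible(x)
}

irr_row <- function(fit, term) {
  fit$irr[fit$irr$term == term, , drop = FALSE]
}

#' Convert an incidence rate ratio to a signed percent change
#'
#' `(1 - irr) * 100`, rounded to one decimal for display, so an IRR of
#' 0.4152 prints as a 58.5% decrease; IRRs above 1 give negative values
#' (i.e. increases).
#'
#' @param irr positive incidence rate ratio.
#' @return signed percent decrease, one decimal.
#' @examples
#' irr_to_percent_change(0.4152)  # 58.5
#' @export
irr_to_percent_change <- function(irr) {
  if (any(!is.finite(irr) | irr <= 0)) stop("irr must be positive")
  round((1 - irr) * 100, 1)
}

#' Refit the discontinuity over a grid of bandwidths
#'
#' Robustness scan: refits at `h_opt - delta, ..., h_opt + delta` in steps
#' of `step` days and tabulates the jump IRR with its CI per bandwidth. A
#' failing refit (e.g. an event-free side at a narrow bandwidth) is recorded
#' and the scan continues.
#'
#' @param panel a `person_day_panel`.
#' @param h_opt central bandwidth in days.
#' @param delta half-range of the scan (days).
#' @param step grid step (days).
#' @param cutoff_day zero-based cutoff day.
#' @param stratum optional age-group label.
#' @param ... passed to [fit_rdd()].
#' @return an `rdd_sensitivity` data frame: `outcome`, `stratum`,
#'   `bandwidth`, `irr_jump`, `conf_low`, `conf_high`, `p`, `log_jump_sign`,
#'   `error`; the attribute `sign_change` flags any sign flip of the
#'   log-jump across the grid.
#' @export
sensitivity_scan <- function(panel, h_opt, delta = 20L, step = 5L,
                             cutoff_day = panel$cutoff_day, stratum = NULL,
                             ...) {
  stopifnot(delta >= 0, step >= 1)
  hs <- unique(c(seq(h_opt - delta, h_opt + delta, by = step), h_opt + delta))
  hs <- hs[hs >= 2]
  if (length(hs) == 0L) stop("no viable bandwidths in the scan range")
  rows <- lapply(hs, function(h) {
    res <- tryCatch(fit_rdd(panel, h, cutoff_day = cutoff_day,
                            stratum = stratum, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(outcome = panel$outcome,
                 stratum = if (is.null(stratum)) "all" else as.character(stratum),
                 bandwidth = h, irr_jump = NA_real_, conf_low = NA_real_,
                 conf_high = NA_real_, p = NA_real_,
                 log_jump_sign = NA_real_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      j <- irr_row(res, "jump")
      data.frame(outcome = res$outcome, stratum = res$stratum, bandwidth = h,
                 irr_jump = j$irr, conf_low = j$conf_low,
                 conf_high = j$conf_high, p = j$p,
                 log_jump_sign = sign(log(j$irr)),
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  sgn <- out$log_jump_sign[!is.na(out$log_jump_sign)]
  attr(out, "sign_change") <- length(unique(sgn[sgn != 0])) > 1L
  class(out) <- c("rdd_sensitivity", "data.frame")
  out
}

#' Tabulate RDD fits in the headline report shape
#'
#' One row per outcome x stratum: baseline IRR, jump IRR with CI and p,
#' pre- and post-trend IRRs with CIs, the p-value for the slope change, the
#' percent change at the cutoff, and the bandwidth used.
#'
#' @param fits an `rdd_fit` or list of them.
#' @return data frame.
#' @export
report_table <- function(fits) {
  if (inherits(fits, "rdd_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    b <- irr_row(f, "baseline_day0"); j <- irr_row(f, "jump")
    pr <- irr_row(f, "pre_trend"); po <- irr_row(f, "post_trend")
    tc <- irr_row(f, "trend_change")
    data.frame(outcome = f$outcome, stratum = f$stratum,
               bandwidth_days = f$bandwidth_days,
               irr_baseline = b$irr, baseline_low = b$conf_low,
               baseline_high = b$conf_high,
               irr_jump = j$irr, jump_low = j$conf_low,
               jump_high = j$conf_high, p_jump = j$p,
               percent_change = irr_to_percent_change(j$irr),
               irr_pre_trend = pr$irr, pre_low = pr$conf_low,
               pre_high = pr$conf_high,
               irr_post_trend = po$irr, post_low = po$conf_low,
               post_high = po$conf_high,
               p_trend_change = tc$p,
               stringsAsFactors = FALSE)
  }))
}

#' Write a report table as CSV and JSON
#' @param table data frame from [report_table()].
#' @param path output path without extension (writes `path.csv` and
#'   `path.json`).
#' @return the two paths, invisibly.
#' @export
write_report <- function(table, path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  utils::write.csv(table, csv, row.names = FALSE)
  jsonlite::write_json(table, js, digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}

#' Plot daily event counts with the fitted discontinuity
#'
#' Daily aggregate counts as points, the fitted segmented rate (scaled to
#' counts) as solid lines on each side of the cutoff, and the extrapolated
#' pre-cutoff counterfactual as a dashed line.
#'
#' @param x an `rdd_fit`.
#' @param panel the `person_day_panel` the fit came from.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rdd_fit <- function(x, panel, ...) {
  days <- seq_len(panel$study_days) - 1L
  counts <- colSums(panel$y)
  n <- panel$n_users
  b <- x$fit$beta
  tc <- days - x$cutoff_day
  pre_line <- n * exp(b[["intercept"]] + b[["time_c"]] * tc)
  post_line <- n * exp(b[["intercept"]] + b[["lockdown"]] +
                         (b[["time_c"]] + b[["time_c_lockdown"]]) * tc)
  graphics::plot(days, counts, pch = 16, cex = 0.5, col = "steelblue",
                 xlab = "study day", ylab = "events per day",
                 main = paste0(x$outcome, " (h = ", x$bandwidth_days, " d)"),
                 ...)
  pre <- days < x$cutoff_day
  graphics::lines(days[pre], pre_line[pre], col = "red", lwd = 2)
  graphics::lines(days[!pre], post_line[!pre], col = "red", lwd = 2)
  graphics::lines(days[!pre], pre_line[!pre], col = "grey30", lty = 2)
  graphics::abline(v = x$cutoff_day - 0.5, col = "blue", lty = 3)
  invisible(x)
}
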
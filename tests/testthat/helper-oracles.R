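# Independent oracles used across tests. These deliberately re-derive the
# quantities through different code paths than the package (Newton with
# analytic derivatives and step-halving here vs IRLS in the package; grid
# search vs plug-in for bandwidths) so agreement is informative.

# Newton-Raphson maximizer of the weighted Poisson log-likelihood with log
# link: gradient X'W(y - mu), Hessian -X' diag(w mu) X, with step-halving.
newton_poisson <- function(x, y, weights = NULL, offset = NULL,
                           tol = 1e-12, max_iter = 200L) {
  x <- as.matrix(x)
  w <- if (is.null(weights)) rep(1, nrow(x)) else weights
  off <- if (is.null(offset)) rep(0, nrow(x)) else offset
  ll <- function(b) {
    eta <- drop(x %*% b) + off
    sum(w * (y * eta - exp(eta)))
  }
  beta <- numeric(ncol(x))
  l_old <- ll(beta)
  for (i in seq_len(max_iter)) {
    mu <- exp(drop(x %*% beta) + off)
    grad <- drop(crossprod(x, w * (y - mu)))
    hess <- crossprod(x, x * (w * mu))
    step <- solve(hess, grad)
    t_ <- 1
    repeat {
      cand <- beta + t_ * step
      if (ll(cand) >= l_old - 1e-12 || t_ < 1e-8) break
      t_ <- t_ / 2
    }
    beta <- beta + t_ * step
    l_new <- ll(beta)
    if (abs(l_new - l_old) < tol * (abs(l_new) + 1)) break
    l_old <- l_new
  }
  beta
}

# Expand a panel's window into one row per person-day (slow, explicit).
expand_person_days <- function(panel, days, stratum = NULL) {
  sel <- if (is.null(stratum)) rep(TRUE, panel$n_users)
         else panel$users$age_group == stratum
  y <- panel$y[sel, days + 1L, drop = FALSE]
  data.frame(y = as.vector(y),
             day = rep(days, each = nrow(y)))
}

# Daily aggregate rate series from binomial sampling around a known curve;
# used for bandwidth-selector experiments without building full panels.
simulate_rate_series <- function(params, n_users, study_days, cutoff_day) {
  t <- seq_len(study_days) - 1L
  p <- true_rate(params, t, cutoff_day)
  stats::rbinom(study_days, n_users, p) / n_users
}

# Uniform-kernel local-linear jump estimate on a rate series: separate
# unweighted linear fits within h days on each side, evaluated at the
# cutoff. This is the estimator class whose MSE the bandwidth selector is
# meant to optimize.
local_linear_jump <- function(rates, cutoff_day, h) {
  t <- seq_along(rates) - 1L
  x <- t - cutoff_day
  lsel <- x >= -h & x < 0
  rsel <- x >= 0 & x <= h
  fl <- stats::lm.fit(cbind(1, x[lsel]), rates[lsel])
  fr <- stats::lm.fit(cbind(1, x[rsel]), rates[rsel])
  fr$coefficients[1L] - fl$coefficients[1L]
}

default_saving_params <- function() {
  list(baseline_rate = 0.0090, pre_trend_irr = 1.0124,
       jump_irr = 0.4152, post_trend_irr = 1.0113)
}
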
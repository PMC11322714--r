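#' Poisson log-link regression by iteratively reweighted least squares
#'
#' The workhorse of the modified Poisson approach: a Poisson likelihood with
#' log link applied to binary (or count) outcomes. Frequency `weights` allow
#' person-days sharing identical day-level covariates to be collapsed into
#' weighted rows without changing either the coefficient estimates or the
#' robust variance; an `offset` allows day-aggregated counts with a
#' log-exposure term. IRLS iterates to a relative deviance change below
#' `tol` and the fit stores both the model-based covariance and the HC0
#' sandwich covariance, since the binary outcome violates the Poisson
#' variance assumption by design.
#'
#' @param x design matrix with named columns (full column rank required).
#' @param y non-negative response (binary person-day indicators, or counts
#'   when used with an exposure offset).
#' @param weights optional non-negative frequency weights (replication
#'   counts).
#' @param offset optional log-scale offset.
#' @param tol relative deviance convergence tolerance.
#' @param max_iter iteration cap.
#' @return a `poisson_fit` with `beta`, `cov_model`, `cov_robust` (HC0),
#'   `mu`, `eta`, `converged`, `n_iter`, `deviance`, `loglik`.
#' @export
fit_poisson <- function(x, y, weights = NULL, offset = NULL,
                        tol = 1e-10, max_iter = 100L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) stop("length(y) != nrow(x)")
  if (any(y < 0)) stop("y must be non-negative")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w < 0)) stop("weights must be non-negative")
  off <- if (is.null(offset)) rep(0, n) else as.numeric(offset)
  if (sum(w * y) <= 0) stop("at least one (weighted) event is required")
  if (sum(w > 0) <= p) stop("more parameters than informative observations")
  if (qr(x[w > 0, , drop = FALSE])$rank < p) {
    stop("design matrix is collinear (rank < ", p, ")")
  }

  has_intercept <- any(apply(x, 2L, function(col) all(col == 1)))
  beta <- rep(0, p)
  if (has_intercept) {
    ic <- which(apply(x, 2L, function(col) all(col == 1)))[1L]
    beta[ic] <- log(sum(w * y) / sum(w * exp(off)))
  } else {
    beta[1L] <- log(sum(w * y) / sum(w * exp(off)))
  }

  dev_old <- Inf
  converged <- FALSE
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta) + off
    mu <- exp(eta)
    W <- w * mu
    z <- (eta - off) + (y - mu) / mu
    fit <- stats::lm.wfit(x, z, W)
    beta <- fit$coefficients
    eta <- drop(x %*% beta) + off
    mu <- exp(eta)
    dev <- 2 * sum(w * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu)))
    trace <- c(trace, dev)
    if (is.finite(dev) &&
        abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (!converged) {
    stop("IRLS did not converge in ", max_iter,
         " iterations; deviance trace tail: ",
         paste(signif(utils::tail(trace, 5L), 8), collapse = ", "))
  }
  if (any(mu[w > 0] > 1) && all(y %in% c(0, 1))) {
    warning("fitted event probability exceeds 1 for ",
            sum(mu[w > 0] > 1), " observation(s); the log link does not ",
            "constrain binary fitted values below 1")
  }

  names(beta) <- colnames(x)
  bread <- crossprod(x, x * (w * mu))
  cov_model <- solve(bread)
  dimnames(cov_model) <- list(colnames(x), colnames(x))
  out <- structure(list(beta = beta, cov_model = cov_model,
                        mu = mu, eta = eta, y = y, x = x, weights = w,
                        offset = off, converged = converged, n_iter = it,
                        deviance = dev,
                        loglik = sum(w * (y * eta - mu - lgamma(y + 1))),
                        n = sum(w), n_rows = n),
                   class = "poisson_fit")
  out$cov_robust <- sandwich_cov(out)
  out
}

#' Heteroskedasticity-robust sandwich covariance for a Poisson fit
#'
#' `B^{-1} M B^{-1}` with bread `B = sum_i w_i mu_i x_i x_i'` (the observed
#' information under the log link) and meat
#' `M = sum_i w_i (y_i - mu_i)^2 x_i x_i'` (HC0). `type = "HC1"` applies the
#' `n/(n-p)` small-sample factor; with ~10^5-10^6 person-days the correction
#' is immaterial, so HC0 is the default. `cluster` groups score
#' contributions (e.g. by user) before forming the meat, giving a
#' cluster-robust variance.
#'
#' @param fit a `poisson_fit`.
#' @param type `"HC0"` (default) or `"HC1"`.
#' @param cluster optional vector of cluster ids, one per design row.
#' @return covariance matrix of the coefficients.
#' @export
sandwich_cov <- function(fit, type = c("HC0", "HC1"), cluster = NULL) {
  stopifnot(inherits(fit, "poisson_fit"))
  type <- match.arg(type)
  x <- fit$x
  w <- fit$weights
  r <- fit$y - fit$mu
  bread <- crossprod(x, x * (w * fit$mu))
  binv <- solve(bread)
  if (is.null(cluster)) {
    meat <- crossprod(x, x * (w * r^2))
  } else {
    if (length(cluster) != nrow(x)) stop("cluster must match design rows")
    sc <- rowsum(x * (w * r), group = cluster)
    meat <- crossprod(sc)
  }
  v <- binv %*% meat %*% binv
  if (type == "HC1") {
    n <- fit$n
    v <- v * n / (n - ncol(x))
  }
  v <- (v + t(v)) / 2
  dimnames(v) <- list(colnames(x), colnames(x))
  v
}

#' Wald test and confidence interval for one coefficient
#'
#' Normal-approximation two-sided test using the robust (default) or
#' model-based standard error; the 95% interval is
#' `estimate +/- 1.959964 * SE`, exponentiated to the IRR scale on request
#' (so printed IRR intervals are geometrically symmetric about the point
#' estimate).
#'
#' @param fit a `poisson_fit`.
#' @param coefficient coefficient name.
#' @param null_value null hypothesis value on the log scale.
#' @param robust use the sandwich SE (default) or the model-based SE.
#' @param level confidence level.
#' @param exponentiate report estimate and CI as `exp()` (IRR scale); the
#'   z and p values always refer to the log-scale test.
#' @return one-row data frame: `term`, `estimate`, `se`, `z`, `p`,
#'   `conf_low`, `conf_high`.
#' @export
wald <- function(fit, coefficient, null_value = 0, robust = TRUE,
                 level = 0.95, exponentiate = FALSE) {
  stopifnot(inherits(fit, "poisson_fit"))
  if (!coefficient %in% names(fit$beta)) {
    stop("unknown coefficient: ", coefficient, " (have: ",
         paste(names(fit$beta), collapse = ", "), ")")
  }
  est <- fit$beta[[coefficient]]
  v <- if (robust) fit$cov_robust else fit$cov_model
  se <- sqrt(v[coefficient, coefficient])
  z <- (est - null_value) / se
  zq <- stats::qnorm(1 - (1 - level) / 2)
  lo <- est - zq * se
  hi <- est + zq * se
  if (exponentiate) {
    est <- exp(est); lo <- exp(lo); hi <- exp(hi)
  }
  data.frame(term = coefficient, estimate = est, se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)), conf_low = lo, conf_high = hi,
             stringsAsFactors = FALSE)
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat("Poisson (log link) fit:", x$n, "observations,",
      x$n_iter, "IRLS iterations\n")
  tab <- data.frame(estimate = x$beta,
                    se_model = sqrt(diag(x$cov_model)),
                    se_robust = sqrt(diag(x$cov_robust)))
  print(round(tab, 6))
  invisible(x)
}

#' Serialize a Poisson fit to JSON
#' @param fit a `poisson_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(list(
    beta = as.list(fit$beta),
    cov_model = fit$cov_model,
    cov_robust = fit$cov_robust,
    converged = fit$converged, n_iter = fit$n_iter,
    deviance = fit$deviance, loglik = fit$loglik, n = fit$n
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
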
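# deterministic panel: exactly k events per day among n users, rotating
# through the cohort so no user pattern confounds the day-level rates
rotating_panel <- function(n_users, study_days, cutoff_day, k) {
  y <- matrix(0L, n_users, study_days)
  for (t in seq_len(study_days)) {
    y[((k * (t - 1) + seq_len(k) - 1L) %% n_users) + 1L, t] <- 1L
  }
  ages <- rep(c(22L, 27L, 33L), length.out = n_users)
  users <- data.frame(user_id = sprintf("u%03d", seq_len(n_users)),
                      age_years = ages, age_group = assign_age_group(ages),
                      stringsAsFactors = FALSE)
  rdtime:::new_person_day_panel(y, users, "saving", cutoff_day)
}

test_that("constant rates on both sides give a unit jump IRR exactly", {
  p <- rotating_panel(100L, 40L, 20L, k = 5L)
  f <- fit_rdd(p, 20L)
  expect_equal(f$fit$beta[["lockdown"]], 0, tolerance = 1e-8)
  expect_equal(irr_row <- f$irr[f$irr$term == "jump", "irr"], 1,
               tolerance = 1e-8)
  expect_equal(f$fit$beta[["time_c"]], 0, tolerance = 1e-8)
  expect_equal(exp(f$fit$beta[["intercept"]]), 0.05, tolerance = 1e-8)
})

test_that("noiseless log-linear input is fitted exactly at any bandwidth", {
  # feed the exact rate curve as weighted day rows: the model is then
  # correctly specified and the coefficients must equal the truth,
  # unchanged when the window grows
  cutoff <- 60L
  pars <- list(baseline_rate = 0.008, pre_trend_irr = 1.01,
               jump_irr = 0.55, post_trend_irr = 1.006)
  truth <- c(log(0.008) + cutoff * log(1.01), log(1.01), log(0.55),
             log(1.006) - log(1.01))
  for (h in c(15L, 30L, 55L)) {
    days <- (cutoff - h):(cutoff + h)
    x <- rdtime:::rdd_design(days, cutoff)
    rates <- true_rate(pars, days, cutoff)
    f <- fit_poisson(x, rates, weights = rep(1000, length(days)))
    expect_equal(unname(f$beta), truth, tolerance = 1e-8)
  }
})

test_that("fit_rdd windows, IRR mapping and strata behave as specified", {
  sim <- simulate_panel(sim_config(n_users = 2500L, study_days = 120L,
                                   cutoff_day = 50L, seed = 61L))
  p <- sim$panels$saving
  f <- fit_rdd(p, 30L)
  expect_identical(f$window, c(20L, 80L))
  expect_identical(f$n_persondays, 2500L * 61L)

  irr <- function(term) f$irr[f$irr$term == term, ]
  b <- f$fit$beta
  expect_equal(irr("jump")$irr, exp(b[["lockdown"]]))
  expect_equal(irr("pre_trend")$irr, exp(b[["time_c"]]))
  # post trend = pre trend x exp(interaction), exactly
  expect_equal(irr("post_trend")$irr,
               irr("pre_trend")$irr * exp(b[["time_c_lockdown"]]))
  expect_equal(irr("baseline_day0")$irr,
               exp(b[["intercept"]] - 50 * b[["time_c"]]))
  expect_true(all(f$irr$conf_low < f$irr$irr & f$irr$irr < f$irr$conf_high))

  # stratum fit uses only that group's person-days
  f25 <- fit_rdd(p, 30L, stratum = "<25")
  expect_identical(f25$n_users, sum(p$users$age_group == "<25"))

  # an event-free side within the window is an error
  empty_pre <- rotating_panel(50L, 40L, 20L, k = 2L)
  empty_pre$y[, 1:20] <- 0L
  expect_error(fit_rdd(empty_pre, 15L), "pre side")
})

test_that("cluster and HC1 variance options are valid covariances", {
  sim <- simulate_panel(sim_config(n_users = 800L, study_days = 80L,
                                   cutoff_day = 35L, seed = 62L))
  p <- sim$panels$voucher
  f0 <- fit_rdd(p, 25L)
  f1 <- fit_rdd(p, 25L, variance = "HC1")
  fc <- fit_rdd(p, 25L, variance = "cluster")
  expect_equal(f0$fit$beta, f1$fit$beta)
  expect_equal(f0$fit$beta, fc$fit$beta)
  n <- f0$fit$n
  expect_equal(f1$fit$cov_robust, f0$fit$cov_robust * n / (n - 4),
               tolerance = 1e-10)
  # under independent Bernoulli generation, clustering by user changes
  # little; the matrix must still be symmetric positive semidefinite
  expect_true(all(eigen(fc$fit$cov_robust)$values > -1e-12))
  rat <- diag(fc$fit$cov_robust) / diag(f0$fit$cov_robust)
  expect_true(all(rat > 0.7 & rat < 1.4))
})

test_that("cluster scores computed on the panel match explicit expansion", {
  sim <- simulate_panel(sim_config(n_users = 60L, study_days = 30L,
                                   cutoff_day = 14L, seed = 63L))
  p <- sim$panels$saving
  fc <- fit_rdd(p, 10L, variance = "cluster")
  days <- 4:24
  xd <- rdtime:::rdd_design(days, 14L)
  mu <- exp(drop(xd %*% fc$fit$beta))
  long <- expand_person_days(p, days)
  xl <- xd[match(long$day, days), ]
  sc <- rowsum((long$y - mu[match(long$day, days)]) * xl,
               rep(seq_len(60), times = length(days)))
  bread <- crossprod(xl, xl * mu[match(long$day, days)])
  v <- solve(bread) %*% crossprod(sc) %*% solve(bread)
  expect_equal(unname(fc$fit$cov_robust), unname(v), tolerance = 1e-8)
})

test_that("irr_to_percent_change converts and rounds for display", {
  expect_equal(irr_to_percent_change(0.4152), 58.5)
  expect_equal(irr_to_percent_change(1.0), 0.0)
  expect_equal(irr_to_percent_change(0.25), 75.0)
  expect_equal(irr_to_percent_change(1.25), -25.0)
  expect_error(irr_to_percent_change(0), "positive")
  expect_error(irr_to_percent_change(-1), "positive")
})

test_that("IK bandwidth: invariants, scale equivariance and rate exponent", {
  set.seed(64)
  r <- simulate_rate_series(default_saving_params(), 3416L, 240L, 82L)
  bw <- ik_bandwidth(r, 82L)
  expect_s3_class(bw, "ik_bandwidth")
  expect_true(bw$h_opt >= 2L && bw$h_opt <= min(82L, 158L))
  expect_identical(bw$h_cap, 82L)

  # multiplying all rates by a constant must not move the selector
  bw3 <- ik_bandwidth(3 * r, 82L)
  expect_identical(bw3$h_opt, bw$h_opt)

  # plug-in N^(-1/5) rate: doubling N with identical pilot quantities
  h_n <- rdtime:::ik_plugin(1e-5, 1/240, 1e-12, 1e-12, 240)
  h_2n <- rdtime:::ik_plugin(1e-5, 1/240, 1e-12, 1e-12, 480)
  expect_equal(h_2n / h_n, 2^(-1/5), tolerance = 1e-12)

  # triangular constant is the classical 3.4375 (printed to 4 decimals)
  expect_equal(rdtime:::ik_kernel_constant("triangular"), 3.4375,
               tolerance = 1e-4)

  expect_error(ik_bandwidth(r[1:15], 12L), "at least 10")
  expect_error(ik_bandwidth(rep(0.05, 100), 50L), "manually")
})

test_that("sensitivity scan covers the grid and records failures", {
  sim <- simulate_panel(sim_config(n_users = 2000L, study_days = 160L,
                                   cutoff_day = 82L, seed = 65L))
  p <- sim$panels$payment

  # delta = 0 reduces to a single fit identical to fit_rdd
  s0 <- sensitivity_scan(p, 55L, delta = 0L)
  expect_identical(nrow(s0), 1L)
  f <- fit_rdd(p, 55L)
  expect_equal(s0$irr_jump, f$irr[f$irr$term == "jump", "irr"])

  # payments scanned 35..75 days: jump varies smoothly, no sign flip
  sc <- sensitivity_scan(p, 55L, delta = 20L, step = 5L)
  expect_identical(sc$bandwidth, seq(35L, 75L, 5L))
  expect_true(all(is.na(sc$error)))
  expect_false(attr(sc, "sign_change"))
  expect_true(all(sc$irr_jump > 0.2 & sc$irr_jump < 1.2))
  expect_lt(max(abs(diff(log(sc$irr_jump)))), 0.35)

  # a failing narrow bandwidth is recorded while the scan continues
  sparse <- rotating_panel(60L, 60L, 30L, k = 1L)
  sparse$y[, 26:30] <- 0L  # no pre-side events within +/-5 days
  s2 <- sensitivity_scan(sparse, 10L, delta = 5L, step = 5L)
  expect_true(any(!is.na(s2$error)))
  expect_true(any(is.na(s2$error)))
})

test_that("report table carries the headline columns per fit", {
  sim <- simulate_panel(sim_config(n_users = 1500L, study_days = 120L,
                                   cutoff_day = 50L, seed = 66L))
  fits <- lapply(sim$panels, fit_rdd, bandwidth_days = 35L)
  tab <- report_table(fits)
  expect_identical(nrow(tab), 3L)
  expect_setequal(tab$outcome, c("saving", "payment", "voucher"))
  expect_equal(tab$percent_change, irr_to_percent_change(tab$irr_jump))
  expect_true(all(tab$jump_low < tab$irr_jump & tab$irr_jump < tab$jump_high))
  paths <- withr::local_tempfile(fileext = "")
  write_report(tab, paths)
  expect_true(file.exists(paste0(paths, ".csv")))
  back <- read.csv(paste0(paths, ".csv"))
  expect_equal(back$irr_jump, tab$irr_jump, tolerance = 1e-12)
})
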
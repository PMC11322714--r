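small_config <- function(...) {
  sim_config(n_users = 150L, study_days = 60L, cutoff_day = 25L,
             seed = 101L, ...)
}

test_that("configuration validation catches bad rates, cutoffs and seeds", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(cutoff_day = 240L), "cutoff_day")
  expect_error(sim_config(seed = 1.5), "seed")
  expect_error(sim_config(outcomes = list(saving = list(
    baseline_rate = 1.2, pre_trend_irr = 1, jump_irr = 1,
    post_trend_irr = 1))), "baseline_rate")
  expect_error(sim_config(outcomes = list(saving = list(
    baseline_rate = 0.01, pre_trend_irr = 1, jump_irr = -2,
    post_trend_irr = 1))), "jump_irr")
  expect_error(sim_config(outcomes = list(banana = list(
    baseline_rate = 0.01, pre_trend_irr = 1, jump_irr = 1,
    post_trend_irr = 1))), "unknown outcome")

  # the default block carries the reference generating parameters
  d <- sim_config()
  expect_equal(d$outcomes$saving$jump_irr, 0.4152)
  expect_equal(d$outcomes$payment$baseline_rate, 0.0026)
  expect_equal(d$outcomes$voucher$post_trend_irr, 1.0067)
})

test_that("generator refuses probability curves that reach one", {
  cfg <- sim_config(n_users = 10L, study_days = 100L, cutoff_day = 50L,
                    outcomes = list(saving = list(
                      baseline_rate = 0.5, pre_trend_irr = 1.05,
                      jump_irr = 1, post_trend_irr = 1.05)),
                    seed = 1L)
  expect_error(simulate_panel(cfg), "probability >= 1 .* day 15")
})

test_that("same config and seed give byte-identical panels", {
  a <- simulate_panel(small_config())
  b <- simulate_panel(small_config())
  expect_identical(a$panels$saving$y, b$panels$saving$y)
  expect_identical(a$panels$payment$y, b$panels$payment$y)
  expect_identical(a$users, b$users)
  c_ <- simulate_panel(sim_config(n_users = 150L, study_days = 60L,
                                  cutoff_day = 25L, seed = 102L))
  expect_false(identical(a$panels$saving$y, c_$panels$saving$y))
})

test_that("panel dimensions and service constraints hold", {
  sim <- simulate_panel(small_config())
  for (p in sim$panels) {
    expect_identical(dim(p$y), c(150L, 60L))
    expect_true(all(p$y %in% c(0L, 1L)))
  }
  expect_true(all(rowSums(sim$panels$payment$y) <= 1L))

  # truth holds the exact logs of the configured IRRs
  tr <- sim$truth[sim$truth$outcome == "saving" & sim$truth$age_group == "<25", ]
  expect_equal(tr$log_jump, log(0.4152))
  expect_equal(tr$pre_slope, log(1.0124))
  expect_equal(tr$slope_change, log(1.0113) - log(1.0124))
})

test_that("flat-rate total event count matches the binomial oracle", {
  # n p = 10000 x 100 x 0.005 = 5000 expected events, sd = sqrt(np(1-p))
  cfg <- sim_config(n_users = 10000L, study_days = 100L, cutoff_day = 50L,
                    outcomes = list(saving = list(
                      baseline_rate = 0.005, pre_trend_irr = 1,
                      jump_irr = 1, post_trend_irr = 1)),
                    seed = 2024L)
  total <- sum(simulate_panel(cfg)$panels$saving$y)
  expect_lt(abs(total - 5000), 4 * sqrt(1e6 * 0.005 * 0.995))
})

test_that("no-discontinuity configurations show no break at the cutoff", {
  # jump 1 and equal slopes: aggregate daily means follow a single smooth
  # exponential, so the fitted log-jump over pooled replicates is null
  cfg_base <- list(n_users = 300L, study_days = 60L, cutoff_day = 30L,
                   outcomes = list(saving = list(
                     baseline_rate = 0.02, pre_trend_irr = 1.004,
                     jump_irr = 1, post_trend_irr = 1.004)))
  counts <- 0
  for (r in 1:200) {
    cfg <- do.call(sim_config, c(cfg_base, list(seed = 5000L + r)))
    counts <- counts + colSums(simulate_panel(cfg)$panels$saving$y)
  }
  days <- 0:59
  x <- rdtime:::rdd_design(days, 30L)
  f <- fit_poisson(rbind(x, x), c(rep(1, 60), rep(0, 60)),
                   weights = c(counts, 200 * 300 - counts))
  j <- wald(f, "lockdown")
  expect_lt(abs(j$z), 3)

  # aggregate mean rates track the configured curve
  p_true <- true_rate(cfg_base$outcomes$saving, days, 30L)
  expect_lt(max(abs(counts / (200 * 300) - p_true)), 5 * sqrt(max(p_true) / (200 * 300)))
})

test_that("age draws are calibrated to the target median and IQR", {
  set.seed(31)
  ages <- rdtime:::draw_ages(5000L, 26, 9)
  expect_lt(abs(median(ages) - 26), 1.01)
  expect_lt(abs(IQR(ages, type = 2) - 9), 2.01)
  expect_true(all(ages >= 12 & ages <= 55))
})

test_that("age-group overrides steer group-specific jumps and slopes", {
  cfg <- sim_config(n_users = 2000L, study_days = 80L, cutoff_day = 40L,
                    outcomes = list(saving = list(
                      baseline_rate = 0.05, pre_trend_irr = 1,
                      jump_irr = 0.5, post_trend_irr = 1)),
                    age_overrides = list(">30" = list(jump_irr = 1.0)),
                    seed = 77L)
  sim <- simulate_panel(cfg)
  tr <- sim$truth
  expect_equal(tr$log_jump[tr$age_group == ">30"], 0)
  expect_equal(tr$log_jump[tr$age_group == "<25"], log(0.5))
  p <- sim$panels$saving
  over <- p$users$age_group == ">30"
  pre <- seq_len(40L); post <- 41:80
  drop_non <- mean(p$y[!over, post]) / mean(p$y[!over, pre])
  drop_over <- mean(p$y[over, post]) / mean(p$y[over, pre])
  expect_gt(drop_over, 0.8)
  expect_lt(drop_non, 0.65)
})

test_that("enrollment option zeroes pre-enrollment person-days", {
  cfg <- sim_config(n_users = 200L, study_days = 50L, cutoff_day = 20L,
                    enrollment = TRUE, seed = 9L)
  sim <- simulate_panel(cfg)
  expect_true("enrollment_day" %in% names(sim$users))
  p <- sim$panels$saving
  for (i in which(sim$users$enrollment_day > 0)[1:10]) {
    ed <- sim$users$enrollment_day[i]
    expect_true(all(p$y[i, seq_len(ed)] == 0L))
  }
})

test_that("written transaction logs and registry rebuild the same panels", {
  sim <- simulate_panel(small_config())
  ev_path <- withr::local_tempfile(fileext = ".csv")
  reg_path <- withr::local_tempfile(fileext = ".csv")
  write_transactions(sim$panels, ev_path)
  write_registry(sim$users, reg_path)

  events <- load_events(ev_path, "2020-01-01", "2020-02-29")
  registry <- load_registry(reg_path)
  expect_identical(registry$age_group, sim$users$age_group)
  val <- validate_constraints(events)
  expect_identical(nrow(val$violations), 0L)
  for (oc in names(sim$panels)) {
    rebuilt <- binarize(val$events, registry, 60L, oc, cutoff_day = 25L)
    expect_identical(unname(rebuilt$y), unname(sim$panels[[oc]]$y))
  }
})
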
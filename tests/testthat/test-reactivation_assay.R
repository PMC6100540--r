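test_that("activity slopes are recovered from traces", {
  t <- seq(0, 5, by = 0.25)
  expect_equal(activity_from_trace(t, 0.1 + 0.02 * t), 0.02,
               tolerance = 1e-12)
  expect_equal(activity_from_trace(t, rep(0.3, length(t))), 0)
  expect_error(activity_from_trace(c(0, 1), c(0, 1)), "at least 3")
  expect_error(activity_from_trace(c(0, 1, 1), c(0, 1, 2)),
               "strictly increasing")
  # noisy trace: recovered within 3 standard errors of the true slope
  set.seed(8)
  n <- 30; tt <- seq(0, 5, length.out = n)
  ab <- 0.05 + 0.015 * tt + rnorm(n, 0, 1e-4)
  fit <- lm(ab ~ tt)
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(activity_from_trace(tt, ab) - 0.015), 3 * se)
  # window restriction uses only the requested points
  ab2 <- ifelse(tt <= 2, 0.1 + 0.02 * tt, 0.14 + 0.001 * (tt - 2))
  expect_equal(activity_from_trace(tt, ab2, window = c(0, 2)), 0.02,
               tolerance = 1e-9)
})

test_that("percent reactivation evaluates the formula exactly", {
  expect_equal(percent_reactivation(1.0, 0.05, 1.0), 100)
  expect_equal(percent_reactivation(1.0, 0.05, 0.05), 0)
  expect_equal(percent_reactivation(2.0, 0.1, 1.0),
               (1 - (2 - 1) / (2 - 0.1)) * 100)  # 47.368...
  expect_equal(round(percent_reactivation(2.0, 0.1, 1.0), 3), 47.368)
  expect_error(percent_reactivation(0.5, 0.5, 1.0), "no inhibition")
  # out-of-range values pass through flagged, never clamped
  over <- percent_reactivation(1.0, 0.05, 1.2)
  expect_gt(as.numeric(over), 100)
  expect_true(isTRUE(attr(over, "out_of_range")))
})

test_that("percent reactivation invariances hold", {
  set.seed(12)
  for (i in 1:25) {
    a0 <- runif(1, 0.5, 2); ai <- a0 * runif(1, 0.01, 0.5)
    ar <- runif(1, ai, a0)
    base <- percent_reactivation(a0, ai, ar)
    # strictly increasing in ar; 100 iff ar = a0
    expect_gt(percent_reactivation(a0, ai, ar + 0.01), as.numeric(base))
    expect_equal(as.numeric(percent_reactivation(a0, ai, a0)), 100)
    # common positive rescaling leaves %R unchanged
    s <- runif(1, 0.1, 10)
    expect_equal(as.numeric(percent_reactivation(s * a0, s * ai, s * ar)),
                 as.numeric(base), tolerance = 1e-9)
    # oximolysis correction: (ar + c, oximolysis = c) == (ar, 0)
    cc <- runif(1, 0, 0.5)
    expect_equal(as.numeric(percent_reactivation(a0, ai, ar + cc, cc)),
                 as.numeric(base), tolerance = 1e-9)
  }
})

test_that("replicate summaries use mean and sample SD", {
  s <- summarize_reactivation(c(10, 10, 10))
  expect_equal(s$pct_R_mean, 10)
  expect_equal(s$pct_R_sd, 0)
  s2 <- summarize_reactivation(c(9, 10, 11))
  expect_equal(s2$pct_R_mean, 10)
  expect_equal(s2$pct_R_sd, 1)   # (n-1) denominator
  s3 <- summarize_reactivation(7, oxime = "x")
  expect_equal(s3$pct_R_mean, 7)
  expect_equal(s3$pct_R_sd, 0)
  expect_true(isTRUE(attr(s3, "single_replicate")))
})

test_that("half-life fits and inhibition timing follow first-order kinetics", {
  ic <- generate_inhibition_course(T_half = 10, n_points = 6)
  k <- fit_half_life(ic$times, ic$activities)
  expect_equal(k$half_life, 10, tolerance = 1e-9)
  expect_equal(k$r_squared, 1, tolerance = 1e-9)
  # the 2-hour incubation corresponds to 7 half-lives of 120/7 min
  ic2 <- generate_inhibition_course(T_half = 120 / 7, n_points = 6)
  k2 <- fit_half_life(ic2$times, ic2$activities)
  expect_equal(k2$half_life, 120 / 7, tolerance = 1e-9)
  it <- inhibition_time(k2, 7)
  expect_equal(it$minutes, 120, tolerance = 1e-6)
  expect_equal(it$residual_fraction, 2^-7)
  expect_equal(inhibition_time(k2, 0)$minutes, 0)
  expect_equal(inhibition_time(k2, 0)$residual_fraction, 1)
  expect_equal(inhibition_time(list(half_life = 10), 3)$minutes, 30)
  expect_equal(inhibition_time(list(half_life = 10), 3)$residual_fraction,
               0.125)
  # noisy course recovered within 5%
  icn <- generate_inhibition_course(T_half = 15, n_points = 10,
                                    noise_cv = 0.02, seed = 4)
  kn <- fit_half_life(icn$times, icn$activities)
  expect_lt(abs(kn$half_life - 15) / 15, 0.05)
  expect_error(fit_half_life(c(0, 1, 2), c(1, 0.5, -0.1)), "positive")
  expect_error(fit_half_life(c(0, 1, 2), c(1, 1.5, 2)), "no decay")
})

test_that("activity tables reduce to reactivation rows with oximolysis", {
  act <- data.frame(
    condition = rep(c("intact", "inhibited", "reactivated",
                      "oximolysis_control"), each = 2),
    replicate = rep(1:2, 4),
    activity = c(1.0, 1.0, 0.05, 0.05, 0.62, 0.62, 0.02, 0.02))
  res <- reactivation_from_activities(act, "ox", "AChE", 1e-4)
  truth <- percent_reactivation(1.0, 0.05, 0.62, 0.02)
  expect_equal(res$pct_R_mean, as.numeric(truth))
  expect_equal(res$pct_R_sd, 0)
  expect_equal(res$n_replicates, 2L)
  expect_error(reactivation_from_activities(act[act$condition != "intact", ]),
               "intact")
})
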
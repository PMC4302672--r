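test_that("Kaplan-Meier estimates match hand product-limit values", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  # S = (1 - 1/3) after t=1; censoring at 2; then (2/3)(1 - 1/1) = 0
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)

  # no events -> flat at 1
  km0 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$survival == 1))

  # doubling every observation leaves the curve unchanged
  set.seed(41)
  t1 <- rexp(30); e1 <- rbinom(30, 1, 0.6)
  a <- km_estimate(t1, e1)
  b <- km_estimate(rep(t1, 2), rep(e1, 2))
  expect_equal(a$time, b$time)
  expect_equal(a$survival, b$survival, tolerance = 1e-12)

  # uncensored data: equals the empirical survival function (counting oracle)
  t2 <- sample(1:20, 25, replace = TRUE)
  kmu <- km_estimate(t2, rep(1, 25))
  o <- oracle_km(t2, rep(1, 25))
  expect_equal(kmu$survival, o$survival, tolerance = 1e-12)
  expect_equal(kmu$survival, vapply(o$time, function(x) mean(t2 > x), 0),
               tolerance = 1e-12)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("log-rank statistic matches the hypergeometric O-E oracle", {
  expect_equal(logrank_test(c(1, 2, 3, 1, 2, 3), rep(1, 6),
                            rep(c("a", "b"), each = 3))$statistic, 0)

  set.seed(42)
  for (rep in 1:5) {
    t <- rexp(30, rep(c(0.5, 1.5), each = 15))
    e <- rbinom(30, 1, 0.8)
    g <- rep(c("a", "b"), each = 15)
    if (sum(e) == 0) next
    lr <- logrank_test(t, e, g)
    expect_equal(lr$statistic, oracle_logrank2(t, e, g), tolerance = 1e-9)
    expect_equal(lr$df, 1L)
  }
  # no events anywhere -> statistic 0, p 1
  lr0 <- logrank_test(c(1, 2, 3, 4), c(0, 0, 0, 0), c("a", "a", "b", "b"))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  expect_error(logrank_test(1:4, rep(1, 4), rep("a", 4)), "2 non-empty")
})

test_that("two-group log-rank equals the Cox score test at beta = 0", {
  set.seed(43)
  for (rep in 1:5) {
    x <- rbinom(60, 1, 0.5)
    t <- rexp(60, 0.5 * exp(0.7 * x))
    e <- as.integer(t < quantile(t, 0.85))
    t <- pmin(t, quantile(t, 0.85))
    t <- t + seq_along(t) * 1e-9   # break ties so both routes see the same data
    lr <- logrank_test(t, e, x)
    cf <- cox_fit(data.frame(x = x), t, e)
    expect_equal(lr$statistic, attr(cf, "score_test"), tolerance = 1e-6)
  }
})

test_that("Cox fits recover planted hazards and solve the minimal instance in closed form", {
  # 3-patient instance: events at t=1 (x=0), t=2 (x=1), censored t=3 (x=0)
  # partial likelihood maximum solves u^2 = 2, beta = log(2)/2
  cf <- cox_fit(data.frame(x = c(0, 1, 0)), c(1, 2, 3), c(1, 1, 0))
  expect_equal(cf$coef, log(2) / 2, tolerance = 1e-6)

  # null covariate stays within 2 SE of zero
  set.seed(44)
  x <- rbinom(500, 1, 0.5)
  t <- rexp(500, 0.1)
  e <- as.integer(t < 15); t <- pmin(t, 15)
  cf0 <- cox_fit(data.frame(x = x), t, e)
  expect_lt(abs(cf0$coef), 2 * cf0$se)

  # true HR 2.9, n = 5000, light censoring -> estimate in [2.6, 3.2]
  set.seed(45)
  x <- rbinom(5000, 1, 0.5)
  t <- rexp(5000, 0.05 * exp(log(2.9) * x))
  cens <- runif(5000, 20, 80)
  e <- as.integer(t <= cens); t <- pmin(t, cens)
  cf29 <- cox_fit(data.frame(x = x), t, e)
  expect_gt(cf29$hr, 2.6)
  expect_lt(cf29$hr, 3.2)
  expect_true(attr(cf29, "converged"))
  expect_equal(cf29$hr, exp(cf29$coef))
  expect_true(cf29$hr_lower < cf29$hr && cf29$hr < cf29$hr_upper)

  # separation is flagged, not thrown
  cfs <- cox_fit(data.frame(x = c(1, 0)), c(1, 2), c(1, 0))
  expect_true(attr(cfs, "separation"))
  expect_error(cox_fit(data.frame(x = rep(1, 10)), rexp(10), rbinom(10, 1, 1)),
               "constant")
})

test_that("the univariable screen mirrors per-level event counts and detects planted HPV risk", {
  coh <- simulate_cohort(n = 500, seed = 46)
  scr <- univariable_screen(coh)
  # event counts per level sum to the totals
  expect_equal(sum(scr$progression_events[scr$variable == "fgfr3_mut"]),
               sum(coh$progression_event))
  expect_equal(sum(scr$recurrence_events[scr$variable == "loh9"]),
               sum(coh$recurrence_event))
  # planted progression hazards: HPV (HR 3.8) reaches significance at n=500
  expect_lt(scr$p_progression[scr$variable == "hpv_pos" & scr$level == "1"],
            0.05)
  expect_lt(scr$p_progression[scr$variable == "grade" & scr$level == "3"],
            0.05)
  # constant variable excluded with a warning
  coh$loh13 <- 0L
  expect_warning(scr2 <- univariable_screen(coh), "constant.*loh13")
  expect_false("loh13" %in% scr2$variable)
})

test_that("the multivariable model keeps only univariably significant predictors", {
  coh <- simulate_cohort(n = 800, seed = 47)
  fit <- multivariable_progression(coh)
  expect_s3_class(fit, "cox_fit")
  sel <- attr(fit, "selected")
  expect_true(all(c("grade", "hpv_pos") %in% sel))
  # the planted effects survive adjustment
  expect_gt(fit$hr[fit$covariate == "grade"], 1)
  expect_gt(fit$hr[fit$covariate == "hpv_pos"], 1)
  # nothing passes on a null cohort
  coh0 <- generate_null_cohort(n = 104, seed = 48)
  expect_message(r0 <- multivariable_progression(coh0, alpha = 1e-6),
                 "no variable passes")
  expect_null(r0)
})
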
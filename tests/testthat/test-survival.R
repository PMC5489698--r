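test_that("censoring horizon truncates times and events", {
  d <- data.frame(time = c(12, 8, 10.5), event = c(TRUE, TRUE, FALSE))
  out <- censor_at(d, 10)
  expect_equal(out$time, c(10, 8, 10))
  expect_equal(out$event, c(FALSE, TRUE, FALSE))
  expect_equal(censor_at(d, Inf), d)
  expect_error(censor_at(d, 0), "positive")
})

test_that("Kaplan-Meier matches the hand product-limit and the exp limit", {
  d <- data.frame(time = c(1, 2, 3), event = c(FALSE, TRUE, TRUE))
  km <- km_estimate(d)
  expect_equal(km_surv_at(km, 2), 0.5)   # risk set 2 at t=2
  expect_equal(km_surv_at(km, 3), 0)     # risk set 1 at t=3
  expect_equal(km_surv_at(km, 0), 1)
  expect_true(all(diff(km$surv) <= 0))
  # no events -> S(t) = 1 everywhere
  d0 <- data.frame(time = 1:5, event = rep(FALSE, 5))
  expect_true(all(km_estimate(d0)$surv == 1))
  # large-sample agreement with the exponential survival function
  set.seed(37)
  de <- data.frame(time = rexp(10000, 0.2), event = TRUE)
  kme <- km_estimate(de)
  for (t in c(1, 3, 5)) {
    expect_lt(abs(km_surv_at(kme, t) - exp(-0.2 * t)), 0.015)
  }
})

test_that("log-rank test is null-calibrated and powered", {
  d <- sim_exp_survival(100, beta = 0, seed = 38)
  dup <- rbind(d, d)
  g <- rep(c("a", "b"), each = 100)
  res <- logrank_test(dup, g)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$p, 1)
  # hazard ratio 3: essentially always significant at n = 200/arm
  set.seed(39)
  ps <- replicate(100, {
    x <- rep(0:1, each = 200)
    t <- rexp(400, 0.2 * 3^x)
    logrank_test(data.frame(time = t, event = TRUE), x)$p
  })
  expect_gte(mean(ps < 0.001), 0.99)
  # null p-values uniform
  set.seed(40)
  ps0 <- replicate(500, {
    x <- rep(0:1, each = 30)
    t <- rexp(60, 0.2)
    logrank_test(data.frame(time = t, event = TRUE), x)$p
  })
  expect_gt(stats::ks.test(ps0, "punif")$p.value, 0.01)
  expect_error(logrank_test(d, rep("a", 100)), "2 groups")
})

test_that("interval hazard ratio recovers the true ratio and inverts", {
  set.seed(41)
  d <- sim_exp_survival(2000, beta = log(2), base_rate = 0.15)
  hr <- interval_hazard_ratio(d, d$x, interval = c(0, 5))
  expect_equal(hr$hr, 2, tolerance = 0.075)
  expect_true(hr$ci_lower < hr$hr && hr$hr < hr$ci_upper)
  swapped <- interval_hazard_ratio(d, 1 - d$x, interval = c(0, 5))
  expect_equal(swapped$hr, 1 / hr$hr, tolerance = 1e-8)
  # identical groups: HR near 1, CI covers 1
  d2 <- rbind(d[1:500, ], d[1:500, ])
  hr2 <- interval_hazard_ratio(d2, rep(0:1, each = 500))
  expect_equal(hr2$hr, 1, tolerance = 1e-6)
  expect_true(hr2$ci_lower <= 1 && 1 <= hr2$ci_upper)
})

test_that("Cox fit recovers coefficients and matches a grid-search oracle", {
  set.seed(42)
  d <- sim_exp_survival(2000, beta = log(2), base_rate = 0.15)
  fit <- cox_fit(d, "x")
  expect_equal(fit$table$coef, log(2), tolerance = 0.09)
  expect_equal(fit$table$hr, exp(fit$table$coef))
  expect_equal(fit$table$ci_lower,
               exp(fit$table$coef - 1.96 * fit$table$se))
  # null covariate: coefficient near 0
  d0 <- sim_exp_survival(2000, beta = 0, seed = 43)
  expect_lt(abs(cox_fit(d0, "x")$table$coef), 0.1)

  # exhaustive partial-likelihood grid oracle, n = 8, binary x, no ties
  small <- data.frame(time = c(1.1, 2.3, 3.1, 4.7, 5.2, 6.9, 7.4, 8.8),
                      event = c(T, T, F, T, T, F, T, T),
                      x = c(1, 0, 1, 1, 0, 0, 1, 0))
  log_pl <- function(beta) {
    ord <- order(small$time)
    s <- small[ord, ]
    ll <- 0
    for (i in which(s$event)) {
      risk <- i:nrow(s)
      ll <- ll + beta * s$x[i] - log(sum(exp(beta * s$x[risk])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-5)
  beta_grid <- grid[which.max(vapply(grid, log_pl, numeric(1)))]
  expect_equal(cox_fit(small, "x")$table$coef, beta_grid, tolerance = 1e-4)

  # duplicating subjects: coefficient unchanged, SE shrinks by sqrt(2)
  d_small <- sim_exp_survival(200, beta = log(2), seed = 44)
  f1 <- cox_fit(d_small, "x", ties = "breslow")
  f2 <- cox_fit(rbind(d_small, d_small), "x", ties = "breslow")
  expect_equal(f2$table$coef, f1$table$coef, tolerance = 1e-6)
  expect_equal(f2$table$se, f1$table$se / sqrt(2), tolerance = 1e-3)

  # complete separation raises a diagnostic error
  sep <- data.frame(time = c(1, 2, 3, 4, 10, 11, 12, 13),
                    event = rep(TRUE, 8), x = c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_error(cox_fit(sep, "x"), "separation")
})

test_that("Schoenfeld test is calibrated under PH and detects violations", {
  set.seed(45)
  rej <- mean(replicate(400, {
    d <- sim_exp_survival(150, beta = 0.7)
    p <- schoenfeld_ph_test(cox_fit(d, "x"))$p[1]
    p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
  # effect reversing sign over time: strong violation
  set.seed(46)
  sim_tv <- function(n = 300) {
    x <- rbinom(n, 1, 0.5)
    h1 <- 0.5 * exp(1.5 * x)   # hazard before t = 1
    h2 <- 0.5 * exp(-1.5 * x)  # hazard after
    t1 <- rexp(n, h1)
    t <- ifelse(t1 < 1, t1, 1 + rexp(n, h2))
    data.frame(time = t, event = TRUE, x = x)
  }
  hits <- mean(replicate(50, {
    schoenfeld_ph_test(cox_fit(sim_tv(), "x"))$p[1] < 0.01
  }))
  expect_gte(hits, 0.9)
  expect_error(schoenfeld_ph_test(
    structure(list(events = 1), class = "cox_fit")), "3 events")
})

test_that("time-dependent AUC matches ranking logic and censoring oracle", {
  # perfect marker: negative survival time ranks all cases above controls
  set.seed(47)
  d <- data.frame(time = rexp(400, 0.3), event = TRUE)
  expect_equal(time_dependent_auc(-d$time, d, t = 2), 1)
  # uninformative marker
  expect_equal(time_dependent_auc(rnorm(400), d, t = 2), 0.5,
               tolerance = 0.08)
  # monotone-transform invariance
  m <- rnorm(400)
  a1 <- time_dependent_auc(m, d, t = 2)
  expect_equal(time_dependent_auc(exp(3 * m), d, t = 2), a1)
  # against the uncensored empirical AUC under 20% censoring
  set.seed(48)
  n <- 2000
  z <- rnorm(n)
  t_full <- rexp(n, 0.12 * exp(0.8 * z))
  full <- data.frame(time = t_full, event = TRUE)
  auc_true <- time_dependent_auc(z, full, t = 5)  # no censoring: empirical
  cens <- runif(n, 0, 40)
  obs <- data.frame(time = pmin(t_full, cens), event = t_full <= cens)
  expect_gt(mean(!obs$event), 0.1)  # materially censored
  expect_equal(time_dependent_auc(z, obs, t = 5), auc_true,
               tolerance = 0.035)
  expect_error(time_dependent_auc(rep(1, 5),
                                  data.frame(time = rep(1, 5),
                                             event = rep(FALSE, 5))),
               "cases")
})

test_that("forward selection finds the prognostic covariate first", {
  set.seed(49)
  n <- 250
  d <- data.frame(x_true = rnorm(n), x_n1 = rnorm(n), x_n2 = rnorm(n),
                  x_n3 = rnorm(n))
  t_ev <- rexp(n, 0.15 * exp(1 * d$x_true))
  d$time <- pmin(t_ev, 10)
  d$event <- t_ev <= 10
  sel <- cv_forward_select(d, c("x_true", "x_n1", "x_n2", "x_n3"),
                           rounds = 3, folds = 5, seed = 50)
  expect_equal(sel$selected[1], "x_true")
  expect_true(all(sel$trajectory$mean_auc >= 0 &
                    sel$trajectory$mean_auc <= 1))
  # determinism
  sel2 <- cv_forward_select(d, c("x_true", "x_n1", "x_n2", "x_n3"),
                            rounds = 3, folds = 5, seed = 50)
  expect_identical(sel$selected, sel2$selected)
  expect_identical(sel$trajectory, sel2$trajectory)
  # pure noise: nothing selected at the default gain threshold
  d_noise <- d
  t0 <- rexp(n, 0.15)
  d_noise$time <- pmin(t0, 10)
  d_noise$event <- t0 <= 10
  sel0 <- cv_forward_select(d_noise, c("x_n1", "x_n2", "x_n3"),
                            rounds = 3, folds = 5, seed = 51)
  expect_length(sel0$selected, 0)
})
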
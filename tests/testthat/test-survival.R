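test_that("PFS derivation applies the trial censoring conventions", {
  # documented progression is an event on that day
  d <- derive_pfs(scans(c(56, 90), c("SD", "PD")), death_day = NA,
                  last_contact_day = 120, visit_interval_days = 56)
  expect_equal(d$time, 90 / 30.4375)
  expect_identical(d$event, 1L)
  expect_identical(d$censor_reason, "progression")
  # death before the first assessment counts as progression
  d <- derive_pfs(scans(numeric(0), character(0)), death_day = 40,
                  last_contact_day = 40, visit_interval_days = 56)
  expect_equal(d$time, 40 / 30.4375)
  expect_identical(d$event, 1L)
  # death after more than one missed visit censors at last nonprogression
  d <- derive_pfs(scans(60, "SD"), death_day = 200, last_contact_day = 200,
                  visit_interval_days = 56)
  expect_equal(d$time, 60 / 30.4375)
  expect_identical(d$event, 0L)
  expect_identical(d$censor_reason, "death_after_missed_visits")
  # death within the visit window is an event
  d <- derive_pfs(scans(60, "SD"), death_day = 150, last_contact_day = 150,
                  visit_interval_days = 56)
  expect_identical(d$event, 1L)
  expect_equal(d$time, 150 / 30.4375)
  # discontinuation without documented progression censors at last clean scan
  d <- derive_pfs(scans(c(56, 112), c("SD", "SD")), death_day = NA,
                  last_contact_day = 130, discontinued_without_pd = TRUE,
                  visit_interval_days = 56)
  expect_identical(d$event, 0L)
  expect_equal(d$time, 112 / 30.4375)
  expect_identical(d$censor_reason, "discontinued_without_documented_pd")
  # derivation is idempotent: same inputs, same datum
  expect_identical(
    derive_pfs(scans(60, "SD"), NA, 100, FALSE, 56),
    derive_pfs(scans(60, "SD"), NA, 100, FALSE, 56))
  expect_error(derive_pfs(scans(60, "SD"), death_day = -1,
                          last_contact_day = 10, visit_interval_days = 56),
               "data error")
  expect_error(derive_pfs(scans(60, "SD"), death_day = NA,
                          last_contact_day = 10, visit_interval_days = 56),
               "data error")
})

test_that("OS derivation events at death and censors at last contact", {
  d <- derive_os(death_day = 180, last_contact_day = 180)
  expect_equal(d$time, 5.91, tolerance = 1e-3)
  expect_identical(d$event, 1L)
  d <- derive_os(death_day = NA, last_contact_day = 365)
  expect_equal(d$time, 11.99, tolerance = 1e-3)
  expect_identical(d$event, 0L)
  d <- derive_os(death_day = 0, last_contact_day = 0)
  expect_identical(d$time, 0)
  expect_identical(d$event, 1L)
})

test_that("Kaplan-Meier estimate matches the hand product-limit table", {
  # events at 1 and 2, censored at 1.5, one later censoring: S(1)=0.75,
  # S(2)=0.375 by hand
  dat <- data.frame(time = c(1, 1.5, 2, 3), event = c(1, 0, 1, 0))
  km <- km_estimate(dat)
  expect_equal(km$table$surv[km$table$time == 1], 0.75)
  expect_equal(km$table$surv[km$table$time == 2], 0.375)
  # events at 1..4, no censoring: S steps through the empirical survivor
  dat <- data.frame(time = 1:4, event = 1)
  km <- km_estimate(dat)
  expect_equal(km$table$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)  # earliest time with S <= 0.5
  # single patient
  km1 <- km_estimate(data.frame(time = 7, event = 1))
  expect_equal(km1$median, 7)
  # all censored: no median, no error
  kmc <- km_estimate(data.frame(time = c(1, 2), event = 0))
  expect_true(is.na(kmc$median))
  expect_error(km_estimate(data.frame(time = numeric(0), event = integer(0))),
               "domain")
})

test_that("without censoring the KM curve equals the empirical survivor function", {
  set.seed(808)
  t <- round(rexp(400, 1 / 3), 2)
  km <- km_estimate(data.frame(time = t, event = 1))
  for (i in seq_len(nrow(km$table))) {
    expect_equal(km$table$surv[i], mean(t > km$table$time[i]),
                 tolerance = 1e-12)
  }
})

test_that("KM median recovers the generating exponential median", {
  set.seed(515)
  med <- 3.4
  t <- rexp(2000, log(2) / med)
  km <- km_estimate(data.frame(time = t, event = 1))
  expect_lt(abs(km$median - med), 0.15)
  # with 30% independent censoring the bias stays small
  cens <- rexp(2000, 0.43 * log(2) / med)  # ~30% censored
  obs <- pmin(t, cens)
  ev <- as.integer(t <= cens)
  kmc <- km_estimate(data.frame(time = obs, event = ev))
  expect_lt(abs(kmc$median - med), 0.2)
  # landmark at the true median is close to one half
  lm <- landmark_table(km, med)
  expect_lt(abs(lm$surv - 0.5), 3 * sqrt(0.25 / 2000) + 0.02)
})

test_that("landmark estimates handle boundaries and follow-up limits", {
  km <- km_estimate(data.frame(time = c(1, 2, 3), event = c(1, 1, 0)))
  lm <- landmark_table(km, c(0, 2.5, 10))
  expect_identical(lm$surv[1], 1)
  expect_false(lm$estimable[3])
  expect_true(is.na(lm$surv[3]))
  expect_error(landmark_table(km, -1), "domain")
})

test_that("univariate Cox estimates match the grid-search oracle on small fixtures", {
  fixtures <- list(
    list(time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 1, 1, 1, 1),
         group = c(1, 1, 0, 1, 0, 0)),
    list(time = c(2, 4, 4, 6, 8, 10, 12, 14), event = c(1, 1, 1, 0, 1, 1, 0, 1),
         group = c(1, 0, 1, 1, 0, 1, 0, 0)),
    list(time = c(1, 1, 2, 3, 5, 8, 13, 21, 34, 55, 60, 70),
         event = c(1, 1, 1, 0, 1, 1, 1, 0, 1, 1, 0, 1),
         group = c(1, 1, 0, 1, 1, 0, 0, 1, 0, 1, 0, 0)))
  for (f in fixtures) {
    fit <- cox_univariate(data.frame(time = f$time, event = f$event), f$group)
    oracle <- cox_grid_oracle(f$time, f$event, f$group)
    expect_true(fit$converged)
    expect_lt(abs(fit$coef - oracle), 2e-4)
  }
  # mutant group with uniformly earlier events: hazard ratio above one
  f <- fixtures[[1]]
  fit <- cox_univariate(data.frame(time = f$time, event = f$event), f$group)
  expect_gt(fit$hr, 1)
})

test_that("Cox screen respects symmetry, rescaling and degenerate inputs", {
  # identical survival in both groups: HR = 1
  dat <- data.frame(time = c(1, 2, 3, 1, 2, 3), event = 1)
  g <- c(0, 0, 0, 1, 1, 1)
  fit <- cox_univariate(dat, g)
  expect_equal(fit$hr, 1, tolerance = 1e-6)
  # HR invariant under time rescaling
  fit10 <- cox_univariate(transform(dat, time = time * 10), g)
  expect_equal(fit$coef, fit10$coef, tolerance = 1e-8)
  # Wald CI excludes 1 exactly when p < 0.05
  set.seed(77)
  big <- data.frame(time = c(rexp(40, 2), rexp(40, 1)), event = 1)
  fitb <- cox_univariate(big, rep(c(1, 0), each = 40))
  expect_identical(fitb$ci_low > 1 || fitb$ci_high < 1, fitb$p_value < 0.05)
  # monotone likelihood flagged as nonconvergent
  mono <- cox_univariate(data.frame(time = c(1, 5), event = c(1, 1)), c(1, 0))
  expect_false(mono$converged)
  expect_error(cox_univariate(dat, rep(1, 6)), "estimability")
  expect_error(cox_univariate(data.frame(time = 1:4, event = 0),
                              c(0, 1, 0, 1)), "estimability")
})

test_that("trial-table survival derivation carries reasons for every censoring", {
  cfg <- synthetic_trial_config(seed = 21, n_screened = 120)
  tr <- simulate_trial(cfg)
  surv <- derive_survival_table(tr$patients, tr$assessments)
  expect_identical(nrow(surv), 2L * nrow(tr$patients))
  expect_true(all(surv$event %in% c(0L, 1L)))
  expect_true(all(surv$time >= 0))
  expect_true(all(nzchar(surv$censor_reason)))
  # derivation is deterministic/idempotent
  expect_identical(surv, derive_survival_table(tr$patients, tr$assessments))
})
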
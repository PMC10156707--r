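test_that("design constructor validates its parameters", {
  expect_s3_class(ppd_design(), "ppd_design")
  expect_error(ppd_design(p0 = 1), "p0")
  expect_error(ppd_design(p0 = -0.1), "p0")
  expect_error(ppd_design(prior_a = 0), "prior")
  expect_error(ppd_design(theta_L = 0.9, theta_U = 0.1), "theta")
  expect_error(ppd_design(theta_T = 0), "theta_T")
  expect_error(ppd_design(n_max = 5, monitor_start = 6), "monitor_start")
})

test_that("posterior exceedance matches the quadrature oracle and its limits", {
  des <- ppd_design()
  # degenerate reference rates
  expect_equal(posterior_exceedance(5, 10, ppd_design(p0 = 0)), 1)
  expect_equal(posterior_exceedance(5, 10, ppd_design(p0 = 1 - 1e-12)), 0,
               tolerance = 1e-9)
  # adaptive-quadrature oracle at the documented example
  expect_equal(posterior_exceedance(2, 10, des),
               exceedance_quadrature(2, 10, des), tolerance = 1e-8)
  # a spread of states
  for (n in c(5, 17, 40)) {
    for (x in c(0, 1, floor(n / 2), n)) {
      expect_equal(posterior_exceedance(x, n, des),
                   exceedance_quadrature(x, n, des), tolerance = 1e-8)
    }
  }
  # strictly increasing in x at fixed n
  vals <- posterior_exceedance(0:10, 10, des)
  expect_true(all(diff(vals) > 0))
  expect_error(posterior_exceedance(5, 3, des), "domain")
  expect_error(posterior_exceedance(-1, 3, des), "domain")
})

test_that("beta-binomial predictive pmf normalizes and matches Monte Carlo", {
  des <- ppd_design()
  expect_equal(beta_binomial_predictive(2, 5, 0, des),
               c(`0` = 1), tolerance = 1e-12)
  for (case in list(c(0, 3, 7), c(4, 9, 12), c(10, 10, 30))) {
    pmf <- beta_binomial_predictive(case[1], case[2], case[3], des)
    expect_length(pmf, case[3] + 1L)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    expect_true(all(pmf >= 0))
  }
  # MC oracle: draw p from posterior, then binomial future responses
  set.seed(424242)
  ndraw <- 1e6
  p <- rbeta(ndraw, 0.05 + 1, 0.05 + 3)
  y <- rbinom(ndraw, 2, p)
  mc <- tabulate(y + 1L, nbins = 3L) / ndraw
  pmf <- beta_binomial_predictive(1, 4, 2, des)
  se <- sqrt(mc * (1 - mc) / ndraw)
  expect_true(all(abs(pmf - mc) < 3 * se))
  expect_error(beta_binomial_predictive(1, 4, -1, des), "domain")
})

test_that("final success cutoff agrees with the quadrature scan oracle", {
  des <- ppd_design()
  expect_identical(final_success_cutoff(10, ppd_design(theta_T = 1e-12)), 0L)
  for (n in c(10, 15, 20, 25)) {
    expect_identical(final_success_cutoff(n, des), final_cutoff_scan(n, des))
  }
  # an unattainable threshold: p0 just under 1 with a demanding theta_T
  hard <- ppd_design(p0 = 1 - 1e-9, theta_T = 0.999)
  expect_true(is.na(final_success_cutoff(3, hard)))
})

test_that("predictive probability matches exhaustive enumeration", {
  des10 <- ppd_design(n_max = 10)
  expect_equal(predictive_probability(1, 5, des10),
               pp_enumeration(1, 5, des10), tolerance = 1e-10)
  # full grid at a moderate horizon
  des <- ppd_design(n_max = 14)
  for (n in c(1, 6, 11, 14)) {
    for (x in 0:n) {
      expect_equal(predictive_probability(x, n, des),
                   pp_enumeration(x, n, des), tolerance = 1e-10)
    }
  }
  expect_error(predictive_probability(1, 15, des), "domain")
})

test_that("predictive probability is nondecreasing in x and collapses to the final rule", {
  des <- ppd_design(n_max = 20)
  for (n in c(1, 5, 10, 19, 20)) {
    pp <- vapply(0:n, predictive_probability, numeric(1), n = n, design = des)
    expect_true(all(diff(pp) >= -1e-12))
  }
  # at n = n_max PP is exactly the 0/1 final verdict
  cut <- final_success_cutoff(20, des)
  pp_final <- vapply(0:20, predictive_probability, numeric(1), n = 20,
                     design = des)
  expect_identical(pp_final, as.numeric(0:20 >= cut))
  # unreachable success short-circuits to zero
  expect_identical(predictive_probability(0, 18, des), 0)
})

test_that("interim decisions follow strict thresholds", {
  des <- ppd_design(n_max = 20)
  # all-responder arm crosses the efficacy boundary
  dec <- interim_decision(5, 5, des)
  expect_identical(as.character(dec), "stop_efficacy")
  expect_gt(attr(dec, "pp"), des$theta_U)
  expect_equal(attr(dec, "pp"), pp_enumeration(5, 5, des), tolerance = 1e-10)
  # zero responders deep into accrual is futile
  dec <- interim_decision(0, 15, des)
  expect_identical(as.character(dec), "stop_futility")
  expect_lt(attr(dec, "pp"), des$theta_L)
  expect_equal(attr(dec, "pp"), pp_enumeration(0, 15, des), tolerance = 1e-10)
  # unreachable strict bounds always continue
  open <- ppd_design(theta_L = 0, theta_U = 1, n_max = 12)
  for (n in c(1, 5, 11)) {
    for (x in c(0, n)) {
      expect_identical(as.character(interim_decision(x, n, open)), "continue")
    }
  }
  expect_error(interim_decision(3, 20, des), "final")
})

test_that("stopping boundaries equal the brute-force table and are monotone", {
  des <- ppd_design(n_max = 20)
  tab <- stopping_boundaries(des)
  brute <- boundaries_brute_force(des)
  interim <- as.data.frame(tab)[!tab$final,
                                c("n", "futility_cutoff", "efficacy_cutoff")]
  rownames(interim) <- rownames(brute) <- NULL
  expect_identical(interim, brute)
  # cutoffs nondecreasing in n; futility strictly below efficacy when both exist
  expect_true(all(diff(tab$futility_cutoff[!is.na(tab$futility_cutoff)]) >= 0))
  expect_true(all(diff(tab$efficacy_cutoff[!is.na(tab$efficacy_cutoff)]) >= 0))
  both <- !is.na(tab$futility_cutoff) & !is.na(tab$efficacy_cutoff)
  expect_true(all(tab$futility_cutoff[both] < tab$efficacy_cutoff[both]))
  # the table reproduces interim_decision on the full (x, n) grid
  for (i in which(!tab$final)) {
    n <- tab$n[i]
    for (x in 0:n) {
      dec <- as.character(interim_decision(x, n, des))
      fut <- tab$futility_cutoff[i]; eff <- tab$efficacy_cutoff[i]
      want <- if (!is.na(fut) && x <= fut) "stop_futility"
              else if (!is.na(eff) && x >= eff) "stop_efficacy" else "continue"
      expect_identical(dec, want)
    }
  }
  # disabled futility threshold yields no futility cutoffs
  open <- stopping_boundaries(ppd_design(theta_L = 0, n_max = 10))
  expect_true(all(is.na(open$futility_cutoff[!open$final])))
})

test_that("dropout inflation rounds enrollment up", {
  expect_identical(inflate_for_dropout(41, 0.10), 46L)
  expect_identical(inflate_for_dropout(10, 0.10), 12L)
  expect_identical(inflate_for_dropout(37, 0), 37L)
  expect_error(inflate_for_dropout(10, 1), "domain")
  expect_error(inflate_for_dropout(10, -0.1), "domain")
})

test_that("arm expansion updates the horizon, audits, and guards state", {
  st <- arm_state("C", n_enrolled = 15, n_responders = 3, n_max_current = 20)
  st2 <- expand_arm(st, 41)
  expect_identical(st2$n_max_current, 41L)
  expect_length(attr(st2, "audit"), 1L)
  expect_identical(attr(st2, "audit")[[1]]$from, 20L)
  # PP is recomputed against the new horizon and generally changes
  des <- ppd_design(n_max = 20)
  pp_old <- predictive_probability(3, 15, des, n_max = st$n_max_current)
  pp_new <- predictive_probability(3, 15, des, n_max = st2$n_max_current)
  expect_false(isTRUE(all.equal(pp_old, pp_new)))
  # equality only when no future patients remain under either horizon
  full <- arm_state("Z", n_enrolled = 20, n_responders = 7, n_max_current = 20)
  expect_equal(predictive_probability(7, 20, des, n_max = 20),
               predictive_probability(7, 20, des, n_max = full$n_max_current))
  expect_error(expand_arm(st, 10), "domain")
  closed <- arm_state("A", 4, 3, status = "closed_administratively",
                      n_max_current = 10)
  expect_error(expand_arm(closed, 20), "state")
  expect_error(arm_state("B", n_enrolled = 46, n_responders = 2,
                         n_max_current = 40), "domain")
})
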
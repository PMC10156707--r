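# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: direct beta-function ratios instead of
# log-scale arithmetic, quadrature instead of pbeta tails, grid search
# instead of Newton-Raphson.

# P(p > p0 | x, n) by adaptive quadrature over the posterior density
exceedance_quadrature <- function(x, n, design) {
  a <- design$prior_a + x
  b <- design$prior_b + n - x
  # integrate away from the singular endpoint when a shape is below 1
  if (b < 1) {
    1 - stats::integrate(function(p) stats::dbeta(p, a, b), 0, design$p0,
                         rel.tol = 1e-12)$value
  } else {
    stats::integrate(function(p) stats::dbeta(p, a, b), design$p0, 1,
                     rel.tol = 1e-12)$value
  }
}

# final success cutoff by scanning x against the quadrature oracle
final_cutoff_scan <- function(n_final, design) {
  for (x in 0:n_final)
    if (exceedance_quadrature(x, n_final, design) > design$theta_T) return(x)
  NA_integer_
}

# predictive probability by exhaustive enumeration with direct beta ratios
pp_enumeration <- function(x, n, design, n_max = design$n_max) {
  cut <- final_cutoff_scan(n_max, design)
  if (is.na(cut)) return(0)
  m <- n_max - n
  a <- design$prior_a + x
  b <- design$prior_b + n - x
  total <- 0
  for (y in 0:m) {
    if (x + y >= cut)
      total <- total + choose(m, y) * beta(a + y, b + m - y) / beta(a, b)
  }
  total
}

# boundary table by brute-force evaluation of the enumeration oracle
boundaries_brute_force <- function(design, n_max = design$n_max) {
  looks <- monitor_looks(design, n_max)
  rows <- lapply(looks, function(n) {
    pp <- vapply(0:n, pp_enumeration, numeric(1L), n = n, design = design,
                 n_max = n_max)
    fut <- which(pp < design$theta_L)
    eff <- which(pp > design$theta_U)
    data.frame(n = n,
               futility_cutoff = if (length(fut)) max(fut) - 1L else NA_integer_,
               efficacy_cutoff = if (length(eff)) min(eff) - 1L else NA_integer_)
  })
  do.call(rbind, rows)
}

# Breslow partial log-likelihood maximized by grid search over log-HR
cox_grid_oracle <- function(time, event, group, grid = seq(-5, 5, by = 1e-4)) {
  z <- as.numeric(group)
  event_times <- sort(unique(time[event == 1]))
  loglik <- numeric(length(grid))
  for (t0 in event_times) {
    d <- which(time == t0 & event == 1)
    risk <- which(time >= t0)
    # Breslow: sum over tied events of beta*z_i - log(sum exp(beta*z_risk))
    s1 <- sum(z[d])
    n1 <- sum(z[risk] == 1)
    n0 <- sum(z[risk] == 0)
    loglik <- loglik + grid * s1 - length(d) * log(n0 + n1 * exp(grid))
  }
  grid[which.max(loglik)]
}

# small deterministic assessment-table builder
scans <- function(days, statuses, patient_id = "P1") {
  data.frame(patient_id = rep_len(patient_id, length(days)), day = days,
             status = statuses, stringsAsFactors = FALSE)
}

default_design <- function(...) ppd_design(...)
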
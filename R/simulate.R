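#' Configuration for the synthetic umbrella-trial generator
#'
#' Defines the statistical structure of a simulated multi-arm umbrella
#' trial: seven biomarker-defined arms with unequal prevalence, per-arm true
#' response probabilities, exponential latent progression and death times,
#' tumor assessments scheduled every two treatment cycles, and early dropout
#' before the first scan. Defaults emulate a heavily pretreated metastatic
#' TNBC umbrella cohort: arm prevalences proportional to observed sizes
#' 4/20/46/10/46/6/9, per-arm response rates and survival medians at the
#' observed arm-level point estimates, 21- or 28-day cycles, and a 10%
#' dropout rate concentrated before the first postbaseline scan.
#'
#' @param seed integer RNG seed.
#' @param n_screened number of screened patients.
#' @param screen_fail_rate probability a screened patient is not enrolled
#'   (independent thinning).
#' @param arm_names arm labels.
#' @param arm_prevalences multinomial probabilities over arms (normalized).
#' @param true_orr per-arm true probability of a confirmed objective
#'   response.
#' @param median_pfs_months,median_os_months per-arm latent exponential
#'   medians; OS must be at least PFS (OS is generated as PFS plus an
#'   exponential post-progression increment).
#' @param cycle_days per-arm treatment cycle length (21 or 28); imaging is
#'   every two cycles.
#' @param dropout_rate probability of dropout before the first scan.
#' @param accrual_rate expected enrollment rate, patients per month.
#' @param max_followup_months administrative data cutoff per patient.
#' @param covariate_prev named vector of binary mutation-covariate
#'   prevalences.
#' @param covariate_hr_pfs named vector of per-covariate hazard ratios
#'   multiplying the latent progression hazard (1 = no effect).
#' @return Object of class `synthetic_trial_config`.
#' @export
synthetic_trial_config <- function(
    seed = 1L,
    n_screened = 151L,
    screen_fail_rate = 10 / 151,
    arm_names = LETTERS[1:7],
    arm_prevalences = c(4, 20, 46, 10, 46, 6, 9),
    true_orr = c(3 / 4, 0, 20 / 46, 2 / 10, 13 / 46, 1 / 6, 3 / 9),
    median_pfs_months = c(3.4, 1.9, 4.6, 2.0, 3.4, 1.2, 3.0),
    median_os_months = c(16.7, 6.1, 16.1, 6.2, 10.1, 2.7, 4.5),
    cycle_days = c(21, 28, 28, 28, 28, 21, 28),
    dropout_rate = 0.10,
    accrual_rate = 3.5,
    max_followup_months = 24,
    covariate_prev = c(mutA = 0.30, mutB = 0.15),
    covariate_hr_pfs = c(mutA = 1, mutB = 1)) {
  k <- length(arm_names)
  stopifnot(length(arm_prevalences) == k, length(true_orr) == k,
            length(median_pfs_months) == k, length(median_os_months) == k,
            length(cycle_days) == k)
  if (all(arm_prevalences <= 0))
    stop("config error: at least one arm must have positive prevalence", call. = FALSE)
  if (any(arm_prevalences < 0)) stop("config error: negative prevalence", call. = FALSE)
  if (any(true_orr < 0 | true_orr > 1))
    stop("config error: 'true_orr' entries must lie in [0, 1]", call. = FALSE)
  if (any(median_pfs_months <= 0) || any(median_os_months <= 0))
    stop("config error: survival medians must be positive", call. = FALSE)
  if (any(median_os_months < median_pfs_months))
    stop("config error: median OS below median PFS", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("config error: 'dropout_rate' must lie in [0, 1)", call. = FALSE)
  stopifnot(length(covariate_prev) == length(covariate_hr_pfs),
            identical(names(covariate_prev), names(covariate_hr_pfs)))
  structure(list(
    seed = as.integer(seed), n_screened = as.integer(n_screened),
    screen_fail_rate = screen_fail_rate, arm_names = arm_names,
    arm_prevalences = arm_prevalences / sum(arm_prevalences),
    true_orr = stats::setNames(true_orr, arm_names),
    median_pfs_months = stats::setNames(median_pfs_months, arm_names),
    median_os_months = stats::setNames(median_os_months, arm_names),
    cycle_days = stats::setNames(cycle_days, arm_names),
    dropout_rate = dropout_rate, accrual_rate = accrual_rate,
    max_followup_months = max_followup_months,
    covariate_prev = covariate_prev,
    covariate_hr_pfs = covariate_hr_pfs),
    class = "synthetic_trial_config")
}

#' @export
print.synthetic_trial_config <- function(x, ...) {
  cat(sprintf("Synthetic umbrella-trial config: %d screened, %d arms, seed %d\n",
              x$n_screened, length(x$arm_names), x$seed))
  cat("  prevalences:", paste(sprintf("%s %.3f", x$arm_names, x$arm_prevalences),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Simulate one patient's full trajectory
#'
#' Draws one patient from the generator: a Bernoulli responder flag at the
#' arm's true response rate; latent progression and death days, exponential
#' with the configured medians (`rate = log(2) / median`, the progression
#' hazard scaled by any covariate hazard ratios), with the death day equal
#' to the progression day plus an exponential post-progression increment so
#' OS never precedes PFS; scheduled assessments every two cycles with
#' statuses read off the latent trajectory (responders show a >= 30% target
#' shrinkage from the first scan on and are confirmed at the next one);
#' and dropout, uniform over the first two cycles, censoring all later
#' observation. Responders' progression days are shifted past the
#' confirmation scan, so a confirmed response is observable whenever
#' dropout and death do not intervene. Uses R's global RNG stream: seed it
#' (or call via [simulate_trial()]) for reproducibility.
#'
#' @param config a [synthetic_trial_config()].
#' @param arm arm label.
#' @param patient_id patient label.
#' @param enrollment_day day of first dose on the trial clock.
#' @return List of class `patient_record`: patient-level fields (including
#'   latent `pfs_day`/`os_day` and covariate flags) plus an `assessments`
#'   data frame.
#' @export
simulate_patient <- function(config, arm, patient_id = "P1", enrollment_day = 0) {
  stopifnot(inherits(config, "synthetic_trial_config"), arm %in% config$arm_names)
  interval <- 2 * config$cycle_days[[arm]]
  cutoff <- config$max_followup_months * DAYS_PER_MONTH
  covs <- stats::rbinom(length(config$covariate_prev), 1L, config$covariate_prev)
  names(covs) <- names(config$covariate_prev)
  hr <- prod(config$covariate_hr_pfs^covs)
  rate_pfs <- hr * log(2) / (config$median_pfs_months[[arm]] * DAYS_PER_MONTH)
  gap_os <- config$median_os_months[[arm]] - config$median_pfs_months[[arm]]
  rate_post <- log(2) / (max(gap_os, 0.1) * DAYS_PER_MONTH)

  responder <- stats::runif(1) < config$true_orr[[arm]]
  conf_day <- 2 * interval  # second scheduled scan confirms the response
  pfs_day <- if (responder) conf_day + stats::rexp(1, rate_pfs)
             else stats::rexp(1, rate_pfs)
  os_day <- pfs_day + stats::rexp(1, rate_post)
  dropout <- stats::runif(1) < config$dropout_rate
  dropout_day <- if (dropout) stats::runif(1, 0, interval) else NA_real_

  obs_end <- min(os_day, cutoff, dropout_day, na.rm = TRUE)
  shrink <- stats::runif(1, -80, -35)  # responder best target change
  days <- seq(interval, by = interval,
              length.out = max(0L, floor(obs_end / interval)))
  prog <- days >= pfs_day
  if (any(prog)) days <- days[seq_len(which(prog)[1L])]  # stop after first PD
  k <- length(days)
  if (k) {
    prog <- days >= pfs_day
    status <- rep(if (responder) "PR" else "SD", k)
    status[prog] <- "PD"
    base_chg <- if (responder) shrink + stats::runif(k, -2, 2)
                else stats::runif(k, -25, 15)
    base_chg[prog] <- if (responder) shrink + 40 else stats::runif(sum(prog), 20, 60)
    nadir_chg <- if (responder) stats::runif(k, -2, 2) else stats::runif(k, 0, 15)
    nadir_chg[prog] <- stats::runif(sum(prog), 20, 60)
    assessments <- data.frame(day = days, status = status,
                              target_sum_change = base_chg,
                              change_from_nadir = nadir_chg,
                              patient_id = patient_id,
                              stringsAsFactors = FALSE)
  } else {
    assessments <- data.frame(day = numeric(0), status = character(0),
                              target_sum_change = numeric(0),
                              change_from_nadir = numeric(0),
                              patient_id = character(0))
  }

  died <- !dropout && os_day <= cutoff
  last_contact <- if (dropout) dropout_day else min(os_day, cutoff)
  structure(list(
    patient_id = patient_id, arm = arm, enrollment_day = enrollment_day,
    responder = responder, pfs_day = pfs_day, os_day = os_day,
    dropout_day = dropout_day,
    death_day = if (died) os_day else NA_real_,
    last_contact_day = last_contact,
    discontinued_without_pd = dropout,
    visit_interval_days = interval,
    covariates = covs,
    assessments = assessments), class = "patient_record")
}

#' Simulate a complete umbrella trial
#'
#' Screens `n_screened` patients, thins by the screening-failure rate,
#' assigns arms by multinomial prevalence, spaces enrollments with
#' exponential inter-arrival gaps at the accrual rate, and simulates every
#' patient with [simulate_patient()]. Output tables use the exact input
#' schemas of the response and survival modules; the truth ledger records
#' the generating parameters for recovery tests.
#'
#' @param config a [synthetic_trial_config()].
#' @return Object of class `synthetic_trial`: list with `patients` (one row
#'   per patient, including covariate columns), `assessments` (long table),
#'   and `truth` (generating parameters plus realized per-arm counts).
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "synthetic_trial_config"))
  set.seed(config$seed)
  enrolled <- stats::runif(config$n_screened) >= config$screen_fail_rate
  n_enr <- sum(enrolled)
  arms <- sample(config$arm_names, n_enr, replace = TRUE,
                 prob = config$arm_prevalences)
  gaps <- stats::rexp(n_enr, config$accrual_rate / DAYS_PER_MONTH)
  enroll_days <- cumsum(gaps)
  recs <- lapply(seq_len(n_enr), function(i)
    simulate_patient(config, arms[i], patient_id = sprintf("P%04d", i),
                     enrollment_day = enroll_days[i]))
  cov_names <- names(config$covariate_prev)
  patients <- do.call(rbind, lapply(recs, function(r) {
    row <- data.frame(patient_id = r$patient_id, arm = r$arm,
                      enrollment_day = r$enrollment_day,
                      responder = r$responder,
                      death_day = r$death_day,
                      last_contact_day = r$last_contact_day,
                      discontinued_without_pd = r$discontinued_without_pd,
                      visit_interval_days = r$visit_interval_days,
                      stringsAsFactors = FALSE)
    for (cn in cov_names) row[[cn]] <- unname(r$covariates[[cn]])
    row
  }))
  assessments <- do.call(rbind, c(
    lapply(recs, function(r) {
      a <- r$assessments
      if (nrow(a)) cbind(a, arm = r$arm) else NULL
    }),
    list(make.row.names = FALSE)))
  if (is.null(assessments))
    assessments <- data.frame(day = numeric(0), status = character(0),
                              target_sum_change = numeric(0),
                              change_from_nadir = numeric(0),
                              patient_id = character(0), arm = character(0))
  truth <- list(config = config,
                n_enrolled = n_enr,
                arm_counts = table(factor(arms, levels = config$arm_names)),
                true_orr = config$true_orr,
                median_pfs_months = config$median_pfs_months,
                median_os_months = config$median_os_months)
  structure(list(patients = patients, assessments = assessments,
                 truth = truth), class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("Synthetic umbrella trial: %d patients enrolled\n",
              nrow(x$patients)))
  print(x$truth$arm_counts)
  invisible(x)
}
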
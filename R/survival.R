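#' Derive progression-free survival for one patient
#'
#' Applies the trial's PFS conventions to one patient's records. Time runs
#' from first dose (day 0) and is reported in months (days / 30.4375).
#' * Documented progression (a PD assessment) is an event on that day.
#' * Death without documented progression is an event on the death day,
#'   unless more than one scheduled assessment visit was missed beforehand —
#'   operationalized as a gap greater than `2 * visit_interval_days` between
#'   the last adequate (non-NE) assessment, or day 0, and death — in which
#'   case the patient is censored on the day of last documented
#'   nonprogression.
#' * Treatment discontinuation without documented progression censors on the
#'   last progression-free assessment day.
#' * Otherwise the patient is censored at the last progression-free
#'   assessment (day 0 when no postbaseline scan exists).
#'
#' @param assessments data frame with `day` and `status` for the patient
#'   (may have zero rows).
#' @param death_day day of death or `NA` if alive at data cutoff.
#' @param last_contact_day day of last contact; must not precede the last
#'   assessment.
#' @param discontinued_without_pd logical: stopped treatment without
#'   documented progression.
#' @param visit_interval_days scheduled days between tumor assessments
#'   (two treatment cycles).
#' @return List of class `survival_datum`: `time` (months), `event` (0/1),
#'   `endpoint = "PFS"`, `censor_reason`.
#' @export
derive_pfs <- function(assessments, death_day = NA, last_contact_day,
                       discontinued_without_pd = FALSE, visit_interval_days) {
  assessments <- check_assessments(assessments)
  if (!is.na(death_day) && death_day < 0)
    stop("data error: death before day 0", call. = FALSE)
  if (nrow(assessments) && last_contact_day < max(assessments$day))
    stop("data error: last contact precedes an assessment", call. = FALSE)
  if (!is.na(death_day) && death_day > last_contact_day)
    stop("data error: death after last contact", call. = FALSE)
  if (visit_interval_days <= 0)
    stop("data error: 'visit_interval_days' must be positive", call. = FALSE)

  day <- assessments$day
  status <- assessments$status
  nonprog_day <- if (any(status %in% c("CR", "PR", "SD")))
    max(day[status %in% c("CR", "PR", "SD")]) else 0
  adequate_day <- if (any(status != "NE")) max(day[status != "NE"]) else 0

  datum <- function(day, event, reason)
    structure(list(time = days_to_months(day), event = event,
                   endpoint = "PFS", censor_reason = reason),
              class = "survival_datum")

  if (any(status == "PD")) {
    return(datum(min(day[status == "PD"]), 1L, "progression"))
  }
  if (!is.na(death_day)) {
    if (death_day - adequate_day > 2 * visit_interval_days)
      return(datum(nonprog_day, 0L, "death_after_missed_visits"))
    return(datum(death_day, 1L, "death_without_progression"))
  }
  if (isTRUE(discontinued_without_pd))
    return(datum(nonprog_day, 0L, "discontinued_without_documented_pd"))
  datum(nonprog_day, 0L, "no_progression_at_cutoff")
}

#' Derive overall survival for one patient
#'
#' Event at the death day when death was observed, otherwise censored at the
#' last contact day. Time in months from first dose.
#'
#' @inheritParams derive_pfs
#' @return List of class `survival_datum` with `endpoint = "OS"`.
#' @export
derive_os <- function(death_day = NA, last_contact_day) {
  if (!is.na(death_day)) {
    if (death_day < 0) stop("data error: death before day 0", call. = FALSE)
    if (death_day > last_contact_day)
      stop("data error: death after last contact", call. = FALSE)
    return(structure(list(time = days_to_months(death_day), event = 1L,
                          endpoint = "OS", censor_reason = "death"),
                     class = "survival_datum"))
  }
  structure(list(time = days_to_months(last_contact_day), event = 0L,
                 endpoint = "OS", censor_reason = "alive_at_last_contact"),
            class = "survival_datum")
}

#' Derive PFS and OS for a whole trial table
#'
#' @param patients data frame with one row per patient: `patient_id`, `arm`
#'   (optional), `death_day` (`NA` if alive), `last_contact_day`,
#'   `discontinued_without_pd`, `visit_interval_days`.
#' @param assessments long data frame (`patient_id`, `day`, `status`).
#' @return Data frame with columns `patient_id`, `arm`, `endpoint`, `time`
#'   (months), `event`, `censor_reason` (two rows per patient).
#' @export
derive_survival_table <- function(patients, assessments) {
  stopifnot(is.data.frame(patients), "patient_id" %in% names(patients))
  has_arm <- "arm" %in% names(patients)
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    a <- assessments[assessments$patient_id == p$patient_id, , drop = FALSE]
    a <- a[order(a$day), , drop = FALSE]
    pfs <- derive_pfs(a, death_day = p$death_day,
                      last_contact_day = p$last_contact_day,
                      discontinued_without_pd = p$discontinued_without_pd,
                      visit_interval_days = p$visit_interval_days)
    os <- derive_os(death_day = p$death_day,
                    last_contact_day = p$last_contact_day)
    data.frame(patient_id = p$patient_id,
               arm = if (has_arm) p$arm else NA_character_,
               endpoint = c("PFS", "OS"),
               time = c(pfs$time, os$time),
               event = c(pfs$event, os$event),
               censor_reason = c(pfs$censor_reason, os$censor_reason),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier estimate with Greenwood errors and median
#'
#' Product-limit estimate of the survivor function, with Greenwood standard
#' errors, pointwise confidence limits and the median with its confidence
#' interval (Brookmeyer-Crowley with log-log transform by default). The
#' median is the earliest time at which the estimated survivor function
#' drops to 0.5 or below; it is `NA` when never reached.
#'
#' @param data data frame with columns `time` (months) and `event` (0/1).
#' @param conf_level confidence level.
#' @param conf_type transformation for the confidence limits, passed to
#'   [survival::survfit()] (default `"log-log"`).
#' @return Object of class `km_estimate`: list with the step `table`
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `surv`, `std_err`, `lower`,
#'   `upper`), `median`, `median_ci`, `n`, `n_events` and the underlying
#'   `survfit` object.
#' @export
km_estimate <- function(data, conf_level = 0.95, conf_type = "log-log") {
  stopifnot(is.data.frame(data), all(c("time", "event") %in% names(data)))
  if (nrow(data) == 0L) stop("domain error: no survival data", call. = FALSE)
  if (any(data$time < 0)) stop("domain error: negative survival times", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data,
                           conf.int = conf_level, conf.type = conf_type)
  s <- summary(fit, censored = TRUE)
  tab <- data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                    n_censor = s$n.censor, surv = s$surv, std_err = s$std.err,
                    lower = s$lower, upper = s$upper)
  med <- summary(fit)$table
  # median convention: earliest time with S(t) <= 0.5 (survfit averages
  # flat intervals instead); the CI stays Brookmeyer-Crowley from survfit
  reached <- tab$time[tab$surv <= 0.5 & tab$n_event > 0]
  structure(list(table = tab,
                 median = if (length(reached)) min(reached) else NA_real_,
                 median_ci = unname(c(med["0.95LCL"], med["0.95UCL"])),
                 n = nrow(data), n_events = sum(data$event),
                 conf_level = conf_level, fit = fit),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d\n", x$n, x$n_events))
  med <- if (is.na(x$median)) "not reached" else
    sprintf("%.2f (%.2f-%.2f) months", x$median, x$median_ci[1], x$median_ci[2])
  cat(sprintf("  median: %s\n", med))
  invisible(x)
}

#' Survivor-function estimate of a fitted curve at a time point
#'
#' @param km a [km_estimate()] object.
#' @param times numeric vector of landmark times (months, `>= 0`).
#' @return Data frame with `time`, `surv`, `lower`, `upper`, `estimable`;
#'   times beyond follow-up are flagged not estimable with `NA` estimates.
#' @export
landmark_table <- function(km, times) {
  stopifnot(inherits(km, "km_estimate"))
  if (any(times < 0)) stop("domain error: negative landmark time", call. = FALSE)
  max_t <- max(km$fit$time)
  rows <- lapply(times, function(t0) {
    if (t0 > max_t)
      return(data.frame(time = t0, surv = NA_real_, lower = NA_real_,
                        upper = NA_real_, estimable = FALSE))
    s <- summary(km$fit, times = t0)
    data.frame(time = t0, surv = s$surv, lower = s$lower, upper = s$upper,
               estimable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Univariate Cox proportional-hazards screen for a binary covariate
#'
#' Fits the Cox partial likelihood (Breslow tie handling by default) for a
#' single binary covariate, returning the hazard ratio with Wald confidence
#' interval and p-value — the standard univariate biomarker screen behind a
#' forest plot. Fits with a monotone partial likelihood (all events on one
#' side) are reported as nonconvergent rather than as a finite estimate.
#'
#' @param data data frame with `time` and `event`.
#' @param group binary covariate (0/1, logical, or two-level factor), one
#'   value per row of `data`.
#' @param label covariate label carried into the result.
#' @param ties tie-handling method, `"breslow"` (default) or `"efron"`.
#' @param conf_level confidence level for the Wald interval.
#' @return Object of class `cox_result`: list with `label`, `coef` (log HR),
#'   `se`, `hr`, `ci_low`, `ci_high`, `p_value`, `n`, `n_events`,
#'   `group_sizes`, `converged`.
#' @export
cox_univariate <- function(data, group, label = "covariate",
                           ties = c("breslow", "efron"), conf_level = 0.95) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(data), all(c("time", "event") %in% names(data)))
  g <- as.integer(as.factor(group)) - 1L
  if (length(g) != nrow(data))
    stop("domain error: 'group' length must match the data", call. = FALSE)
  if (length(unique(g)) < 2L)
    stop("estimability error: covariate is constant", call. = FALSE)
  if (sum(data$event) == 0L)
    stop("estimability error: no events observed", call. = FALSE)
  dat <- data.frame(time = data$time, event = data$event, g = g)
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ g, data = dat,
                    ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1L, 1L]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  converged <- !warned && is.finite(beta) && abs(beta) < 15
  structure(list(label = label, coef = beta, se = se, hr = exp(beta),
                 ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
                 p_value = 2 * stats::pnorm(-abs(beta / se)),
                 n = nrow(dat), n_events = sum(dat$event),
                 group_sizes = as.vector(table(g)),
                 converged = converged),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("Cox screen [%s]: nonconvergent (monotone likelihood)\n", x$label))
  } else {
    cat(sprintf("Cox screen [%s]: HR %.3f (%.3f-%.3f), p = %.4g, %d/%d events\n",
                x$label, x$hr, x$ci_low, x$ci_high, x$p_value,
                x$n_events, x$n))
  }
  invisible(x)
}
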
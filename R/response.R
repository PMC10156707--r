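RESPONSE_LEVELS <- c("CR", "PR", "SD", "PD", "NE")

#' Classify a single tumor assessment from percent changes
#'
#' Applies the solid-tumor response thresholds to one timepoint: progressive
#' disease (PD) when the target-lesion sum has grown at least 20% from its
#' nadir, partial response (PR) when it has shrunk at least 30% from
#' baseline, stable disease (SD) otherwise. The nadir rule dominates:
#' growth from nadir is checked first. Complete responses (disappearance of
#' all lesions) are recorded upstream as a status code, not derived from
#' percent changes. When both inputs are missing the timepoint is not
#' evaluable (NE).
#'
#' @param target_sum_change percent change of the target-lesion diameter sum
#'   versus baseline (negative = shrinkage).
#' @param change_from_nadir percent change versus the smallest sum observed
#'   so far; when missing, the baseline change is used for the PD check
#'   (the nadir is never larger than baseline, so this is conservative).
#' @return Character vector with values in `c("PR", "SD", "PD", "NE")`.
#' @export
classify_timepoint <- function(target_sum_change, change_from_nadir = NULL) {
  if (is.null(change_from_nadir)) change_from_nadir <- rep(NA_real_, length(target_sum_change))
  n <- max(length(target_sum_change), length(change_from_nadir))
  base <- rep_len(as.numeric(target_sum_change), n)
  nad <- rep_len(as.numeric(change_from_nadir), n)
  growth <- ifelse(is.na(nad), base, nad)
  out <- rep("NE", n)
  have <- !(is.na(base) & is.na(nad))
  out[have] <- "SD"
  out[have & !is.na(growth) & growth >= 20] <- "PD"
  pr <- have & out != "PD" & !is.na(base) & base <= -30
  out[pr] <- "PR"
  out
}

check_assessments <- function(assessments) {
  if (!is.data.frame(assessments) || !all(c("day", "status") %in% names(assessments)))
    stop("data error: assessments need columns 'day' and 'status'", call. = FALSE)
  if (nrow(assessments) == 0L) return(assessments)
  if (any(!assessments$status %in% RESPONSE_LEVELS))
    stop("data error: unknown response status code", call. = FALSE)
  if (any(!is.finite(assessments$day)) || any(assessments$day < 0))
    stop("data error: assessment days must be nonnegative", call. = FALSE)
  if (is.unsorted(assessments$day, strictly = FALSE))
    stop("data error: assessments must be sorted by day", call. = FALSE)
  if (anyDuplicated(assessments$day))
    stop("data error: at most one assessment per day", call. = FALSE)
  assessments
}

#' Derive the confirmed best overall response for one patient
#'
#' Reduces a patient's ordered postbaseline assessments to a single best
#' overall response (BOR) under the confirmation rules:
#' * CR or PR counts only when a later scan at least `confirm_min_days`
#'   days after the first qualifying scan shows the same-or-better category
#'   (a PR may be confirmed by a CR; a CR only by a CR);
#' * SD requires an SD-or-better scan at least `sd_min_days` days after the
#'   first dose (day 0);
#' * otherwise PD if progression was documented;
#' * `NA` when there is no postbaseline scan.
#' Assessments on or after the first documented progression never upgrade
#' the BOR; NE scans are skipped for confirmation. A patient whose scans
#' exist but qualify for none of the categories (e.g. a single early SD
#' followed by loss to follow-up) is returned as `NA` with reason
#' `"not_evaluable"`; an unconfirmed PR is downgraded to SD when the
#' SD-duration rule holds.
#'
#' @param assessments data frame with columns `day` (integer days from first
#'   dose, sorted, unique) and `status` (`CR`/`PR`/`SD`/`PD`/`NE`);
#'   optionally `patient_id`.
#' @param sd_min_days minimum days from first dose for SD (default 56,
#'   i.e. 8 weeks, inclusive).
#' @param confirm_min_days minimum gap to the confirming scan (default 28,
#'   i.e. 4 weeks, inclusive).
#' @return A list of class `bor` with `patient_id`, `bor` (one of
#'   `CR`/`PR`/`SD`/`PD`/`NA`), `confirmed`, `response_day`,
#'   `confirmation_day`, `reason`.
#' @export
derive_bor <- function(assessments, sd_min_days = 56, confirm_min_days = 28) {
  assessments <- check_assessments(assessments)
  pid <- if ("patient_id" %in% names(assessments) && nrow(assessments))
    assessments$patient_id[1L] else NA_character_
  res <- list(patient_id = pid, bor = NA_character_, confirmed = FALSE,
              response_day = NA_real_, confirmation_day = NA_real_,
              reason = "no_postbaseline_assessment")
  class(res) <- "bor"
  if (nrow(assessments) == 0L) return(res)

  day <- assessments$day
  status <- assessments$status
  pd_day <- if (any(status == "PD")) min(day[status == "PD"]) else Inf
  pre <- day < pd_day & status != "NE"
  d <- day[pre]; s <- status[pre]

  confirm <- function(ok_first, ok_confirming) {
    first <- which(s %in% ok_first)
    for (i in first) {
      j <- which(s %in% ok_confirming & d >= d[i] + confirm_min_days)
      if (length(j)) return(c(d[i], d[j[1L]]))
    }
    NULL
  }
  hit <- confirm("CR", "CR")
  if (!is.null(hit)) {
    res[c("bor", "confirmed")] <- list("CR", TRUE)
    res$response_day <- hit[1L]; res$confirmation_day <- hit[2L]
    res$reason <- "confirmed_cr"
    return(res)
  }
  hit <- confirm(c("CR", "PR"), c("CR", "PR"))
  if (!is.null(hit)) {
    res[c("bor", "confirmed")] <- list("PR", TRUE)
    res$response_day <- hit[1L]; res$confirmation_day <- hit[2L]
    res$reason <- "confirmed_pr"
    return(res)
  }
  if (any(s %in% c("CR", "PR", "SD") & d >= sd_min_days)) {
    res$bor <- "SD"
    res$reason <- if (any(s %in% c("CR", "PR"))) "unconfirmed_response_downgraded" else "sd_duration_met"
    return(res)
  }
  if (is.finite(pd_day)) {
    res$bor <- "PD"
    res$reason <- "progression_before_qualifying_response"
    return(res)
  }
  res$reason <- "not_evaluable"
  res
}

#' Derive best overall responses for a whole trial table
#'
#' Splits a long assessment table by patient, sorts by day and applies
#' [derive_bor()] to each patient.
#'
#' @param assessments data frame with columns `patient_id`, `day`, `status`
#'   and optionally `arm`.
#' @inheritParams derive_bor
#' @return Data frame with one row per patient: `patient_id`, `arm` (if
#'   present), `bor`, `confirmed`, `response_day`, `confirmation_day`,
#'   `reason`.
#' @export
derive_bor_table <- function(assessments, sd_min_days = 56, confirm_min_days = 28) {
  stopifnot(is.data.frame(assessments), "patient_id" %in% names(assessments))
  has_arm <- "arm" %in% names(assessments)
  if (nrow(assessments) == 0L)
    return(data.frame(patient_id = character(0), arm = character(0),
                      bor = character(0), confirmed = logical(0),
                      response_day = numeric(0), confirmation_day = numeric(0),
                      reason = character(0), stringsAsFactors = FALSE))
  split_idx <- split(seq_len(nrow(assessments)), assessments$patient_id)
  rows <- lapply(split_idx, function(idx) {
    a <- assessments[idx, , drop = FALSE]
    a <- a[order(a$day), , drop = FALSE]
    b <- derive_bor(a, sd_min_days = sd_min_days, confirm_min_days = confirm_min_days)
    data.frame(patient_id = a$patient_id[1L],
               arm = if (has_arm) a$arm[1L] else NA_character_,
               bor = b$bor, confirmed = b$confirmed,
               response_day = b$response_day,
               confirmation_day = b$confirmation_day,
               reason = b$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Two-sided exact interval from inverting the binomial test, in its
#' beta-quantile form: lower endpoint the `alpha/2` quantile of
#' `Beta(x, n - x + 1)` (0 when `x = 0`), upper endpoint the `1 - alpha/2`
#' quantile of `Beta(x + 1, n - x)` (1 when `x = n`).
#'
#' @param x number of successes, `0 <= x <= n`.
#' @param n number of trials, `n >= 1`.
#' @param conf_level two-sided confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)` on the proportion scale.
#' @examples
#' clopper_pearson(42, 141)  # c(0.2239..., 0.3808...)
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  check_xn(x, n)
  if (n < 1) stop("domain error: 'n' must be at least 1", call. = FALSE)
  alpha <- 1 - conf_level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Binomial proportion with exact interval, on the reporting scale
#'
#' Packages a responder count with its exact Clopper-Pearson interval as
#' percentages rounded half-up to one decimal, the trial reporting
#' convention.
#'
#' @inheritParams clopper_pearson
#' @return Object of class `binomial_summary`: list with `x`, `n`,
#'   `proportion`, `ci_low`, `ci_high` (percent, one decimal) and
#'   `conf_level`.
#' @export
binomial_summary <- function(x, n, conf_level = 0.95) {
  ci <- clopper_pearson(x, n, conf_level)
  structure(list(x = as.integer(x), n = as.integer(n),
                 proportion = round_half_up(100 * x / n, 1L),
                 ci_low = round_half_up(100 * ci[["lower"]], 1L),
                 ci_high = round_half_up(100 * ci[["upper"]], 1L),
                 conf_level = conf_level),
            class = "binomial_summary")
}

#' @export
print.binomial_summary <- function(x, ...) {
  cat(sprintf("%d/%d = %s\n", x$x, x$n, format_rate_ci(x)))
  invisible(x)
}

#' Format a binomial summary as "xx.x (lo–hi)"
#'
#' @param s a [binomial_summary()] object.
#' @return Character scalar.
#' @export
format_rate_ci <- function(s) {
  sprintf("%.1f (%.1f–%.1f)", s$proportion, s$ci_low, s$ci_high)
}

#' Objective response and disease control rates with exact intervals
#'
#' ORR counts confirmed CR + PR; DCR counts CR + PR + SD (stable disease
#' held at least 8 weeks, already enforced by [derive_bor()]). Both use the
#' intention-to-treat denominator, so patients without a postbaseline scan
#' (`bor = NA`) stay in the denominator.
#'
#' @param bors data frame as returned by [derive_bor_table()] (columns
#'   `bor`, `confirmed`).
#' @param denominator intention-to-treat patient count; must be at least the
#'   number of rows in `bors`.
#' @param conf_level confidence level for the exact intervals.
#' @return List with elements `orr` and `dcr`, each a [binomial_summary()].
#' @export
summarize_orr_dcr <- function(bors, denominator = nrow(bors), conf_level = 0.95) {
  if (denominator < 1) stop("domain error: denominator must be positive", call. = FALSE)
  if (denominator < nrow(bors))
    stop("domain error: denominator smaller than the number of patients", call. = FALSE)
  n_resp <- sum(bors$bor %in% c("CR", "PR") & bors$confirmed, na.rm = TRUE)
  n_dc <- n_resp + sum(bors$bor %in% "SD", na.rm = TRUE)
  list(orr = binomial_summary(n_resp, denominator, conf_level),
       dcr = binomial_summary(n_dc, denominator, conf_level))
}
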
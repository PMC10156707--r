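#' Read a design configuration file
#'
#' Reads a structured key-value (YAML) file with keys `p0`, `prior_a`,
#' `prior_b`, `theta_T`, `theta_L`, `theta_U`, `n_max`, `monitor_start`,
#' `monitor_step` (missing keys fall back to the [ppd_design()] defaults)
#' into a validated design object.
#'
#' @param path file path.
#' @return A [ppd_design()] object.
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("p0", "prior_a", "prior_b", "theta_T", "theta_L", "theta_U",
               "n_max", "monitor_start", "monitor_step")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("config error: unknown design keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(ppd_design, cfg)
}

design_hash <- function(designs) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(lapply(designs, unclass), tf, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tf))
}

adjudication_days <- function(bors, assessments, patients) {
  # trial-clock day at which each patient's best-response determination
  # becomes available; NA for never-evaluable patients
  vapply(seq_len(nrow(bors)), function(i) {
    b <- bors[i, ]
    enroll <- patients$enrollment_day[match(b$patient_id, patients$patient_id)]
    a <- assessments[assessments$patient_id == b$patient_id, , drop = FALSE]
    if (is.na(b$bor)) return(NA_real_)
    d <- if (b$confirmed) {
      b$confirmation_day
    } else if (b$bor == "PD") {
      min(a$day[a$status == "PD"])
    } else {
      # SD is determinable at the first scan meeting the duration rule
      qual <- a$day[a$status %in% c("CR", "PR", "SD") & a$day >= 56]
      if (length(qual)) min(qual) else max(a$day)
    }
    enroll + d
  }, numeric(1L))
}

#' Replay Bayesian monitoring over an umbrella-trial dataset
#'
#' Runs the predictive-probability monitor arm by arm over a (simulated or
#' supplied) trial: derives each patient's confirmed best overall response,
#' replays adjudications in calendar order, applies the interim rule at each
#' scheduled look, freezes an arm's data when it stops, applies the final
#' rule at the arm's maximum size, and assembles a trial report with
#' per-arm response counts, exact-interval ORR/DCR summaries, the decision
#' history and pooled intention-to-treat summaries. A patient enters the
#' `(n, x)` monitoring state only once a best-response determination is
#' available; patients who never become evaluable stay in the
#' intention-to-treat denominator but never trigger looks.
#'
#' @param trial list with data frames `patients` (columns `patient_id`,
#'   `arm`, `enrollment_day`, ...) and `assessments` (`patient_id`, `day`,
#'   `status`), e.g. a [simulate_trial()] result.
#' @param designs a single [ppd_design()] applied to every arm, or a named
#'   list of designs per arm.
#' @param expansions optional named list of arm expansions, each
#'   `list(at_n = <evaluable size>, new_n_max = <raised maximum>)`, applied
#'   when the arm's evaluable count reaches `at_n` while still open.
#' @param stop_on_efficacy stop enrolling when the efficacy boundary is
#'   crossed (default `TRUE`); with `FALSE` the crossing is recorded and
#'   monitoring continues to the final analysis.
#' @return Object of class `trial_report`: per-arm summaries (`arms`),
#'   `decisions` (data frame: arm, look, n, x, pp, action), pooled ITT
#'   summaries (`pooled`), `bor_table`, and a `config_hash` for provenance.
#' @export
run_monitored_trial <- function(trial, designs, expansions = list(),
                                stop_on_efficacy = TRUE) {
  patients <- trial$patients
  assessments <- trial$assessments
  stopifnot(is.data.frame(patients), is.data.frame(assessments))
  arm_names <- sort(unique(patients$arm))
  if (inherits(designs, "ppd_design")) {
    designs <- stats::setNames(rep(list(designs), length(arm_names)), arm_names)
  } else {
    # designed arms with no enrolled patients still get a report row
    arm_names <- sort(union(arm_names, names(designs)))
  }
  if (!all(arm_names %in% names(designs)))
    stop("data error: no design supplied for arm(s): ",
         paste(setdiff(arm_names, names(designs)), collapse = ", "),
         call. = FALSE)

  bors <- derive_bor_table(assessments)
  # patients with no assessment rows at all never appear in the long table
  missing <- setdiff(patients$patient_id, bors$patient_id)
  if (length(missing)) {
    bors <- rbind(bors, data.frame(
      patient_id = missing,
      arm = patients$arm[match(missing, patients$patient_id)],
      bor = NA_character_, confirmed = FALSE, response_day = NA_real_,
      confirmation_day = NA_real_, reason = "no_postbaseline_assessment",
      stringsAsFactors = FALSE))
  }
  bors$arm <- patients$arm[match(bors$patient_id, patients$patient_id)]
  bors$adjudication_day <- adjudication_days(bors, assessments, patients)
  bors$enrollment_day <- patients$enrollment_day[
    match(bors$patient_id, patients$patient_id)]

  decisions <- list()
  arms <- list()
  for (arm in arm_names) {
    design <- stopifnot_design(designs[[arm]])
    ab <- bors[bors$arm == arm, , drop = FALSE]
    ab <- ab[order(ab$enrollment_day), , drop = FALSE]
    ev <- ab[!is.na(ab$adjudication_day), , drop = FALSE]
    ev <- ev[order(ev$adjudication_day), , drop = FALSE]
    n_max_cur <- design$n_max
    status <- "open"
    stop_day <- Inf
    n <- 0L; x <- 0L; look <- 0L
    exp_spec <- expansions[[arm]]
    for (i in seq_len(nrow(ev))) {
      n <- n + 1L
      x <- x + as.integer(isTRUE(ev$confirmed[i]) && ev$bor[i] %in% c("CR", "PR"))
      if (!is.null(exp_spec) && n == exp_spec$at_n && status == "open" &&
          exp_spec$new_n_max > n_max_cur) {
        n_max_cur <- as.integer(exp_spec$new_n_max)
        decisions[[length(decisions) + 1L]] <- data.frame(
          arm = arm, look = NA_integer_, n = n, x = x, pp = NA_real_,
          action = sprintf("expand_to_%d", n_max_cur))
      }
      if (n >= n_max_cur) {
        cut <- final_success_cutoff(n_max_cur, design)
        success <- !is.na(cut) && x >= cut
        status <- if (success) "completed_success" else "completed_failure"
        look <- look + 1L
        decisions[[length(decisions) + 1L]] <- data.frame(
          arm = arm, look = look, n = n, x = x,
          pp = as.numeric(success),
          action = if (success) "declare_success" else "declare_failure")
        stop_day <- ev$adjudication_day[i]
        break
      }
      if (n %in% monitor_looks(design, n_max_cur)) {
        look <- look + 1L
        dec <- interim_decision(x, n, design, n_max = n_max_cur)
        decisions[[length(decisions) + 1L]] <- data.frame(
          arm = arm, look = look, n = n, x = x, pp = attr(dec, "pp"),
          action = as.character(dec))
        if (dec == "stop_futility") {
          status <- "stopped_futility"; stop_day <- ev$adjudication_day[i]
          break
        }
        if (dec == "stop_efficacy" && stop_on_efficacy) {
          status <- "stopped_efficacy"; stop_day <- ev$adjudication_day[i]
          break
        }
      }
    }
    itt <- ab[ab$enrollment_day <= stop_day, , drop = FALSE]
    counts <- c(CR = sum(itt$bor %in% "CR"), PR = sum(itt$bor %in% "PR"),
                SD = sum(itt$bor %in% "SD"), PD = sum(itt$bor %in% "PD"),
                `NA` = sum(is.na(itt$bor)))
    rates <- if (nrow(itt)) summarize_orr_dcr(itt, denominator = nrow(itt))
             else NULL
    arms[[arm]] <- list(arm = arm, n_itt = nrow(itt),
                        n_evaluable = n, n_responders = x,
                        counts = counts, orr = rates$orr, dcr = rates$dcr,
                        status = status, n_max_final = n_max_cur,
                        itt_patients = itt$patient_id)
  }
  decisions <- if (length(decisions)) do.call(rbind, decisions)
               else data.frame(arm = character(0), look = integer(0),
                               n = integer(0), x = integer(0),
                               pp = numeric(0), action = character(0))
  itt_ids <- unlist(lapply(arms, `[[`, "itt_patients"), use.names = FALSE)
  pooled_b <- bors[bors$patient_id %in% itt_ids, , drop = FALSE]
  pooled <- list(n_itt = nrow(pooled_b),
                 counts = c(CR = sum(pooled_b$bor %in% "CR"),
                            PR = sum(pooled_b$bor %in% "PR"),
                            SD = sum(pooled_b$bor %in% "SD"),
                            PD = sum(pooled_b$bor %in% "PD"),
                            `NA` = sum(is.na(pooled_b$bor))),
                 orr = if (nrow(pooled_b))
                   summarize_orr_dcr(pooled_b, nrow(pooled_b))$orr else NULL,
                 dcr = if (nrow(pooled_b))
                   summarize_orr_dcr(pooled_b, nrow(pooled_b))$dcr else NULL)
  structure(list(arms = arms, decisions = decisions, pooled = pooled,
                 bor_table = bors, config_hash = design_hash(designs)),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat("Monitored umbrella-trial report\n")
  for (a in x$arms)
    cat(sprintf("  arm %s: n=%d (evaluable %d), responders %d, %s, ORR %s\n",
                a$arm, a$n_itt, a$n_evaluable, a$n_responders, a$status,
                if (is.null(a$orr)) "NA" else format_rate_ci(a$orr)))
  if (!is.null(x$pooled$orr))
    cat(sprintf("  pooled ITT (n=%d): ORR %s, DCR %s\n", x$pooled$n_itt,
                format_rate_ci(x$pooled$orr), format_rate_ci(x$pooled$dcr)))
  invisible(x)
}

summary_cell <- function(s) if (is.null(s)) "NA" else format_rate_ci(s)

#' Render a trial report as response-summary tables
#'
#' Builds the wide per-arm response table (best-response counts, then
#' responder counts and percentage cells formatted `"xx.x (lo–hi)"` for the
#' objective response and disease control rates) and, when `dir` is given,
#' writes `report.csv`, `report.json` and `decisions.csv`.
#'
#' @param report a `trial_report` from [run_monitored_trial()].
#' @param dir optional output directory (created if needed).
#' @return The wide report data frame, invisibly when writing.
#' @export
report_tables <- function(report, dir = NULL) {
  stopifnot(inherits(report, "trial_report"))
  cols <- c(list(ITT = c(
    as.character(report$pooled$counts),
    as.character(report$pooled$counts[["CR"]] + report$pooled$counts[["PR"]]),
    summary_cell(report$pooled$orr),
    as.character(report$pooled$counts[["CR"]] + report$pooled$counts[["PR"]] +
                   report$pooled$counts[["SD"]]),
    summary_cell(report$pooled$dcr),
    "", sprintf("%d", report$pooled$n_itt))),
    lapply(report$arms, function(a) c(
      as.character(a$counts),
      as.character(a$counts[["CR"]] + a$counts[["PR"]]),
      summary_cell(a$orr),
      as.character(a$counts[["CR"]] + a$counts[["PR"]] + a$counts[["SD"]]),
      summary_cell(a$dcr),
      a$status, sprintf("%d", a$n_itt))))
  out <- data.frame(row = c("CR, n", "PR, n", "SD, n", "PD, n", "NA, n",
                            "Objective response, n", "ORR % (95% CI)",
                            "Disease control, n", "DCR % (95% CI)",
                            "Final status", "N"),
                    cols, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(out, file.path(dir, "report.csv"), row.names = FALSE)
    utils::write.csv(report$decisions, file.path(dir, "decisions.csv"),
                     row.names = FALSE)
    json <- list(config_hash = report$config_hash,
                 pooled = list(n = report$pooled$n_itt,
                               counts = as.list(report$pooled$counts),
                               orr = unclass(report$pooled$orr),
                               dcr = unclass(report$pooled$dcr)),
                 arms = lapply(report$arms, function(a)
                   list(arm = a$arm, n = a$n_itt, status = a$status,
                        counts = as.list(a$counts),
                        orr = unclass(a$orr), dcr = unclass(a$dcr))))
    jsonlite::write_json(json, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}

#' Simulate an umbrella trial and run the monitor over it
#'
#' Convenience wrapper: [simulate_trial()] then [run_monitored_trial()],
#' optionally writing the report files and per-endpoint Kaplan-Meier step
#' tables (`km_curves.csv`).
#'
#' @param config a [synthetic_trial_config()].
#' @param designs design(s) as in [run_monitored_trial()].
#' @param dir optional output directory.
#' @inheritParams run_monitored_trial
#' @return List with `trial` (the dataset), `report` and `survival` (the
#'   derived PFS/OS table).
#' @export
simulate_and_analyze <- function(config, designs, dir = NULL,
                                 expansions = list(),
                                 stop_on_efficacy = TRUE) {
  trial <- simulate_trial(config)
  report <- run_monitored_trial(trial, designs, expansions = expansions,
                                stop_on_efficacy = stop_on_efficacy)
  surv <- derive_survival_table(trial$patients, trial$assessments)
  if (!is.null(dir)) {
    report_tables(report, dir)
    km_rows <- do.call(rbind, lapply(c("PFS", "OS"), function(ep) {
      km <- km_estimate(surv[surv$endpoint == ep, ])
      cbind(endpoint = ep, km$table)
    }))
    utils::write.csv(km_rows, file.path(dir, "km_curves.csv"),
                     row.names = FALSE)
  }
  list(trial = trial, report = report, survival = surv)
}
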
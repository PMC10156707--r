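# hand-built monitored arm: confirmed PR pattern or SD-then-PD pattern
monitored_fixture <- function(n, responder, arm = "X", interval = 56) {
  pats <- data.frame(patient_id = sprintf("%s%02d", arm, seq_len(n)),
                     arm = arm, enrollment_day = 30 * (seq_len(n) - 1),
                     death_day = NA_real_, last_contact_day = 600,
                     discontinued_without_pd = FALSE,
                     visit_interval_days = interval,
                     stringsAsFactors = FALSE)
  sc <- do.call(rbind, lapply(seq_len(n), function(i) {
    st <- if (responder[i]) c("PR", "PR", "SD") else c("SD", "PD")
    data.frame(patient_id = pats$patient_id[i], arm = arm,
               day = interval * seq_along(st), status = st,
               stringsAsFactors = FALSE)
  }))
  list(patients = pats, assessments = sc)
}
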
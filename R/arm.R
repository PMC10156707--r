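#' Per-arm monitoring state
#'
#' Tracks one arm's evaluable enrollment, responder count, status and current
#' maximum size. The maximum may be raised during the trial (see
#' [expand_arm()]); every change is recorded in an audit trail kept as the
#' `"audit"` attribute.
#'
#' @param arm_id arm label.
#' @param n_enrolled evaluable patients observed so far.
#' @param n_responders confirmed responders among them.
#' @param status one of `"open"`, `"stopped_futility"`, `"stopped_efficacy"`,
#'   `"completed_success"`, `"completed_failure"`,
#'   `"closed_administratively"`.
#' @param n_max_current current maximum evaluable size.
#' @return An object of class `arm_state`.
#' @export
arm_state <- function(arm_id, n_enrolled = 0L, n_responders = 0L,
                      status = "open", n_max_current) {
  statuses <- c("open", "stopped_futility", "stopped_efficacy",
                "completed_success", "completed_failure",
                "closed_administratively")
  status <- match.arg(status, statuses)
  n_enrolled <- as.integer(n_enrolled)
  n_responders <- as.integer(n_responders)
  n_max_current <- as.integer(n_max_current)
  if (n_responders < 0L || n_enrolled < 0L || n_responders > n_enrolled)
    stop("domain error: need 0 <= n_responders <= n_enrolled", call. = FALSE)
  if (n_enrolled > n_max_current)
    stop("domain error: enrollment exceeds the arm's maximum size", call. = FALSE)
  structure(list(arm_id = arm_id, n_enrolled = n_enrolled,
                 n_responders = n_responders, status = status,
                 n_max_current = n_max_current),
            audit = list(), class = "arm_state")
}

#' @export
print.arm_state <- function(x, ...) {
  cat(sprintf("Arm %s: %d/%d responders, status %s, n_max %d\n",
              x$arm_id, x$n_responders, x$n_enrolled, x$status,
              x$n_max_current))
  invisible(x)
}

#' Expand (or amend) an arm's maximum evaluable size
#'
#' Raises the arm's monitoring horizon mid-trial, e.g. after promising
#' interim efficacy; subsequent predictive probabilities are computed against
#' the new maximum. Only open arms can be expanded, and the new maximum must
#' cover current enrollment. The change is appended to the audit trail.
#'
#' @param state an [arm_state()] object with status `"open"`.
#' @param new_n_max new maximum evaluable size.
#' @return The updated `arm_state`.
#' @export
expand_arm <- function(state, new_n_max) {
  if (!inherits(state, "arm_state")) stop("'state' must be an 'arm_state'", call. = FALSE)
  if (state$status != "open")
    stop("state error: cannot expand an arm that is not open", call. = FALSE)
  new_n_max <- as.integer(new_n_max)
  if (new_n_max < state$n_enrolled)
    stop("domain error: new maximum is below current enrollment", call. = FALSE)
  audit <- attr(state, "audit")
  audit[[length(audit) + 1L]] <- list(
    event = "expand", from = state$n_max_current, to = new_n_max,
    at_n = state$n_enrolled, time = Sys.time())
  state$n_max_current <- new_n_max
  attr(state, "audit") <- audit
  state
}
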
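#' Bayesian predictive-probability design specification
#'
#' Constructs the design object for a single-arm (or one umbrella-trial arm)
#' phase II design monitored with Bayesian predictive probability. The
#' response probability `p` carries a `Beta(prior_a, prior_b)` prior; after
#' observing `x` responders among `n` evaluable patients the posterior is
#' `Beta(prior_a + x, prior_b + n - x)`. The arm is declared effective at its
#' final analysis when the posterior probability that `p` exceeds the
#' reference rate `p0` is greater than `theta_T`; at interim looks the arm
#' stops for futility when the predictive probability (PP) of eventual
#' success falls below `theta_L`, and for efficacy when PP rises above
#' `theta_U`. All comparisons are strict, so ties continue (interim) or fail
#' (final).
#'
#' The defaults are the monitored-trial parameters used throughout the
#' package's examples: reference rate 15%, a diffuse `Beta(0.05, 0.05)`
#' prior, final threshold 0.5, and interim thresholds 0.1 / 0.9, with
#' continuous monitoring (a look after every evaluable patient).
#'
#' @param p0 reference response proportion in `[0, 1)`; the posterior must
#'   beat this rate for the arm to succeed.
#' @param prior_a,prior_b positive Beta prior shape parameters.
#' @param theta_T final success threshold in `(0, 1)`.
#' @param theta_L interim futility threshold in `[0, 1)`; `0` disables
#'   futility stopping.
#' @param theta_U interim efficacy threshold in `(0, 1]`; `1` disables
#'   efficacy stopping.
#' @param n_max planned maximum number of evaluable patients.
#' @param monitor_start first evaluable-patient count at which an interim
#'   decision applies.
#' @param monitor_step number of evaluable patients between interim looks.
#' @return An object of class `ppd_design` (a validated list of the above).
#' @examples
#' des <- ppd_design(n_max = 20)
#' posterior_exceedance(3, 10, des)
#' predictive_probability(3, 10, des)
#' @export
ppd_design <- function(p0 = 0.15, prior_a = 0.05, prior_b = 0.05,
                       theta_T = 0.5, theta_L = 0.1, theta_U = 0.9,
                       n_max = 20L, monitor_start = 1L, monitor_step = 1L) {
  num1 <- function(z, nm) {
    if (!is.numeric(z) || length(z) != 1L || !is.finite(z))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    as.numeric(z)
  }
  p0 <- num1(p0, "p0"); prior_a <- num1(prior_a, "prior_a")
  prior_b <- num1(prior_b, "prior_b"); theta_T <- num1(theta_T, "theta_T")
  theta_L <- num1(theta_L, "theta_L"); theta_U <- num1(theta_U, "theta_U")
  if (p0 < 0 || p0 >= 1) stop("config error: 'p0' must lie in [0, 1)", call. = FALSE)
  if (prior_a <= 0 || prior_b <= 0)
    stop("config error: prior shapes must be positive", call. = FALSE)
  if (theta_T <= 0 || theta_T >= 1)
    stop("config error: 'theta_T' must lie in (0, 1)", call. = FALSE)
  if (theta_L < 0 || theta_L >= 1 || theta_U <= 0 || theta_U > 1 ||
      theta_L >= theta_U)
    stop("config error: need 0 <= theta_L < theta_U <= 1", call. = FALSE)
  n_max <- as.integer(num1(n_max, "n_max"))
  monitor_start <- as.integer(num1(monitor_start, "monitor_start"))
  monitor_step <- as.integer(num1(monitor_step, "monitor_step"))
  if (n_max < 1L) stop("config error: 'n_max' must be a positive integer", call. = FALSE)
  if (monitor_start < 1L || monitor_step < 1L)
    stop("config error: monitoring schedule entries must be positive integers", call. = FALSE)
  if (monitor_start > n_max)
    stop("config error: 'monitor_start' must not exceed 'n_max'", call. = FALSE)
  structure(list(p0 = p0, prior_a = prior_a, prior_b = prior_b,
                 theta_T = theta_T, theta_L = theta_L, theta_U = theta_U,
                 n_max = n_max, monitor_start = monitor_start,
                 monitor_step = monitor_step),
            class = "ppd_design")
}

#' @export
print.ppd_design <- function(x, ...) {
  cat("Bayesian predictive-probability design\n")
  cat(sprintf("  reference rate p0 = %g, prior Beta(%g, %g)\n",
              x$p0, x$prior_a, x$prior_b))
  cat(sprintf("  thresholds: final theta_T = %g, futility theta_L = %g, efficacy theta_U = %g\n",
              x$theta_T, x$theta_L, x$theta_U))
  cat(sprintf("  n_max = %d, interim looks at n = %s\n", x$n_max,
              paste(utils::head(monitor_looks(x), 8L), collapse = ", ")))
  invisible(x)
}

stopifnot_design <- function(design) {
  if (!inherits(design, "ppd_design"))
    stop("'design' must be a 'ppd_design' object", call. = FALSE)
  design
}

check_xn <- function(x, n) {
  if (any(!is.finite(x)) || any(!is.finite(n)) || any(x < 0) || any(n < 0) ||
      any(x != floor(x)) || any(n != floor(n)))
    stop("domain error: 'x' and 'n' must be nonnegative integers", call. = FALSE)
  if (any(x > n))
    stop("domain error: responder count 'x' cannot exceed sample size 'n'", call. = FALSE)
}

#' Interim look schedule of a design
#'
#' Evaluable-patient counts at which an interim decision is taken; the final
#' analysis at `n_max` is governed by the final rule, not the interim rule,
#' and is excluded.
#'
#' @param design a [ppd_design()] object.
#' @param n_max maximum evaluable size; defaults to the design's, and can be
#'   raised after an arm expansion.
#' @return Integer vector of interim look sizes (possibly empty).
#' @export
monitor_looks <- function(design, n_max = design$n_max) {
  stopifnot_design(design)
  looks <- seq.int(design$monitor_start, n_max, by = design$monitor_step)
  looks[looks < n_max]
}

#' Posterior probability that the response rate beats the reference
#'
#' With a `Beta(prior_a, prior_b)` prior and `x` responders among `n`,
#' returns `P(p > p0 | x, n)`, i.e. one minus the regularized incomplete
#' beta function at `p0` with posterior shapes `(prior_a + x, prior_b + n - x)`.
#'
#' @param x responder count(s), `0 <= x <= n`.
#' @param n evaluable sample size.
#' @param design a [ppd_design()] object supplying prior and `p0`.
#' @return Probability in `[0, 1]`, vectorized over `x`.
#' @export
posterior_exceedance <- function(x, n, design) {
  stopifnot_design(design)
  check_xn(x, n)
  stats::pbeta(design$p0, design$prior_a + x, design$prior_b + n - x,
               lower.tail = FALSE)
}

#' Beta-binomial predictive distribution over future responders
#'
#' The posterior predictive pmf of the number of responders `Y` among `m`
#' future patients given `x` responders in `n` so far:
#' `P(Y = y) = C(m, y) B(a + x + y, b + n - x + m - y) / B(a + x, b + n - x)`.
#' Computed in log-beta arithmetic to avoid overflow.
#'
#' @inheritParams posterior_exceedance
#' @param m number of future patients (`m >= 0`).
#' @return Named numeric vector of length `m + 1` (names `0:m`) summing to 1.
#' @export
beta_binomial_predictive <- function(x, n, m, design) {
  stopifnot_design(design)
  check_xn(x, n)
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0 || m != floor(m))
    stop("domain error: 'm' must be a nonnegative integer", call. = FALSE)
  a <- design$prior_a + x
  b <- design$prior_b + n - x
  y <- 0:m
  lp <- lchoose(m, y) + lbeta(a + y, b + m - y) - lbeta(a, b)
  stats::setNames(exp(lp), y)
}

#' Smallest responder count declaring final success
#'
#' The smallest `x` for which the posterior exceedance at `n_final` patients
#' is strictly greater than `theta_T`; `NA` when even `x = n_final` fails
#' (success unattainable at that size).
#'
#' @param n_final final evaluable sample size (`>= 1`).
#' @param design a [ppd_design()] object.
#' @return Integer cutoff in `0:n_final`, or `NA_integer_`.
#' @export
final_success_cutoff <- function(n_final, design) {
  stopifnot_design(design)
  if (!is.numeric(n_final) || length(n_final) != 1L || n_final < 1 ||
      n_final != floor(n_final))
    stop("domain error: 'n_final' must be a positive integer", call. = FALSE)
  x <- 0:n_final
  ok <- posterior_exceedance(x, n_final, design) > design$theta_T
  if (!any(ok)) return(NA_integer_)
  as.integer(x[which(ok)[1L]])
}

#' Predictive probability of eventual trial success
#'
#' The probability, under the current posterior, that the arm will meet its
#' final success criterion once `n_max` evaluable patients are observed:
#' `PP = sum_y P(Y = y) 1[P(p > p0 | x + y, n_max) > theta_T]` with `Y` the
#' beta-binomial count of responders among the `n_max - n` remaining
#' patients. At `n = n_max` this is exactly the final rule, so PP is 0 or 1.
#'
#' @inheritParams posterior_exceedance
#' @param n_max horizon for the computation; defaults to the design's and can
#'   be raised after an arm expansion.
#' @return Probability in `[0, 1]`.
#' @export
predictive_probability <- function(x, n, design, n_max = design$n_max) {
  stopifnot_design(design)
  check_xn(x, n)
  if (n > n_max)
    stop("domain error: 'n' exceeds the maximum sample size", call. = FALSE)
  cut <- final_success_cutoff(n_max, design)
  if (is.na(cut)) return(0)
  m <- n_max - n
  pmf <- beta_binomial_predictive(x, n, m, design)
  y <- 0:m
  min(1, max(0, sum(pmf[x + y >= cut])))
}

#' Interim stop/continue decision
#'
#' Applies the interim rule at a look with `n < n_max` evaluable patients:
#' stop for futility when `PP < theta_L`, stop for efficacy when
#' `PP > theta_U`, otherwise continue. Both inequalities are strict, so a PP
#' exactly on a threshold continues. Whether `n` is on the monitoring
#' schedule is the caller's concern (see [monitor_looks()]).
#'
#' @inheritParams predictive_probability
#' @return One of `"continue"`, `"stop_futility"`, `"stop_efficacy"`, with
#'   the predictive probability attached as attribute `"pp"`.
#' @export
interim_decision <- function(x, n, design, n_max = design$n_max) {
  stopifnot_design(design)
  if (n >= n_max)
    stop("final analysis reached: apply the final success rule, not the interim rule",
         call. = FALSE)
  pp <- predictive_probability(x, n, design, n_max = n_max)
  action <- if (pp < design$theta_L) "stop_futility"
            else if (pp > design$theta_U) "stop_efficacy"
            else "continue"
  structure(action, pp = pp)
}

#' Futility and efficacy stopping boundaries
#'
#' Tabulates, for every monitored interim size and for the final analysis,
#' the responder-count cutoffs implied by the predictive-probability rule:
#' `futility_cutoff` is the largest `x` with `PP(x, n) < theta_L` (`NA` when
#' no count is futile) and `efficacy_cutoff` the smallest `x` with
#' `PP(x, n) > theta_U` (`NA` when unreachable). The row at `n = n_max`
#' carries the final rule, for which PP is 0/1, so its efficacy cutoff is the
#' final success cutoff. Because PP is nondecreasing in `x` at fixed `n`,
#' each cutoff is found by bisection-free threshold scan.
#'
#' @inheritParams predictive_probability
#' @return A data frame of class `ppd_boundaries` with columns `n`,
#'   `futility_cutoff`, `efficacy_cutoff`, `final` (logical).
#' @export
stopping_boundaries <- function(design, n_max = design$n_max) {
  stopifnot_design(design)
  looks <- monitor_looks(design, n_max)
  rows <- lapply(looks, function(n) {
    pp <- vapply(0:n, predictive_probability, numeric(1L),
                 n = n, design = design, n_max = n_max)
    fut <- which(pp < design$theta_L)
    eff <- which(pp > design$theta_U)
    data.frame(n = n,
               futility_cutoff = if (length(fut)) max(fut) - 1L else NA_integer_,
               efficacy_cutoff = if (length(eff)) min(eff) - 1L else NA_integer_,
               final = FALSE)
  })
  cut <- final_success_cutoff(n_max, design)
  rows[[length(rows) + 1L]] <- data.frame(
    n = n_max,
    futility_cutoff = if (is.na(cut)) n_max else cut - 1L,
    efficacy_cutoff = if (is.na(cut)) NA_integer_ else cut,
    final = TRUE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ppd_boundaries", "data.frame")
  out
}

#' Inflate an evaluable sample size for anticipated dropout
#'
#' Number of patients to enroll so that, after a fraction `dropout_rate`
#' drop out before becoming evaluable, `n_evaluable` remain:
#' `ceiling(n_evaluable / (1 - dropout_rate))`.
#'
#' @param n_evaluable required number of evaluable patients.
#' @param dropout_rate anticipated dropout proportion in `[0, 1)`.
#' @return Integer enrollment target.
#' @examples
#' inflate_for_dropout(41, 0.10)  # 46
#' @export
inflate_for_dropout <- function(n_evaluable, dropout_rate) {
  if (!is.numeric(n_evaluable) || length(n_evaluable) != 1L ||
      n_evaluable < 0 || n_evaluable != floor(n_evaluable))
    stop("domain error: 'n_evaluable' must be a nonnegative integer", call. = FALSE)
  if (!is.numeric(dropout_rate) || length(dropout_rate) != 1L ||
      dropout_rate < 0 || dropout_rate >= 1)
    stop("domain error: 'dropout_rate' must lie in [0, 1)", call. = FALSE)
  as.integer(ceiling(n_evaluable / (1 - dropout_rate)))
}
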
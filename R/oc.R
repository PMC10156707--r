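#' Operating characteristics of a predictive-probability design
#'
#' Probability of stopping early for futility, probability of declaring
#' efficacy (early stop or final success), expected evaluable sample size and
#' the distribution of the stopping size, under an assumed true response
#' probability.
#'
#' `mode = "exact"` propagates the Markov chain over states `(n, x)` through
#' every interim look, pruning mass absorbed by the stopping boundaries, and
#' is exact up to floating point. `mode = "mc"` simulates patient-by-patient
#' Bernoulli accrual through the same boundary table; the two agree within
#' Monte-Carlo error and are cross-checked against each other in the test
#' suite.
#'
#' @param design a [ppd_design()] object.
#' @param true_p assumed true response probability in `[0, 1]`.
#' @param mode `"exact"` (state-space recursion) or `"mc"` (simulation).
#' @param n_sims number of simulated trials when `mode = "mc"`.
#' @param seed optional RNG seed used only in `"mc"` mode.
#' @param n_max horizon; defaults to the design's.
#' @return An object of class `ppd_oc`: list with `true_p`,
#'   `prob_early_futility`, `prob_early_efficacy`, `prob_declare_efficacy`
#'   (early efficacy + final success), `prob_failure`, `expected_n`, and
#'   `final_n_distribution` (named probability vector over stopping sizes).
#' @export
operating_characteristics <- function(design, true_p,
                                      mode = c("exact", "mc"),
                                      n_sims = 10000L, seed = NULL,
                                      n_max = design$n_max) {
  stopifnot_design(design)
  mode <- match.arg(mode)
  if (!is.numeric(true_p) || length(true_p) != 1L || !is.finite(true_p) ||
      true_p < 0 || true_p > 1)
    stop("domain error: 'true_p' must lie in [0, 1]", call. = FALSE)
  bounds <- stopping_boundaries(design, n_max)
  if (mode == "exact") {
    oc_exact(design, true_p, bounds, n_max)
  } else {
    oc_mc(design, true_p, bounds, n_max, n_sims = n_sims, seed = seed)
  }
}

# decision lookup against a boundary table row: -1 futility, +1 efficacy, 0 continue
boundary_action <- function(x, row) {
  fut <- row$futility_cutoff
  eff <- row$efficacy_cutoff
  ifelse(!is.na(fut) & x <= fut, -1L,
         ifelse(!is.na(eff) & x >= eff, 1L, 0L))
}

oc_exact <- function(design, true_p, bounds, n_max) {
  interim <- bounds[!bounds$final, , drop = FALSE]
  # open[k] = P(still monitoring with x = k - 1 responders)
  open <- 1
  stops <- list()  # per stopping size: c(fut = , eff = )
  final_success <- 0; final_failure <- 0
  for (n in seq_len(n_max)) {
    open <- c(open * (1 - true_p), 0) + c(0, open * true_p)
    row <- interim[interim$n == n, , drop = FALSE]
    if (nrow(row) == 1L) {
      act <- boundary_action(0:n, row)
      p_fut <- sum(open[act == -1L]); p_eff <- sum(open[act == 1L])
      if (p_fut > 0 || p_eff > 0) {
        stops[[as.character(n)]] <- c(fut = p_fut, eff = p_eff)
        open[act != 0L] <- 0
      }
    }
  }
  cut <- final_success_cutoff(n_max, design)
  x <- 0:n_max
  final_success <- if (is.na(cut)) 0 else sum(open[x >= cut])
  final_failure <- sum(open) - final_success
  build_oc(true_p, stops, final_success, final_failure, n_max,
           mode = "exact", n_sims = NA_integer_)
}

oc_mc <- function(design, true_p, bounds, n_max, n_sims, seed) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  interim <- bounds[!bounds$final, , drop = FALSE]
  resp <- matrix(stats::rbinom(n_sims * n_max, 1L, true_p), nrow = n_sims)
  cum <- t(apply(resp, 1L, cumsum))
  active <- rep(TRUE, n_sims)
  stop_n <- rep(n_max, n_sims)
  outcome <- rep(NA_character_, n_sims)
  for (i in seq_len(nrow(interim))) {
    row <- interim[i, , drop = FALSE]
    n <- row$n
    act <- boundary_action(cum[, n], row)
    hit <- active & act != 0L
    if (any(hit)) {
      stop_n[hit] <- n
      outcome[hit] <- ifelse(act[hit] == -1L, "early_futility", "early_efficacy")
      active[hit] <- FALSE
    }
  }
  cut <- final_success_cutoff(n_max, design)
  fin <- active
  outcome[fin] <- ifelse(!is.na(cut) & cum[fin, n_max] >= cut,
                         "final_success", "final_failure")
  stops <- list()
  for (n in sort(unique(stop_n[stop_n < n_max]))) {
    stops[[as.character(n)]] <- c(
      fut = mean(stop_n == n & outcome == "early_futility"),
      eff = mean(stop_n == n & outcome == "early_efficacy"))
  }
  build_oc(true_p, stops,
           mean(outcome == "final_success"), mean(outcome == "final_failure"),
           n_max, mode = "mc", n_sims = n_sims)
}

build_oc <- function(true_p, stops, final_success, final_failure, n_max,
                     mode, n_sims) {
  early_fut <- sum(vapply(stops, `[[`, numeric(1L), "fut"))
  early_eff <- sum(vapply(stops, `[[`, numeric(1L), "eff"))
  sizes <- as.integer(names(stops))
  dist <- vapply(stops, sum, numeric(1L))
  final_mass <- final_success + final_failure
  dist <- c(dist, stats::setNames(final_mass, as.character(n_max)))
  dist <- dist[dist > 0]
  dist <- dist[order(as.integer(names(dist)))]
  structure(list(
    true_p = true_p,
    prob_early_futility = early_fut,
    prob_early_efficacy = early_eff,
    prob_declare_efficacy = early_eff + final_success,
    prob_failure = early_fut + final_failure,
    expected_n = sum(as.integer(names(dist)) * dist),
    final_n_distribution = dist,
    mode = mode, n_sims = n_sims), class = "ppd_oc")
}

#' @export
print.ppd_oc <- function(x, ...) {
  cat(sprintf("Operating characteristics (%s) at true p = %g\n", x$mode, x$true_p))
  cat(sprintf("  P(early futility stop) = %.4f\n", x$prob_early_futility))
  cat(sprintf("  P(declare efficacy)    = %.4f\n", x$prob_declare_efficacy))
  cat(sprintf("  expected evaluable n   = %.2f\n", x$expected_n))
  invisible(x)
}

#' Operating-characteristic grid over true response rates
#'
#' Convenience wrapper evaluating [operating_characteristics()] over a grid
#' of assumed true response probabilities.
#'
#' @inheritParams operating_characteristics
#' @param true_p_grid numeric vector of true response probabilities.
#' @return A data frame with one row per `true_p`.
#' @export
oc_grid <- function(design, true_p_grid, mode = c("exact", "mc"),
                    n_sims = 10000L, seed = NULL, n_max = design$n_max) {
  mode <- match.arg(mode)
  rows <- lapply(seq_along(true_p_grid), function(i) {
    oc <- operating_characteristics(design, true_p_grid[i], mode = mode,
                                    n_sims = n_sims,
                                    seed = if (is.null(seed)) NULL else seed + i,
                                    n_max = n_max)
    data.frame(true_p = oc$true_p,
               prob_early_futility = oc$prob_early_futility,
               prob_early_efficacy = oc$prob_early_efficacy,
               prob_declare_efficacy = oc$prob_declare_efficacy,
               prob_failure = oc$prob_failure,
               expected_n = oc$expected_n)
  })
  do.call(rbind, rows)
}
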
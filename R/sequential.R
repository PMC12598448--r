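#' Sequential Bayes-factor monitoring
#'
#' Recomputes a Bayes factor as subjects accrue, starting at the
#' preregistered minimum sample size, and stops at the first crossing of the
#' evidence bounds: BF10 >= `upper` concludes support for H1, BF10 <=
#' `lower` support for H0. Crossings that would occur before `n_min` are
#' never acted on because monitoring only starts there; if the stream is
#' exhausted without a crossing the decision is `undecided`.
#'
#' @param subject_values numeric vector in order of accrual (one value per
#'   subject, e.g. subject-level DLS).
#' @param test function mapping a numeric vector to a `bayes_result` (or any
#'   list with a `bf10` element); default directed JZS test.
#' @param n_min minimum sample size before monitoring starts (default 30).
#' @param upper,lower stopping bounds (defaults 3 and 1/3).
#' @return An object of class `sequential_decision`: `bf_path` (tibble of n
#'   and BF10), `stop_n`, `outcome` (`support_h1`, `support_h0`,
#'   `undecided`), the bounds and `n_min`.
#' @export
sequential_monitor <- function(subject_values,
                               test = function(v) jzs_bf_one_sample(v, "greater"),
                               n_min = 30, upper = 3, lower = 1 / 3) {
  n_total <- length(subject_values)
  path_n <- integer(0); path_bf <- numeric(0)
  outcome <- "undecided"
  stop_n <- NA_integer_
  if (n_total < n_min) {
    # stream exhausted before monitoring could start: report the BF at the
    # available n (when computable) and stay undecided
    if (n_total >= 2) {
      bf <- test(subject_values)$bf10
      path_n <- n_total; path_bf <- bf
    }
  } else {
    for (n in seq(n_min, n_total)) {
      bf <- test(subject_values[seq_len(n)])$bf10
      path_n <- c(path_n, n); path_bf <- c(path_bf, bf)
      if (bf >= upper) { outcome <- "support_h1"; stop_n <- n; break }
      if (bf <= lower) { outcome <- "support_h0"; stop_n <- n; break }
    }
  }
  structure(
    list(bf_path = tibble::tibble(n = path_n, bf10 = path_bf),
         stop_n = stop_n, outcome = outcome,
         upper = upper, lower = lower, n_min = n_min),
    class = "sequential_decision"
  )
}

#' @export
print.sequential_decision <- function(x, ...) {
  last <- if (nrow(x$bf_path)) x$bf_path$bf10[nrow(x$bf_path)] else NA_real_
  cat(sprintf(
    "<sequential_decision> %s at n = %s (bounds %g / %g, n_min %d, last BF10 = %.3g)\n",
    x$outcome, ifelse(is.na(x$stop_n), "-", x$stop_n), x$upper, x$lower,
    x$n_min, last))
  invisible(x)
}

#' Operating characteristics of a sequential Bayesian design
#'
#' Monte-Carlo calibration of the sequential stopping rule: simulated
#' cohorts are streamed through [sequential_monitor()] and the probabilities
#' of concluding for H1 / H0 / remaining undecided are estimated, together
#' with the mean stopping sample size. The default generator draws
#' `n_max` standard-normal subjects shifted by `effect_size` (i.e. the
#' standardized effect).
#'
#' @param effect_size true standardized effect of the simulated cohorts.
#' @param n_min,n_max monitoring start and maximum sample size.
#' @param upper,lower stopping bounds.
#' @param reps number of simulated cohorts (>= 1).
#' @param seed integer seed; the run is reproducible.
#' @param generator function `(n, effect_size)` returning one cohort;
#'   default `rnorm(n, effect_size, 1)`.
#' @param test passed to [sequential_monitor()].
#' @return List: `p_support_h1`, `p_support_h0`, `p_undecided`,
#'   `mean_stop_n` (bound crossings only, `NA` if none), `reps`.
#' @export
design_simulation <- function(effect_size, n_min = 30, n_max = 60,
                              upper = 3, lower = 1 / 3, reps = 100, seed = 1,
                              generator = function(n, es) rnorm(n, es, 1),
                              test = function(v) jzs_bf_one_sample(v, "greater")) {
  stopifnot(reps >= 1)
  res <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      cohort <- generator(n_max, effect_size)
      dec <- sequential_monitor(cohort, test = test, n_min = n_min,
                                upper = upper, lower = lower)
      c(h1 = dec$outcome == "support_h1",
        h0 = dec$outcome == "support_h0",
        stop_n = if (is.na(dec$stop_n)) NA_real_ else dec$stop_n)
    }, numeric(3))
  })
  stops <- res["stop_n", ]
  list(
    p_support_h1 = mean(res["h1", ]),
    p_support_h0 = mean(res["h0", ]),
    p_undecided = 1 - mean(res["h1", ]) - mean(res["h0", ]),
    mean_stop_n = if (all(is.na(stops))) NA_real_ else mean(stops, na.rm = TRUE),
    reps = reps
  )
}
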
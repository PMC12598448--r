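# Independent oracles and fixture builders. These deliberately recompute
# everything from scratch (naive window evaluation, fine-grid quadrature,
# all-pairs counting) so they share no code path with the implementations
# they check.

# Brute-force dispersion-duration fixation finder: every candidate window is
# evaluated from scratch (mean + all distances), growing from each start to
# the first failing extension, with the same greedy left-to-right selection.
oracle_fixations <- function(samples, r = 25, min_dur = 200, max_gap = 2) {
  t <- samples$t_ms; x <- samples$x_px; y <- samples$y_px
  valid <- samples$valid & !is.na(x) & !is.na(y)
  n <- nrow(samples)
  window_ok <- function(i, j) {
    vv <- (i:j)[valid[i:j]]
    cx <- mean(x[vv]); cy <- mean(y[vv])
    all(sqrt((x[vv] - cx)^2 + (y[vv] - cy)^2) <= r)
  }
  rows <- list()
  i <- 1L
  while (i <= n) {
    if (!valid[i]) { i <- i + 1L; next }
    j <- i
    repeat {
      nxt <- j + 1L
      gap <- 0L
      while (nxt <= n && !valid[nxt]) { gap <- gap + 1L; nxt <- nxt + 1L }
      if (nxt > n || gap > max_gap) break
      if (window_ok(i, nxt)) j <- nxt else break
    }
    if (t[j] - t[i] > min_dur) {
      vv <- (i:j)[valid[i:j]]
      rows[[length(rows) + 1]] <- data.frame(
        onset_ms = t[i], offset_ms = t[j], duration_ms = t[j] - t[i],
        x = mean(x[vv]), y = mean(y[vv]), n_samples = length(vv))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(rows)) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), x = numeric(0),
                      y = numeric(0), n_samples = integer(0)))
  }
  do.call(rbind, rows)
}

# Fine-grid trapezoid quadrature for the default-prior one-sample BF.
oracle_jzs <- function(values, direction = "two_sided", r = 0.707,
                       n_grid = 200001) {
  n <- length(values)
  tstat <- mean(values) / (sd(values) / sqrt(n))
  nu <- n - 1
  half <- abs(tstat) / sqrt(n) + 15 / sqrt(n) + 30 * r
  lo <- if (direction == "greater") 0 else -half
  hi <- if (direction == "less") 0 else half
  grid <- seq(lo, hi, length.out = n_grid)
  prior <- dcauchy(grid, 0, r)
  if (direction != "two_sided") prior <- 2 * prior
  f <- suppressWarnings(dt(tstat, nu, ncp = grid * sqrt(n))) * prior
  h <- grid[2] - grid[1]
  m1 <- h * (sum(f) - (f[1] + f[length(f)]) / 2)
  m1 / dt(tstat, nu)
}

# All-pairs tau-b with tie correction.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Regular 120 Hz sample grid of a given duration.
sample_times <- function(duration_ms, rate_hz = 120) {
  dt <- 1000 / rate_hz
  seq(0, duration_ms - dt / 2, by = dt)
}

# Trace of a constant gaze point.
constant_trace <- function(x, y, duration_ms, t0 = 0, rate_hz = 120) {
  t <- t0 + sample_times(duration_ms, rate_hz)
  tibble::tibble(t_ms = t, x_px = x, y_px = y, valid = TRUE)
}

# Bounded random-walk trace: jumps between dwell clusters, the regime the
# detector is built for, plus occasional dropouts.
random_walk_trace <- function(n_samples, seed, screen_w = 1920,
                              screen_h = 1080, rate_hz = 120) {
  set.seed(seed)
  t <- sample_times(n_samples * 1000 / rate_hz, rate_hz)[seq_len(n_samples)]
  x <- numeric(n_samples); y <- numeric(n_samples)
  cx <- runif(1, 100, screen_w - 100); cy <- runif(1, 100, screen_h - 100)
  for (i in seq_len(n_samples)) {
    if (runif(1) < 0.02) {  # saccade to a new cluster
      cx <- runif(1, 100, screen_w - 100); cy <- runif(1, 100, screen_h - 100)
    }
    x[i] <- cx + rnorm(1, 0, 8)
    y[i] <- cy + rnorm(1, 0, 8)
  }
  tibble::tibble(t_ms = t, x_px = x, y_px = y,
                 valid = runif(n_samples) >= 0.05)
}

# Hand-built fixation table (already-detected fixations for DLS tests).
make_fix <- function(onset, offset, x, y) {
  tibble::tibble(onset_ms = onset, offset_ms = offset,
                 duration_ms = offset - onset, x = x, y = y,
                 n_samples = rep(10L, length(onset)))
}

# Minimal trial-metrics row for exclusion-rule tests.
metrics_row <- function(look_baseline = 2000, look_contingent = 15000,
                        look_disruption = 2000, n_fix_disruption = 3,
                        uncovered_fraction = 0.1, end_reason = "timeout") {
  tibble::tibble(
    participant_id = "s001", trial_id = "t01", age_days = 261L,
    condition = "drop",
    look_baseline_ms = look_baseline, look_contingent_ms = look_contingent,
    look_disruption_ms = look_disruption,
    dls_baseline = 0.1, dls_contingent = 0.1, dls_disruption = 0.1,
    dls_contingent_first_half = 0.1, dls_contingent_second_half = 0.1,
    dls_disruption_exploratory = 0.1,
    n_fix_disruption = n_fix_disruption,
    uncovered_fraction = uncovered_fraction, end_reason = end_reason)
}
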
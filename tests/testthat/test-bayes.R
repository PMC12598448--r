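test_that("null-centered data cannot favor H1 under the default prior", {
  x <- rep(c(-1, 1), length.out = 45) + rep(c(-0.01, 0.01), length.out = 45)
  x <- x - mean(x)                     # t statistic exactly 0 at n = 45
  b <- jzs_bf_one_sample(x, "two_sided")
  expect_equal(b$statistic, 0)
  expect_lt(b$bf10, 1)
})

test_that("JZS BF matches an independent fine-grid quadrature oracle", {
  # fixtures: null cohorts (any direction) and d = 1 effects tested in the
  # hypothesized direction, the regimes the pipeline's tests live in
  set.seed(101)
  dirs <- c("two_sided", "greater", "less")
  for (i in 1:20) {
    n <- sample(10:60, 1)
    d <- if (i %% 2 == 0) 1 else 0
    x <- rnorm(n, d, 1)
    dir <- if (d == 1) { if (i %% 4 == 0) "greater" else "two_sided" }
           else dirs[(i %% 3) + 1]
    got <- jzs_bf_one_sample(x, dir)$bf10
    want <- oracle_jzs(x, dir)
    expect_lt(abs(got - want) / want, 1e-4)
  }
})

test_that("JZS BF input validation and monotonicity in the t statistic", {
  expect_error(jzs_bf_one_sample(rep(0.3, 10)), "variance")
  expect_error(jzs_bf_one_sample(c(1, 1) - c(1, 1)), "variance")
  expect_error(jzs_bf_one_sample(0.5), "at least 2")

  # directed BF increases with the (standardized) sample mean at fixed n
  base <- seq(-0.5, 0.5, length.out = 20)
  base <- base / sd(base)
  bfs <- vapply(c(-0.5, 0, 0.4, 0.8, 1.5),
                function(m) jzs_bf_one_sample(base + m, "greater")$bf10,
                numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("rank-based BF is seeded, calibrated, and reports convergence", {
  # same seed -> identical result
  set.seed(5); x <- rnorm(45, 0.4, 1)
  b1 <- rank_bf_one_sample(x, "greater", n_mcmc = 1500, burn_in = 300, seed = 9)
  b2 <- rank_bf_one_sample(x, "greater", n_mcmc = 1500, burn_in = 300, seed = 9)
  expect_identical(b1$bf10, b2$bf10)
  expect_true(is.finite(b1$rhat))

  # strongly positive sample: overwhelming evidence. With not a single
  # negative value the rank likelihood barely anchors the effect scale, the
  # sampler random-walks, and the result must be flagged, never silent.
  y <- abs(rnorm(45)) + 0.5
  expect_warning(
    b <- rank_bf_one_sample(y, "greater", n_mcmc = 1500, burn_in = 300,
                            seed = 2),
    "converge")
  expect_gt(b$bf10, 100)
  expect_false(b$converged)

  # symmetric-about-zero samples: evidence should lean to the null
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    z <- rnorm(45, 0, 1); z <- c(z, -z)[1:45]; z <- z - median(z)
    b <- rank_bf_one_sample(z, "two_sided", n_mcmc = 800, burn_in = 200,
                            seed = s)
    hits <- hits + (b$bf10 < 1)
  }
  expect_gte(hits, 19)

  expect_error(rank_bf_one_sample(c(1, 2, 3)), "at least 5")
})

test_that("tau-b handles perfect association, reversal, and ties", {
  expect_equal(kendall_tau_b(1:10, 2 * (1:10) + 3), 1)
  expect_equal(kendall_tau_b(1:10, rev(1:10)), -1)
  x <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7, 8, 8)
  y <- c(2, 1, 3, 3, 5, 4, 6, 5, 8, 7, 9, 9)
  expect_equal(kendall_tau_b(x, y), oracle_tau_b(x, y))
  set.seed(3)
  for (i in 1:5) {
    a <- sample(1:6, 15, replace = TRUE)
    b <- sample(1:6, 15, replace = TRUE)
    expect_equal(kendall_tau_b(a, b), oracle_tau_b(a, b))
  }
  expect_error(kendall_tau_b(1:5, 1:4), "equal length")
})

test_that("tau Bayes factor behaves at the null and under monotone signal", {
  # near-null association at n = 45: density ratio at the null peak favors H0
  xx <- 1:45
  yy <- as.vector(rbind(seq(1, 23), c(seq(45, 24), NA)))[1:45]
  # ^ interleaving a rising and a falling run balances concordances
  tau <- kendall_tau_b(xx, yy)
  expect_lt(abs(tau), 0.06)
  expect_lt(kendall_tau_bf(xx, yy)$bf10, 1)

  # monotone association at n = 45: strong evidence
  xm <- rnorm(45)
  bm <- kendall_tau_bf(xm, exp(xm), direction = "greater")
  expect_equal(bm$statistic, 1)
  expect_gt(bm$bf10, 10)

  expect_error(kendall_tau_bf(rep(1, 10), 1:10), "constant")
})

test_that("simulated null tau data give median BF below 1", {
  set.seed(77)
  bfs <- replicate(300, {
    kendall_tau_bf(rnorm(45), rnorm(45))$bf10
  })
  expect_lt(median(bfs), 1)
})

test_that("evidence classification partitions the BF scale", {
  expect_equal(classify_bf(2), "anecdotal_h1")
  expect_equal(classify_bf(0.2), "moderate_h0")
  expect_equal(classify_bf(150), "extreme_h1")
  expect_equal(classify_bf(c(5, 15, 50, 1 / 5, 1 / 15, 1 / 50, 1 / 500)),
               c("moderate_h1", "strong_h1", "very_strong_h1",
                 "moderate_h0", "strong_h0", "very_strong_h0", "extreme_h0"))
  # no gaps or overlaps across a log-spaced sweep
  sweep <- 10^seq(-3, 3, length.out = 601)
  labs <- classify_bf(sweep)
  expect_true(all(nchar(labs) > 0))
  expect_equal(length(unique(labs)), 10)
  expect_error(classify_bf(0), "positive")
  expect_error(classify_bf(-2), "positive")
})
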
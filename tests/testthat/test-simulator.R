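spec1 <- generate_stimulus_set(2, 2, seed = 1, screen_w = 250, screen_h = 250)[1, ]

test_that("a fully invalid recording yields a maximum-length 43 s trial", {
  s <- constant_trace(10, 10, 43000)
  s$valid <- FALSE
  rec <- new_gaze_recording("s1", "t1", 200, s)
  tr <- simulate_trial(rec, spec1)
  expect_equal(tr$uncovered_fraction, 0)
  expect_equal(tr$end_reason, "timeout")
  expect_equal(tr$schedule$t_stop, 38000)
  expect_equal(tr$schedule$disruption_off, 43000)
  # phase durations 5000 / 3000 / <= 30000 / 5000
  expect_equal(tr$schedule$transition_on - tr$schedule$baseline_on, 5000)
  expect_equal(tr$schedule$contingent_on - tr$schedule$transition_on, 3000)
  expect_lte(tr$schedule$t_stop - tr$schedule$contingent_on, 30000)
  expect_equal(tr$schedule$disruption_off - tr$schedule$t_stop, 5000)
})

test_that("uncovering is idempotent: one point uncovers exactly one cell", {
  rec <- new_gaze_recording("s1", "t1", 200, constant_trace(30, 30, 43000))
  tr <- simulate_trial(rec, spec1)
  expect_equal(nrow(tr$uncover_events), 1)
  expect_equal(tr$uncovered_fraction, 25 * 25 / (250 * 250))
  expect_equal(tr$end_reason, "timeout")
})

test_that("gaze outside the contingent phase or screen never uncovers", {
  t <- c(1000, 6000, 42000)  # baseline, transition, disruption
  s <- tibble::tibble(t_ms = t, x_px = 30, y_px = 30, valid = TRUE)
  tr <- simulate_trial(new_gaze_recording("s", "t", 200, s), spec1)
  expect_equal(tr$uncovered_fraction, 0)

  s <- tibble::tibble(t_ms = c(9000, 9100), x_px = c(-5, 400), y_px = 30,
                      valid = TRUE)
  tr <- simulate_trial(new_gaze_recording("s", "t", 200, s), spec1)
  expect_equal(tr$uncovered_fraction, 0)
  expect_equal(tr$end_reason, "timeout")
})

test_that("raster-scan gaze stops at the fraction predicted by event replay", {
  # visit cell centers left-to-right, top-to-bottom, one per sample
  cx <- rep(seq(12.5, 237.5, by = 25), times = 10)
  cy <- rep(seq(12.5, 237.5, by = 25), each = 10)
  t <- 8000 + (seq_along(cx) - 1) * 25
  s <- tibble::tibble(t_ms = t, x_px = cx, y_px = cy, valid = TRUE)
  tr <- simulate_trial(new_gaze_recording("s", "t", 200, s), spec1)

  # step-through oracle: replay events, cumulating area until >= 20%
  seen <- character(0); frac <- 0; t_stop_oracle <- NA
  for (i in seq_along(t)) {
    key <- paste(floor(cx[i] / 25), floor(cy[i] / 25))
    if (!key %in% seen) {
      seen <- c(seen, key)
      frac <- frac + 25 * 25 / (250 * 250)
      if (frac >= 0.20) { t_stop_oracle <- t[i]; break }
    }
  }
  expect_equal(tr$end_reason, "fraction_reached")
  expect_equal(tr$schedule$t_stop, t_stop_oracle)
  expect_gte(tr$uncovered_fraction, 0.20)

  # stop-rule tightness: without the final event the fraction is below 20%
  n_ev <- nrow(tr$uncover_events)
  area <- 25 * 25 / (250 * 250)
  expect_lt((n_ev - 1) * area, 0.20)

  # monotonicity: cumulative uncovered fraction never decreases
  path <- cumsum(rep(area, n_ev))
  expect_true(all(diff(path) >= 0))
})

test_that("uncovered_fraction is area-weighted and exact on clean grids", {
  cov <- new_cover(250, 250, 25)
  expect_equal(uncovered_fraction(cov), 0)
  cov$grid[] <- FALSE
  expect_equal(uncovered_fraction(cov), 1)
  cov <- new_cover(250, 250, 25)
  cov$grid[1:2, 1:10] <- FALSE  # 20 of 100 equal cells
  expect_equal(uncovered_fraction(cov), 0.20)

  # ragged edge cells carry their true (smaller) area
  cov <- new_cover(110, 60, 25)   # 5x3 cells, last col 10 px, last row 10 px
  cov$grid[3, 5] <- FALSE
  expect_equal(uncovered_fraction(cov), (10 * 10) / (110 * 60))
})

test_that("visible object region is the uncovered-cell / object intersection", {
  spec <- generate_stimulus_set(2, 2, seed = 1)[1, ]  # 1920x1080, drop
  cov <- new_cover(1920, 1080, 25)
  expect_equal(visible_object_region(cov, spec)$area, 0)

  cov$grid[] <- FALSE
  obj <- object_rects(spec)
  total <- sum((obj$x1 - obj$x0) * (obj$y1 - obj$y0))
  expect_equal(visible_object_region(cov, spec)$area, total)

  # one cleared cell fully inside an object rectangle -> exactly one cell area
  cov <- new_cover(1920, 1080, 25)
  cell_x <- floor((obj$x0[1] + 40) / 25)
  cell_y <- floor((obj$y0[1] + 40) / 25)
  cov$grid[cell_y + 1, cell_x + 1] <- FALSE
  reg <- visible_object_region(cov, spec)
  expect_equal(reg$area, 25 * 25)
  expect_true(region_contains(reg, cell_x * 25 + 1, cell_y * 25 + 1))
  expect_false(region_contains(reg, obj$x0[1] - 5, obj$y0[1] - 5))
})
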
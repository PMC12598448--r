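lay50 <- build_aoi_layout(1000, 1000, 0.5, "drop")     # objects TL + BR

test_that("DLS endpoints and arithmetic match the definition", {
  # all looking inside object quadrants -> 1
  fx <- make_fix(c(0, 600), c(500, 1100), c(100, 900), c(100, 900))
  expect_equal(compute_dls(fx, lay50, 0, 2000), 1)

  # equal time in all four quadrants -> 0
  fx <- make_fix(c(0, 300, 600, 900), c(250, 550, 850, 1150),
                 c(100, 900, 100, 900), c(100, 100, 900, 900))
  expect_equal(compute_dls(fx, lay50, 0, 2000), 0)

  # 3 s object / 1 s non-object -> (3-1)/4 = 0.5
  fx <- make_fix(c(0, 4000), c(3000, 5000), c(100, 900), c(100, 100))
  expect_equal(compute_dls(fx, lay50, 0, 6000), 0.5)

  # exclusive non-object looking -> -1
  fx <- make_fix(0, 500, 900, 100)
  expect_equal(compute_dls(fx, lay50, 0, 1000), -1)

  # no on-screen looking in the window -> undefined
  expect_true(is.na(compute_dls(fx, lay50, 2000, 3000)))
  expect_true(is.na(compute_dls(make_fix(0, 500, -50, -50), lay50, 0, 1000)))
})

test_that("DLS is invariant to uniform rescaling of looking times", {
  fx <- make_fix(c(0, 1000, 2000), c(700, 1400, 2900),
                 c(100, 900, 900), c(100, 100, 900))
  base <- compute_dls(fx, lay50, 0, 3000)
  fx2 <- fx
  fx2$onset_ms <- fx$onset_ms * 3; fx2$offset_ms <- fx$offset_ms * 3
  fx2$duration_ms <- fx2$offset_ms - fx2$onset_ms
  expect_equal(compute_dls(fx2, lay50, 0, 9000), base)
})

test_that("uniform-by-area gaze calibrates to 2*fraction - 1", {
  lay <- build_aoi_layout(1920, 1080, 0.5572, "rise")
  set.seed(11)
  n <- 2000
  fx <- make_fix(seq(0, by = 400, length.out = n),
                 seq(300, by = 400, length.out = n),
                 runif(n, 0, 1920), runif(n, 0, 1080))
  got <- compute_dls(fx, lay, 0, max(fx$offset_ms))
  se <- sqrt(0.5572 * (1 - 0.5572) / n) * 2
  expect_lt(abs(got - (2 * 0.5572 - 1)), 3 * se)
})

test_that("exploratory DLS removes visible-part looking from the numerator", {
  spec <- generate_stimulus_set(2, 2, seed = 1)[1, ]  # 1920x1080 drop
  lay <- layout_for_stimulus(spec)
  obj <- object_rects(spec)

  # fully covered objects: exploratory DLS equals the standard DLS
  cov <- new_cover(1920, 1080, 25)
  vis <- visible_object_region(cov, spec)
  fx <- make_fix(c(0, 1000), c(800, 1500), c(obj$x0[1] + 10, 1800),
                 c(obj$y0[1] + 10, 100))
  expect_equal(exploratory_dls(fx, lay, 0, 2000, vis),
               compute_dls(fx, lay, 0, 2000))

  # all object-AOI fixations on visible parts: numerator loses T_obj entirely
  cov$grid[] <- FALSE
  vis_all <- visible_object_region(cov, spec)
  t_obj <- 800; t_non <- 500
  expect_equal(exploratory_dls(fx, lay, 0, 2000, vis_all),
               -t_non / (t_obj + t_non))
  # config switch: visible-part time also leaves the denominator
  expect_equal(exploratory_dls(fx, lay, 0, 2000, vis_all,
                               exclude_from_denominator = TRUE), -1)

  # mixed hand-built case: two fixations on visible parts, one on covered
  # object area, one on background. Uncover only the cell at obj1's corner.
  cov <- new_cover(1920, 1080, 25)
  cx <- floor((obj$x0[1] + 30) / 25); cy <- floor((obj$y0[1] + 30) / 25)
  cov$grid[cy + 1, cx + 1] <- FALSE
  vis1 <- visible_object_region(cov, spec)
  in_cell <- c(cx * 25 + 5, cy * 25 + 5)
  fx <- make_fix(c(0, 1000, 2000, 3000), c(600, 1900, 2400, 3300),
                 c(in_cell[1], in_cell[1], obj$x1[1] + 20, 1800),
                 c(in_cell[2], in_cell[2], obj$y1[1] + 20, 100))
  # durations: 600 + 900 on visible object, 400 covered object AOI, 300 non
  expect_equal(exploratory_dls(fx, lay, 0, 4000, vis1),
               ((600 + 900 + 400 - 1500) - 300) / (1900 + 300))
  # and exploratory never exceeds the standard DLS
  expect_lte(exploratory_dls(fx, lay, 0, 4000, vis1),
             compute_dls(fx, lay, 0, 4000))
})

test_that("trial exclusion rules implement the preregistered criteria", {
  # baseline looking 500 ms -> whole trial excluded
  m <- apply_trial_exclusions(metrics_row(look_baseline = 500))
  expect_false(m$valid_baseline)
  expect_false(m$valid_contingent)
  expect_false(m$valid_disruption)
  expect_equal(m$exclusion_reason, "baseline_looking_lt_1s")

  # contingent looking 4 s but the 20% stop fraction was reached -> kept
  m <- apply_trial_exclusions(metrics_row(look_contingent = 4000,
                                          uncovered_fraction = 0.21,
                                          end_reason = "fraction_reached"))
  expect_true(m$valid_contingent)

  # contingent looking 5 s, fraction 0.10 -> contingent + disruption excluded
  m <- apply_trial_exclusions(metrics_row(look_contingent = 5000,
                                          uncovered_fraction = 0.10))
  expect_true(m$valid_baseline)
  expect_false(m$valid_contingent)
  expect_false(m$valid_disruption)
  expect_equal(m$exclusion_reason, "contingent_disengaged")

  # no disruption fixation -> disruption-only exclusion
  m <- apply_trial_exclusions(metrics_row(n_fix_disruption = 0))
  expect_true(m$valid_contingent)
  expect_false(m$valid_disruption)
  expect_equal(m$exclusion_reason, "no_disruption_fixation")

  # idempotent and row-order independent
  rows <- rbind(metrics_row(look_baseline = 500), metrics_row(),
                metrics_row(n_fix_disruption = 0))
  once <- apply_trial_exclusions(rows)
  expect_identical(apply_trial_exclusions(once[, names(rows)]), once)
  perm <- apply_trial_exclusions(rows[c(3, 1, 2), ])
  expect_identical(perm$valid_contingent, once$valid_contingent[c(3, 1, 2)])
})

test_that("split halves use the realized contingent window midpoint", {
  sch <- list(contingent_on = 8000, t_stop = 20000)
  # all-object looking only in the second half
  fx <- rbind(
    make_fix(c(8000, 10000), c(9000, 11000), c(100, 900), c(100, 100)),
    make_fix(c(14500, 16000), c(15500, 17000), c(100, 900), c(100, 900))
  )
  halves <- split_half_contingent(fx, lay50, sch)
  expect_equal(unname(halves["first"]), 0)   # one object, one non-object hit
  expect_equal(unname(halves["second"]), 1)

  # trace mirrored around the midpoint gives equal halves
  fx <- make_fix(c(9000, 18000), c(10000, 19000), c(100, 100), c(100, 100))
  halves <- split_half_contingent(fx, lay50, sch)
  expect_equal(unname(halves["first"]), unname(halves["second"]))
})

test_that("subject aggregation averages condition means and applies inclusion", {
  mk <- function(pid, cond, dls, valid = TRUE) {
    m <- metrics_row()
    m$participant_id <- pid; m$condition <- cond
    m$dls_contingent <- dls
    m <- apply_trial_exclusions(m)
    if (!valid) { m$look_contingent_ms <- 0; m <- apply_trial_exclusions(m) }
    m
  }
  rows <- rbind(
    mk("s1", "drop", 0.2), mk("s1", "drop", 0.4),
    mk("s1", "rise", 0.0), mk("s1", "rise", 0.2),
    mk("s2", "drop", 0.5), mk("s2", "drop", 0.5), mk("s2", "drop", 0.5),
    mk("s2", "rise", 0.5)
  )
  subj <- aggregate_subjects(rows)
  s1 <- subj[subj$participant_id == "s1", ]
  expect_equal(s1$dls_contingent, 0.2)   # mean of condition means 0.3 and 0.1
  expect_true(s1$included)
  # 3 drop / 1 rise valid trials -> excluded
  expect_false(subj$included[subj$participant_id == "s2"])

  # identical subjects -> group mean equals the common value
  rows2 <- rbind(mk("a", "drop", 0.3), mk("a", "drop", 0.3),
                 mk("a", "rise", 0.3), mk("a", "rise", 0.3),
                 mk("b", "drop", 0.3), mk("b", "drop", 0.3),
                 mk("b", "rise", 0.3), mk("b", "rise", 0.3))
  subj2 <- aggregate_subjects(rows2)
  expect_equal(mean(subj2$dls_contingent), 0.3)

  # undefined DLS trials drop out of the condition mean instead of counting 0
  rows3 <- rbind(mk("c", "drop", NA), mk("c", "drop", 0.4),
                 mk("c", "rise", 0.2), mk("c", "rise", 0.2))
  expect_equal(aggregate_subjects(rows3)$dls_contingent, 0.3)
})
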
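#' Parameters of the synthetic infant-gaze generator
#'
#' The generator emulates infant looking in the scratch paradigm: alternating
#' fixations and saccades sampled at 120 Hz, with the probability that a new
#' fixation targets an object quadrant depending on the trial phase. The
#' defaults encode the group-level behaviour the paradigm is built to detect:
#' a baseline preference for the objects while they are visible
#' (`p_obj_baseline = 0.64`, i.e. an expected DLS of 2p - 1 = 0.28), a
#' within-trial learning ramp in the contingent phase (`0.56 -> 0.62`, so the
#' second half shows a larger DLS than the first), a sustained preference
#' during the disruption (`0.60`), and a positive age effect on the
#' disruption preference (`age_slope` per day, centred on the cohort mean
#' age). Fixation durations are log-normal (median 300 ms, sigma 0.5),
#' saccades last 50 ms, and 10% of samples are lost (tracker dropout).
#'
#' @param p_obj_baseline,p_obj_contingent_start,p_obj_contingent_end,p_obj_disruption
#'   probability that a new fixation targets an object quadrant in each
#'   phase; within the contingent phase the probability ramps linearly from
#'   start to end over the nominal 30 s.
#' @param age_slope additive change in `p_obj_disruption` per day of age,
#'   centred on the cohort mean age.
#' @param fix_median_ms,fix_sigma log-normal fixation duration parameters.
#' @param saccade_gap_ms saccade duration between fixations, ms.
#' @param missing_rate i.i.d. probability a sample is invalid.
#' @param sample_rate_hz nominal sampling rate (default 120).
#' @param jitter_px maximum per-sample jitter around the fixation target.
#' @return List of class `synth_params`.
#' @export
synth_params <- function(p_obj_baseline = 0.64,
                         p_obj_contingent_start = 0.56,
                         p_obj_contingent_end = 0.62,
                         p_obj_disruption = 0.60,
                         age_slope = 5e-4,
                         fix_median_ms = 300, fix_sigma = 0.5,
                         saccade_gap_ms = 50, missing_rate = 0.10,
                         sample_rate_hz = 120, jitter_px = 5) {
  p <- list(p_obj_baseline = p_obj_baseline,
            p_obj_contingent_start = p_obj_contingent_start,
            p_obj_contingent_end = p_obj_contingent_end,
            p_obj_disruption = p_obj_disruption,
            age_slope = age_slope,
            fix_median_ms = fix_median_ms, fix_sigma = fix_sigma,
            saccade_gap_ms = saccade_gap_ms, missing_rate = missing_rate,
            sample_rate_hz = sample_rate_hz, jitter_px = jitter_px)
  probs <- unlist(p[c("p_obj_baseline", "p_obj_contingent_start",
                      "p_obj_contingent_end", "p_obj_disruption")])
  if (any(probs < 0 | probs > 1)) {
    stop("object-targeting probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p$p_obj_contingent_end < p$p_obj_contingent_start) {
    stop("p_obj_contingent_end must be >= p_obj_contingent_start (learning ramp)",
         call. = FALSE)
  }
  structure(p, class = "synth_params")
}

# phase-appropriate object-targeting probability on the nominal trial clock
phase_p_obj <- function(t_ms, params, p_disruption) {
  if (t_ms < 5000) return(params$p_obj_baseline)
  # transition: scored by no analysis; using the contingent-start preference
  # avoids a discontinuity for fixations straddling the 8 s boundary
  if (t_ms < 8000) return(params$p_obj_contingent_start)
  if (t_ms < 38000) {
    frac <- (t_ms - 8000) / 30000
    return(params$p_obj_contingent_start +
             frac * (params$p_obj_contingent_end - params$p_obj_contingent_start))
  }
  p_disruption
}

# uniform point in the union of two rectangles, area-weighted; the margin
# (the jitter radius) keeps jittered samples inside the chosen region, so
# the targeting probability p is exactly the probability of object-AOI looking
sample_point_in <- function(rects, margin = 0) {
  area <- (rects$x1 - rects$x0) * (rects$y1 - rects$y0)
  k <- sample.int(nrow(rects), 1, prob = area)
  c(runif(1, rects$x0[k] + margin, rects$x1[k] - margin),
    runif(1, rects$y0[k] + margin, rects$y1[k] - margin))
}

#' Generate one synthetic gaze recording
#'
#' Builds a 43-s (maximum-length) gaze trace at the configured sampling rate
#' as an alternation of fixations and saccades. Each fixation's target is an
#' object quadrant with the phase-appropriate probability (uniform placement
#' within the chosen quadrant pair, area-weighted), samples are jittered by
#' at most `jitter_px` around the target, saccade samples interpolate
#' linearly between targets, and samples are marked invalid i.i.d. at the
#' missingness rate. Deterministic under `seed`.
#'
#' The learning ramp and the disruption probability are mapped onto the
#' nominal phase clock (contingent \[8, 38) s); under infant-like parameters
#' the realized contingent phase almost always runs to the 30-s cap, so the
#' nominal and realized phases coincide.
#'
#' @param stimulus a single row of a `stimulus_set`.
#' @param params a [synth_params()] list.
#' @param seed integer seed.
#' @param participant_id,trial_id,age_days recording metadata.
#' @param p_obj_disruption_override subject-specific disruption probability
#'   (used by [synth_cohort()] to apply the age effect); `NULL` uses
#'   `params$p_obj_disruption`.
#' @return A `gaze_recording`: list with `participant_id`, `trial_id`,
#'   `age_days` and a `samples` tibble (`t_ms`, `x_px`, `y_px`, `valid`).
#' @export
synth_trial <- function(stimulus, params = synth_params(), seed = 1,
                        participant_id = "s01", trial_id = "t01",
                        age_days = 261, p_obj_disruption_override = NULL) {
  stopifnot(inherits(params, "synth_params"), nrow(stimulus) == 1)
  layout <- layout_for_stimulus(stimulus)
  obj_rects <- layout$rects[layout$rects$quadrant %in% layout$object_quadrants, ]
  non_rects <- layout$rects[!layout$rects$quadrant %in% layout$object_quadrants, ]
  p_dis <- if (is.null(p_obj_disruption_override)) params$p_obj_disruption
           else min(max(p_obj_disruption_override, 0.01), 0.99)

  dt_ms <- 1000 / params$sample_rate_hz
  t_max <- 43000
  with_seed(seed, {
    # event list: alternating fixation / saccade intervals with targets
    ev_start <- numeric(0); ev_end <- numeric(0)
    ev_x <- numeric(0); ev_y <- numeric(0); ev_fix <- logical(0)
    t <- 0
    while (t < t_max) {
      p <- phase_p_obj(t, params, p_dis)
      target <- if (runif(1) < p) sample_point_in(obj_rects, params$jitter_px)
                else sample_point_in(non_rects, params$jitter_px)
      # saccade to the new target, then fixate
      s_end <- min(t + params$saccade_gap_ms, t_max)
      ev_start <- c(ev_start, t); ev_end <- c(ev_end, s_end)
      ev_x <- c(ev_x, target[1]); ev_y <- c(ev_y, target[2])
      ev_fix <- c(ev_fix, FALSE)
      dur <- rlnorm(1, log(params$fix_median_ms), params$fix_sigma)
      f_end <- min(s_end + dur, t_max)
      ev_start <- c(ev_start, s_end); ev_end <- c(ev_end, f_end)
      ev_x <- c(ev_x, target[1]); ev_y <- c(ev_y, target[2])
      ev_fix <- c(ev_fix, TRUE)
      t <- f_end
    }
    n_ev <- length(ev_start)
    times <- seq(0, t_max - dt_ms / 2, by = dt_ms)
    ev_of <- findInterval(times, ev_start)
    x <- ev_x[ev_of]
    y <- ev_y[ev_of]
    # saccade samples: interpolate from the previous event's target
    sac <- !ev_fix[ev_of]
    if (any(sac)) {
      from_x <- c(layout$screen_w / 2, ev_x)[ev_of]
      from_y <- c(layout$screen_h / 2, ev_y)[ev_of]
      prog <- (times - ev_start[ev_of]) /
        pmax(ev_end[ev_of] - ev_start[ev_of], dt_ms)
      prog <- pmin(prog, 1)
      x[sac] <- from_x[sac] + prog[sac] * (ev_x[ev_of[sac]] - from_x[sac])
      y[sac] <- from_y[sac] + prog[sac] * (ev_y[ev_of[sac]] - from_y[sac])
    }
    jit <- params$jitter_px
    x <- pmin(pmax(x + runif(length(x), -jit, jit), 0), layout$screen_w - 1e-6)
    y <- pmin(pmax(y + runif(length(y), -jit, jit), 0), layout$screen_h - 1e-6)
    valid <- runif(length(x)) >= params$missing_rate
    new_gaze_recording(
      participant_id, trial_id, age_days,
      tibble::tibble(t_ms = times, x_px = x, y_px = y, valid = valid)
    )
  })
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws subject ages uniformly on the given range, applies the age effect
#' to the disruption-phase object preference, and generates
#' `trials_per_subject` recordings per subject from a counterbalanced
#' stimulus set (alternating drop / rise, presentation set alternating
#' between subjects). Ground truth (the per-phase targeting probabilities
#' actually used) is returned alongside, so recovery can be checked at every
#' pipeline stage.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param trials_per_subject trials per subject (default 16, one full set).
#' @param age_range_days inclusive age range; default about 6-10 months.
#' @param params a [synth_params()] list.
#' @param seed integer seed.
#' @param stimuli optional `stimulus_set`; generated at the defaults if
#'   missing.
#' @return List: `recordings` (list of `gaze_recording`), `stimuli`,
#'   `subjects` (tibble of participant, age), `truth` (tibble of per-trial
#'   targeting probabilities).
#' @export
synth_cohort <- function(n_subjects, trials_per_subject = 16,
                         age_range_days = c(180, 304),
                         params = synth_params(), seed = 1,
                         stimuli = NULL) {
  stopifnot(n_subjects >= 1)
  if (is.null(stimuli)) {
    stimuli <- generate_stimulus_set(seed = seed)
  }
  with_seed(seed, {
    ages <- round(runif(n_subjects, age_range_days[1], age_range_days[2]))
    mean_age <- mean(age_range_days)
    recordings <- vector("list", n_subjects * trials_per_subject)
    truth <- vector("list", n_subjects * trials_per_subject)
    k <- 0L
    for (i in seq_len(n_subjects)) {
      pid <- sprintf("s%03d", i)
      set <- if (i %% 2 == 1) "A" else "B"
      in_set <- which(!is.na(stimuli$set_id) & stimuli$set_id == set)
      in_set <- in_set[order(stimuli$order_in_set[in_set])]
      if (!length(in_set)) in_set <- seq_len(nrow(stimuli))
      trial_rows <- rep_len(in_set, trials_per_subject)
      p_dis <- params$p_obj_disruption +
        params$age_slope * (ages[i] - mean_age)
      p_dis <- min(max(p_dis, 0.01), 0.99)
      for (j in seq_len(trials_per_subject)) {
        k <- k + 1L
        spec <- stimuli[trial_rows[j], ]
        tid <- sprintf("t%02d", j)
        recordings[[k]] <- synth_trial(
          spec, params, seed = sample.int(2^31 - 1, 1),
          participant_id = pid, trial_id = tid, age_days = ages[i],
          p_obj_disruption_override = p_dis
        )
        truth[[k]] <- tibble::tibble(
          participant_id = pid, trial_id = tid,
          stimulus_id = spec$stimulus_id, condition = spec$condition,
          age_days = ages[i],
          p_obj_baseline = params$p_obj_baseline,
          p_obj_contingent_start = params$p_obj_contingent_start,
          p_obj_contingent_end = params$p_obj_contingent_end,
          p_obj_disruption = p_dis
        )
      }
    }
    list(recordings = recordings, stimuli = stimuli,
         subjects = tibble::tibble(participant_id = sprintf("s%03d", seq_len(n_subjects)),
                                   age_days = ages),
         truth = do.call(rbind, truth))
  })
}
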
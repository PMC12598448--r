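#' Per-quadrant looking times within a phase window
#'
#' Fixations are clipped to the window and assigned to AOI quadrants by their
#' centroid; off-screen centroids contribute to no quadrant.
#'
#' @param fixations a [detect_fixations()] table (whole-trial).
#' @param layout an [build_aoi_layout()] object.
#' @param t0,t1 phase window in ms.
#' @return Named numeric vector of looking time (ms) per quadrant
#'   (`TL`, `TR`, `BL`, `BR`).
#' @export
looking_times <- function(fixations, layout, t0, t1) {
  fx <- clip_fixations(fixations, t0, t1)
  q <- aoi_of_point(layout, fx$x, fx$y)
  out <- c(TL = 0, TR = 0, BL = 0, BR = 0)
  if (nrow(fx)) {
    agg <- tapply(fx$duration_ms, factor(q, levels = names(out)), sum)
    agg[is.na(agg)] <- 0
    out[] <- agg
  }
  out
}

#' Differential looking score for a phase window
#'
#' DLS = (T_obj - T_nonobj) / (T_obj + T_nonobj), where T_obj is the summed
#' looking time (by fixation centroid) to the two quadrants containing
#' objects and T_nonobj to the two quadrants without objects. Values lie in
#' \[-1, 1\]: 1 means exclusive looking to object quadrants, 0 equal looking
#' to all four quadrants, -1 exclusive looking to non-object quadrants. When
#' there is no on-screen looking in the window the score is undefined
#' (`NA`).
#'
#' @inheritParams looking_times
#' @return A single DLS value or `NA`.
#' @export
compute_dls <- function(fixations, layout, t0, t1) {
  lt <- looking_times(fixations, layout, t0, t1)
  obj <- sum(lt[layout$object_quadrants])
  non <- sum(lt[setdiff(names(lt), layout$object_quadrants)])
  if (obj + non <= 0) return(NA_real_)
  (obj - non) / (obj + non)
}

#' Exploratory disruption-phase DLS
#'
#' As [compute_dls()], but looking time of fixations whose centroid falls on
#' already-uncovered (visible) object parts is subtracted from the
#' object-quadrant looking time, so only "exploratory" fixations to still
#' covered areas count toward the numerator. By default the denominator is
#' left unchanged (total on-screen looking including visible-part fixations);
#' set `exclude_from_denominator = TRUE` to drop that time from the
#' denominator as well. The result can only be smaller than or equal to the
#' standard DLS; with a fully covered image it equals it.
#'
#' @inheritParams looking_times
#' @param visible_region a [visible_object_region()] for the cover at
#'   disruption onset.
#' @param exclude_from_denominator also remove visible-part looking time from
#'   the denominator (default `FALSE`).
#' @return A single DLS value or `NA`.
#' @export
exploratory_dls <- function(fixations, layout, t0, t1, visible_region,
                            exclude_from_denominator = FALSE) {
  fx <- clip_fixations(fixations, t0, t1)
  q <- aoi_of_point(layout, fx$x, fx$y)
  on <- !is.na(q)
  is_obj <- on & q %in% layout$object_quadrants
  on_visible <- is_obj & region_contains(visible_region, fx$x, fx$y)
  t_obj_raw <- sum(fx$duration_ms[is_obj])
  t_vis <- sum(fx$duration_ms[on_visible])
  t_non <- sum(fx$duration_ms[on & !is_obj])
  denom <- if (exclude_from_denominator) t_obj_raw - t_vis + t_non
           else t_obj_raw + t_non
  if (denom <= 0) return(NA_real_)
  ((t_obj_raw - t_vis) - t_non) / denom
}

#' Split-half DLS of the contingent phase
#'
#' The realized contingent window `[contingent_on, t_stop)` is split at its
#' midpoint; fixations are clipped at the midpoint and a DLS computed for
#' each half.
#'
#' @param fixations whole-trial fixation table.
#' @param layout an `aoi_layout`.
#' @param schedule the `schedule` element of a `trial_record`.
#' @return Named numeric vector `c(first = ..., second = ...)` (either may be
#'   `NA`).
#' @export
split_half_contingent <- function(fixations, layout, schedule) {
  mid <- (schedule$contingent_on + schedule$t_stop) / 2
  c(first = compute_dls(fixations, layout, schedule$contingent_on, mid),
    second = compute_dls(fixations, layout, mid, schedule$t_stop))
}

#' Compute the full per-trial metrics row
#'
#' Runs fixation-based scoring for all phases of one simulated trial:
#' per-phase on-screen looking times, the DLS for baseline / contingent /
#' disruption, the contingent split halves, the exploratory disruption DLS,
#' and the preregistered exclusion flags.
#'
#' @param recording the trial's `gaze_recording`.
#' @param fixations [detect_fixations()] output for the recording.
#' @param trial the [simulate_trial()] record.
#' @param exploratory_excludes_denominator passed to [exploratory_dls()].
#' @return One-row tibble (see [apply_trial_exclusions()] for the flags).
#' @export
compute_trial_metrics <- function(recording, fixations, trial,
                                  exploratory_excludes_denominator = FALSE) {
  layout <- layout_for_stimulus(trial$stimulus)
  sch <- trial$schedule
  win <- list(
    baseline = c(sch$baseline_on, sch$transition_on),
    contingent = c(sch$contingent_on, sch$t_stop),
    disruption = c(sch$t_stop, sch$disruption_off)
  )
  look <- vapply(win, function(w) sum(looking_times(fixations, layout, w[1], w[2])),
                 numeric(1))
  dls <- vapply(win, function(w) compute_dls(fixations, layout, w[1], w[2]),
                numeric(1))
  halves <- split_half_contingent(fixations, layout, sch)
  vis <- visible_object_region(trial$cover_at_disruption, trial$stimulus)
  dls_expl <- exploratory_dls(fixations, layout, win$disruption[1],
                              win$disruption[2], vis,
                              exploratory_excludes_denominator)
  n_fix_disruption <- nrow(clip_fixations(fixations, win$disruption[1],
                                          win$disruption[2]))
  m <- tibble::tibble(
    participant_id = recording$participant_id,
    trial_id = recording$trial_id,
    age_days = recording$age_days,
    condition = trial$stimulus$condition,
    look_baseline_ms = look[["baseline"]],
    look_contingent_ms = look[["contingent"]],
    look_disruption_ms = look[["disruption"]],
    dls_baseline = dls[["baseline"]],
    dls_contingent = dls[["contingent"]],
    dls_disruption = dls[["disruption"]],
    dls_contingent_first_half = halves[["first"]],
    dls_contingent_second_half = halves[["second"]],
    dls_disruption_exploratory = dls_expl,
    n_fix_disruption = n_fix_disruption,
    uncovered_fraction = trial$uncovered_fraction,
    end_reason = trial$end_reason
  )
  apply_trial_exclusions(m)
}

#' Apply the preregistered trial-level exclusion rules
#'
#' Three rules, applied per trial:
#' \itemize{
#'   \item baseline: less than 1 s of on-screen looking during the baseline
#'     phase excludes the entire trial;
#'   \item contingent: the trial is kept for the contingent and disruption
#'     analyses iff the infant either looked at the screen for at least 10 s
#'     during the contingent phase or scratched the 20% stop fraction free
#'     (an engaged early stop), otherwise both phases are excluded;
#'   \item disruption: additionally excluded if the phase contains no
#'     fixation.
#' }
#' The flags are idempotent: re-applying the rules to an already flagged
#' table leaves it unchanged.
#'
#' @param metrics a trial-metrics tibble (any number of rows) with the
#'   looking-time, `n_fix_disruption`, `uncovered_fraction` and `end_reason`
#'   columns of [compute_trial_metrics()].
#' @param min_baseline_look_ms,min_contingent_look_ms,stop_fraction rule
#'   thresholds.
#' @return `metrics` with logical columns `valid_baseline`,
#'   `valid_contingent`, `valid_disruption` and a `exclusion_reason` string
#'   (`""` when fully valid).
#' @export
apply_trial_exclusions <- function(metrics, min_baseline_look_ms = 1000,
                                   min_contingent_look_ms = 10000,
                                   stop_fraction = 0.20) {
  vb <- metrics$look_baseline_ms >= min_baseline_look_ms
  engaged <- metrics$look_contingent_ms >= min_contingent_look_ms |
    metrics$uncovered_fraction >= stop_fraction |
    metrics$end_reason == "fraction_reached"
  vc <- vb & engaged
  vd <- vc & metrics$n_fix_disruption >= 1
  reason <- rep("", nrow(metrics))
  reason[vc & !vd] <- "no_disruption_fixation"
  reason[vb & !vc] <- "contingent_disengaged"
  reason[!vb] <- "baseline_looking_lt_1s"
  metrics$valid_baseline <- vb
  metrics$valid_contingent <- vc
  metrics$valid_disruption <- vd
  metrics$exclusion_reason <- reason
  metrics
}

#' Aggregate trial metrics to subject-level summaries
#'
#' For each participant and phase, the DLS of valid trials is averaged within
#' each condition (drop / rise), and the subject-level DLS is the unweighted
#' mean of the two condition means, so unequal trial counts per condition do
#' not bias the subject value. Trials with an undefined DLS drop out of the
#' condition mean. A subject is `included` iff they contribute at least
#' `min_trials_per_condition` trials valid for the contingent analysis in
#' each condition.
#'
#' @param metrics trial-metrics table with exclusion flags
#'   ([compute_trial_metrics()] rows).
#' @param min_trials_per_condition inclusion threshold (default 2).
#' @return Tibble, one row per participant: valid-trial counts, per-phase
#'   subject DLS (`dls_baseline`, `dls_contingent`, `dls_disruption`,
#'   split halves, exploratory), `age_days`, `included`.
#' @export
aggregate_subjects <- function(metrics, min_trials_per_condition = 2) {
  cond_mean <- function(df, col, flag) {
    vapply(c("drop", "rise"), function(cn) {
      v <- df[[col]][df$condition == cn & df[[flag]]]
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  subj_value <- function(df, col, flag) mean(cond_mean(df, col, flag))

  ids <- unique(metrics$participant_id)
  rows <- lapply(ids, function(id) {
    df <- metrics[metrics$participant_id == id, ]
    n_drop <- sum(df$valid_contingent & df$condition == "drop")
    n_rise <- sum(df$valid_contingent & df$condition == "rise")
    tibble::tibble(
      participant_id = id,
      age_days = df$age_days[1],
      n_valid_trials_drop = n_drop,
      n_valid_trials_rise = n_rise,
      dls_baseline = subj_value(df, "dls_baseline", "valid_baseline"),
      dls_contingent = subj_value(df, "dls_contingent", "valid_contingent"),
      dls_disruption = subj_value(df, "dls_disruption", "valid_disruption"),
      dls_contingent_first_half =
        subj_value(df, "dls_contingent_first_half", "valid_contingent"),
      dls_contingent_second_half =
        subj_value(df, "dls_contingent_second_half", "valid_contingent"),
      dls_disruption_exploratory =
        subj_value(df, "dls_disruption_exploratory", "valid_disruption"),
      included = n_drop >= min_trials_per_condition &
        n_rise >= min_trials_per_condition
    )
  })
  do.call(rbind, rows)
}
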
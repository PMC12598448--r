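#' Run the full analysis pipeline
#'
#' Sequences every stage on one dataset: obtain gaze recordings (synthetic
#' cohort or an external gaze CSV), replay each recording through the
#' scratch-trial mechanics, detect fixations, compute trial metrics and
#' exclusion flags, aggregate to subject level, and run the statistical
#' layer (per-phase directed one-sample tests of DLS > 0, the contingent
#' split-half comparison, the exploratory disruption DLS, post-hoc paired
#' phase comparisons, and age associations per phase). All intermediate
#' tables can be written to `out_dir`.
#'
#' @param config a [load_config()] / [default_config()] list (a plain list
#'   is accepted).
#' @param gaze_path optional path to a gaze CSV ([read_gaze_table()]
#'   format); when `NULL` a synthetic cohort is generated from the config.
#' @param out_dir optional output directory for the CSV tables and the text
#'   report.
#' @param seed overrides `config$seed`.
#' @param verbose log stage counts to stderr.
#' @return An object of class `run_report`: `trial_metrics`, `subjects`,
#'   `group` (per-phase mean / SD / SE / n over included subjects),
#'   `tests` (named list of `bayes_result`), and the exclusion accounting
#'   (`trials_recorded`, `trials_excluded`, `exclusion_rate`,
#'   `subjects_recorded`, `subjects_retained`).
#' @export
run_pipeline <- function(config = default_config(), gaze_path = NULL,
                         out_dir = NULL, seed = NULL, verbose = FALSE) {
  cfg <- config
  if (!is.null(seed)) cfg$seed <- seed
  say <- function(fmt, ...) {
    if (verbose) message(sprintf(paste0("[%s] ", fmt),
                                 format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), ...))
  }

  params <- synth_params(
    p_obj_baseline = cfg$p_obj_baseline,
    p_obj_contingent_start = cfg$p_obj_contingent_start,
    p_obj_contingent_end = cfg$p_obj_contingent_end,
    p_obj_disruption = cfg$p_obj_disruption,
    age_slope = cfg$age_slope,
    fix_median_ms = cfg$fix_median_ms, fix_sigma = cfg$fix_sigma,
    saccade_gap_ms = cfg$saccade_gap_ms, missing_rate = cfg$missing_rate,
    sample_rate_hz = cfg$sample_rate_hz, jitter_px = cfg$jitter_px
  )
  stimuli <- generate_stimulus_set(
    cfg$n_pairs, cfg$n_backgrounds, seed = cfg$seed,
    screen_w = cfg$screen_w, screen_h = cfg$screen_h,
    object_area_fraction = cfg$object_area_fraction,
    object_square_frac = cfg$object_square_frac
  )

  if (is.null(gaze_path)) {
    say("generating synthetic cohort: %d subjects x %d trials",
        cfg$n_subjects, cfg$trials_per_subject)
    cohort <- synth_cohort(cfg$n_subjects, cfg$trials_per_subject,
                           c(cfg$age_min_days, cfg$age_max_days),
                           params, seed = cfg$seed, stimuli = stimuli)
    recordings <- cohort$recordings
    rec_stim <- match(cohort$truth$stimulus_id, stimuli$stimulus_id)
  } else {
    say("reading gaze table %s", gaze_path)
    recordings <- read_gaze_table(gaze_path)
    # external recordings cycle through presentation set A in trial order
    in_a <- which(!is.na(stimuli$set_id) & stimuli$set_id == "A")
    in_a <- in_a[order(stimuli$order_in_set[in_a])]
    trial_no <- as.integer(factor(vapply(recordings, `[[`, "", "trial_id")))
    rec_stim <- rep_len(in_a, max(trial_no))[trial_no]
  }
  say("stage io: %d recordings", length(recordings))

  metrics <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    spec <- stimuli[rec_stim[i], ]
    trial <- simulate_trial(rec, spec, square_px = cfg$square_px,
                            stop_fraction = cfg$stop_fraction,
                            contingent_cap_ms = cfg$contingent_cap_ms,
                            baseline_ms = cfg$baseline_ms,
                            transition_ms = cfg$transition_ms,
                            disruption_ms = cfg$disruption_ms)
    fx <- detect_fixations(rec$samples, cfg$max_dispersion_px,
                           cfg$min_fixation_ms, cfg$max_gap_samples)
    metrics[[i]] <- compute_trial_metrics(
      rec, fx, trial, cfg$exploratory_excludes_denominator)
  }
  metrics <- do.call(rbind, metrics)
  metrics <- apply_trial_exclusions(metrics, cfg$min_baseline_look_ms,
                                    cfg$min_contingent_look_ms,
                                    cfg$stop_fraction)
  say("stage metrics: %d trial rows, %d excluded from contingent analysis",
      nrow(metrics), sum(!metrics$valid_contingent))

  subjects <- aggregate_subjects(metrics, cfg$min_trials_per_condition)
  say("stage aggregation: %d subjects, %d included",
      nrow(subjects), sum(subjects$included))
  inc <- subjects[subjects$included, ]

  group_stats <- function(v) {
    v <- v[!is.na(v)]
    c(n = length(v), mean = mean(v), sd = sd(v),
      se = sd(v) / sqrt(length(v)))
  }
  phases <- c(baseline = "dls_baseline", contingent = "dls_contingent",
              disruption = "dls_disruption",
              contingent_first_half = "dls_contingent_first_half",
              contingent_second_half = "dls_contingent_second_half",
              disruption_exploratory = "dls_disruption_exploratory")
  group <- do.call(rbind, lapply(names(phases), function(ph) {
    g <- group_stats(inc[[phases[[ph]]]])
    tibble::tibble(phase = ph, n = g[["n"]], mean = g[["mean"]],
                   sd = g[["sd"]], se = g[["se"]])
  }))

  one_sample <- function(v) {
    v <- v[!is.na(v)]
    if (cfg$use_rank_tests) {
      rank_bf_one_sample(v, "greater", cfg$prior_scale, cfg$n_mcmc,
                         cfg$burn_in, cfg$n_chains, seed = cfg$seed,
                         rhat_threshold = cfg$rhat_threshold)
    } else {
      jzs_bf_one_sample(v, "greater", cfg$prior_scale)
    }
  }
  paired <- function(a, b) {
    d <- a - b
    d <- d[!is.na(d)]
    jzs_bf_one_sample(d, "two_sided", cfg$prior_scale)
  }
  age_cor <- function(v) {
    ok <- !is.na(v)
    kendall_tau_bf(inc$age_days[ok], v[ok], cfg$tau_prior_width, "greater")
  }

  say("stage stats")
  # tests that cannot run on this dataset (e.g. too few subjects for a tau
  # BF) are omitted from the report rather than aborting the run
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  tests <- list(
    dls_baseline_gt0 = safe(one_sample(inc$dls_baseline)),
    dls_contingent_gt0 = safe(one_sample(inc$dls_contingent)),
    dls_disruption_gt0 = safe(one_sample(inc$dls_disruption)),
    split_half_second_gt_first = safe({
      d <- inc$dls_contingent_second_half - inc$dls_contingent_first_half
      one_sample(d[!is.na(d)])
    }),
    dls_disruption_exploratory_gt0 =
      safe(one_sample(inc$dls_disruption_exploratory)),
    paired_baseline_vs_contingent =
      safe(paired(inc$dls_baseline, inc$dls_contingent)),
    paired_contingent_vs_disruption =
      safe(paired(inc$dls_contingent, inc$dls_disruption)),
    paired_baseline_vs_disruption =
      safe(paired(inc$dls_baseline, inc$dls_disruption)),
    age_tau_baseline = safe(age_cor(inc$dls_baseline)),
    age_tau_contingent = safe(age_cor(inc$dls_contingent)),
    age_tau_disruption = safe(age_cor(inc$dls_disruption))
  )
  tests <- Filter(Negate(is.null), tests)

  report <- structure(
    list(
      trial_metrics = metrics,
      subjects = subjects,
      group = group,
      tests = tests,
      trials_recorded = nrow(metrics),
      trials_excluded = sum(!metrics$valid_contingent),
      exclusion_rate = sum(!metrics$valid_contingent) / nrow(metrics),
      subjects_recorded = nrow(subjects),
      subjects_retained = sum(subjects$included),
      config = cfg
    ),
    class = "run_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_table(metrics, file.path(out_dir, "trial_metrics.csv"))
    write_metrics_table(subjects, file.path(out_dir, "subjects.csv"))
    write_metrics_table(group, file.path(out_dir, "group_dls.csv"))
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
    say("wrote tables to %s", out_dir)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("== gaze-scratch pipeline report ==\n")
  cat(sprintf("trials: %d recorded, %d excluded (rate %.1f%%)\n",
              x$trials_recorded, x$trials_excluded, 100 * x$exclusion_rate))
  cat(sprintf("subjects: %d recorded, %d retained\n\n",
              x$subjects_recorded, x$subjects_retained))
  cat("group DLS (included subjects):\n")
  for (i in seq_len(nrow(x$group))) {
    cat(sprintf("  %-24s n = %2d  M = %6.3f  SD = %.3f  SE = %.3f\n",
                x$group$phase[i], x$group$n[i], x$group$mean[i],
                x$group$sd[i], x$group$se[i]))
  }
  cat("\ntests:\n")
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    extra <- if (!is.na(t$rhat)) sprintf(", Rhat = %.3f", t$rhat) else ""
    stat <- if (!is.na(t$statistic) && t$method == "kendall_tau") {
      sprintf("tau = %.3f, ", t$statistic)
    } else ""
    cat(sprintf("  %-32s %sBF10 = %.4g (%s%s)\n", nm, stat, t$bf10,
                classify_bf(t$bf10), extra))
  }
  invisible(x)
}
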
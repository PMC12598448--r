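#' Default run configuration
#'
#' Flat key/value list of every tunable parameter of the pipeline, with the
#' defaults used throughout the package: screen and AOI geometry, scratch
#' mechanics, fixation detection, exclusion thresholds, the Bayesian layer,
#' and the synthetic-cohort generator.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    # stimulus / AOI geometry
    screen_w = 1920, screen_h = 1080,
    object_area_fraction = 0.5572,
    object_square_frac = 0.15,
    n_pairs = 16, n_backgrounds = 16,
    # scratch mechanics
    square_px = 25, stop_fraction = 0.20,
    baseline_ms = 5000, transition_ms = 3000,
    contingent_cap_ms = 30000, disruption_ms = 5000,
    # fixation detection
    max_dispersion_px = 25, min_fixation_ms = 200, max_gap_samples = 2,
    # DLS / exclusions
    exploratory_excludes_denominator = FALSE,
    min_baseline_look_ms = 1000, min_contingent_look_ms = 10000,
    min_trials_per_condition = 2,
    # Bayesian layer
    prior_scale = 0.707, tau_prior_width = 1,
    n_min = 30, bf_upper = 3, bf_lower = 1 / 3,
    n_mcmc = 5000, burn_in = 1000, n_chains = 2, rhat_threshold = 1.1,
    use_rank_tests = TRUE,
    # synthetic cohort
    n_subjects = 45, trials_per_subject = 16,
    age_min_days = 180, age_max_days = 304,
    p_obj_baseline = 0.64, p_obj_contingent_start = 0.56,
    p_obj_contingent_end = 0.62, p_obj_disruption = 0.60,
    age_slope = 5e-4,
    fix_median_ms = 300, fix_sigma = 0.5,
    saccade_gap_ms = 50, missing_rate = 0.10,
    sample_rate_hz = 120, jitter_px = 5,
    seed = 1
  )
}

#' Load a run configuration
#'
#' Reads a YAML file of flat key/value overrides on top of
#' [default_config()]. Unknown keys are rejected with the nearest valid key
#' named (so typos like `min_fix_ms` fail loudly), and values must match the
#' type of the default they override.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Named list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    for (key in names(user)) {
      if (!key %in% names(cfg)) {
        d <- adist(key, names(cfg))
        stop(sprintf("unknown config key '%s' (did you mean '%s'?)",
                     key, names(cfg)[which.min(d)]), call. = FALSE)
      }
      val <- user[[key]]
      if (is.numeric(cfg[[key]]) && !is.numeric(val)) {
        stop(sprintf("config key '%s' must be numeric", key), call. = FALSE)
      }
      if (is.logical(cfg[[key]]) && !is.logical(val)) {
        stop(sprintf("config key '%s' must be logical", key), call. = FALSE)
      }
      cfg[[key]] <- val
    }
  }
  structure(cfg, class = c("run_config", "list"))
}
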
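#' Construct a gaze recording
#'
#' One trial of one participant: time-ordered gaze samples at a nominal
#' 120 Hz. Missing gaze (blinks, tracking loss) is encoded as a `valid =
#' FALSE` row, not an absent row, so sampling-rate bookkeeping survives
#' dropouts; consumers ignore the coordinates of invalid samples.
#'
#' @param participant_id,trial_id opaque identifier strings.
#' @param age_days nonnegative integer age covariate.
#' @param samples data frame with columns `t_ms` (>= 0, strictly
#'   increasing), `x_px`, `y_px` (0-based pixels, origin top-left, y down),
#'   `valid` (logical).
#' @return List of class `gaze_recording`.
#' @export
new_gaze_recording <- function(participant_id, trial_id, age_days, samples) {
  if (nrow(samples) && any(diff(samples$t_ms) <= 0)) {
    stop(sprintf("samples of trial '%s' are not strictly increasing in t_ms",
                 trial_id), call. = FALSE)
  }
  if (nrow(samples) && samples$t_ms[1] < 0) {
    stop("t_ms must be nonnegative", call. = FALSE)
  }
  structure(list(participant_id = as.character(participant_id),
                 trial_id = as.character(trial_id),
                 age_days = as.integer(age_days),
                 samples = tibble::as_tibble(samples)),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> %s/%s, age %d d, %d samples (%.1f%% valid)\n",
              x$participant_id, x$trial_id, x$age_days, nrow(x$samples),
              if (nrow(x$samples)) 100 * mean(x$samples$valid) else NA))
  invisible(x)
}

gaze_cols <- c("participant_id", "trial_id", "age_days", "t_ms", "x_px",
               "y_px", "valid")

#' Read a gaze-sample table into recordings
#'
#' Reads a delimited text file (UTF-8, header row, one row per sample) and
#' splits it into one `gaze_recording` per (participant, trial). The reader
#' never reorders or drops samples: non-monotone timestamps within a trial
#' (including duplicates) are an integrity error naming the trial, not a
#' silent re-sort.
#'
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @return List of `gaze_recording` objects (empty list for a header-only
#'   file), in file order of first appearance.
#' @export
read_gaze_table <- function(path, delim = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  missing <- setdiff(gaze_cols, names(df))
  if (length(missing)) {
    stop(sprintf("gaze table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!nrow(df)) return(list())
  df$valid <- as.logical(df$valid)
  key <- paste(df$participant_id, df$trial_id, sep = "\r")
  idx <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  lapply(idx, function(ii) {
    new_gaze_recording(df$participant_id[ii[1]], df$trial_id[ii[1]],
                       df$age_days[ii[1]],
                       df[ii, c("t_ms", "x_px", "y_px", "valid")])
  })
}

#' Write gaze recordings to a sample table
#'
#' Inverse of [read_gaze_table()]; full float precision, so a read-back
#' round-trips the values exactly.
#'
#' @param recordings list of `gaze_recording` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(recordings, path) {
  rows <- lapply(recordings, function(r) {
    if (!nrow(r$samples)) return(NULL)
    tibble::tibble(participant_id = r$participant_id, trial_id = r$trial_id,
                   age_days = r$age_days, t_ms = r$samples$t_ms,
                   x_px = r$samples$x_px, y_px = r$samples$y_px,
                   valid = r$samples$valid)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- tibble::as_tibble(setNames(
      list(character(0), character(0), integer(0), numeric(0), numeric(0),
           numeric(0), logical(0)), gaze_cols))
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' Write and read trial-metrics tables
#'
#' Comma-delimited UTF-8 with a header row; one row per trial. Undefined DLS
#' values (no looking in the phase) are serialized as the explicit `NA`
#' sentinel. `readr` writes shortest round-trip float representations, so a
#' read-back is value-identical.
#'
#' @param metrics trial-metrics tibble (may have zero rows).
#' @param path file path.
#' @return `path` invisibly for the writer; a tibble for the reader.
#' @export
write_metrics_table <- function(metrics, path) {
  readr::write_csv(metrics, path, na = "NA")
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
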
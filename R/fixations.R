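#' Dispersion-duration (I-DT) fixation detection
#'
#' Detects fixations as maximal greedy windows in which every valid gaze
#' sample lies within `max_dispersion_px` (Euclidean) of the window centroid
#' (the mean location of its valid samples), lasting strictly more than
#' `min_duration_ms`. The detector scans left to right: a window opens at a
#' valid sample and grows sample by sample, recomputing the centroid as
#' samples join; the first candidate whose admission would put any member
#' (including itself) outside the dispersion radius closes the window. A run
#' of up to `max_gap_samples` consecutive invalid samples (blinks / tracking
#' loss) is tolerated inside a window; a longer run closes it. Windows start
#' and end on valid samples; a closed window is emitted as a fixation iff its
#' duration (offset minus onset time) exceeds `min_duration_ms`, otherwise
#' the scan restarts one sample later. Emitted fixations are therefore
#' pairwise disjoint and time-ordered.
#'
#' The defaults (25 px, 200 ms) implement the infant-eye-tracking convention
#' of a mean gaze location within 25 pixels for more than 200 ms.
#'
#' @param samples data frame with columns `t_ms`, `x_px`, `y_px`, `valid`,
#'   time-ordered.
#' @param max_dispersion_px dispersion radius around the centroid, px.
#' @param min_duration_ms minimum duration, ms (strict inequality).
#' @param max_gap_samples longest run of invalid samples tolerated inside a
#'   fixation window.
#' @return Tibble with one row per fixation: `onset_ms`, `offset_ms`,
#'   `duration_ms`, centroid `x`, `y`, and `n_samples` (valid members).
#' @export
detect_fixations <- function(samples, max_dispersion_px = 25,
                             min_duration_ms = 200, max_gap_samples = 2) {
  n <- nrow(samples)
  out_on <- numeric(0); out_off <- numeric(0)
  out_x <- numeric(0); out_y <- numeric(0); out_k <- integer(0)
  if (n == 0) {
    return(tibble::tibble(onset_ms = out_on, offset_ms = out_off,
                          duration_ms = numeric(0), x = out_x, y = out_y,
                          n_samples = out_k))
  }
  t <- samples$t_ms; x <- samples$x_px; y <- samples$y_px
  valid <- samples$valid & !is.na(samples$x_px) & !is.na(samples$y_px)
  r2 <- max_dispersion_px^2

  i <- 1L
  while (i <= n) {
    if (!valid[i]) { i <- i + 1L; next }
    # open window at i, grow greedily
    mx <- x[i]; my <- y[i]                   # member coordinates
    sumx <- x[i]; sumy <- y[i]; k <- 1L
    end_valid <- i
    j <- i + 1L
    gap <- 0L
    while (j <= n) {
      if (!valid[j]) {
        gap <- gap + 1L
        if (gap > max_gap_samples) break
        j <- j + 1L
        next
      }
      ncx <- (sumx + x[j]) / (k + 1L)
      ncy <- (sumy + y[j]) / (k + 1L)
      if ((x[j] - ncx)^2 + (y[j] - ncy)^2 <= r2 &&
          all((mx - ncx)^2 + (my - ncy)^2 <= r2)) {
        mx <- c(mx, x[j]); my <- c(my, y[j])
        sumx <- sumx + x[j]; sumy <- sumy + y[j]; k <- k + 1L
        end_valid <- j
        gap <- 0L
        j <- j + 1L
      } else break
    }
    if (t[end_valid] - t[i] > min_duration_ms) {
      out_on <- c(out_on, t[i]); out_off <- c(out_off, t[end_valid])
      out_x <- c(out_x, sumx / k); out_y <- c(out_y, sumy / k)
      out_k <- c(out_k, k)
      i <- end_valid + 1L
    } else {
      i <- i + 1L
    }
  }
  tibble::tibble(onset_ms = out_on, offset_ms = out_off,
                 duration_ms = out_off - out_on,
                 x = out_x, y = out_y, n_samples = out_k)
}

#' Clip fixations to a time window
#'
#' Keeps fixations overlapping `[t0, t1)` and replaces `duration_ms` by the
#' overlap, so a fixation straddling a phase boundary contributes its
#' within-phase portion to each phase.
#'
#' @param fixations a [detect_fixations()] table.
#' @param t0,t1 window bounds in ms.
#' @return The clipped fixation table (possibly zero rows).
#' @export
clip_fixations <- function(fixations, t0, t1) {
  ov <- pmin(fixations$offset_ms, t1) - pmax(fixations$onset_ms, t0)
  keep <- !is.na(ov) & ov > 0
  out <- fixations[keep, , drop = FALSE]
  out$duration_ms <- ov[keep]
  out
}
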
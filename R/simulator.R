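#' Create a fresh cover grid
#'
#' The cover is a grid of square cells of side `square_px`; cells on the
#' right/bottom edges may be smaller so the grid tiles the screen exactly.
#' `TRUE` means covered.
#'
#' @param screen_w,screen_h screen size in pixels.
#' @param square_px cover square side in pixels (default 25).
#' @return An object of class `cover_state`.
#' @export
new_cover <- function(screen_w, screen_h, square_px = 25) {
  nx <- ceiling(screen_w / square_px)
  ny <- ceiling(screen_h / square_px)
  cell_w <- rep(square_px, nx)
  cell_w[nx] <- screen_w - (nx - 1) * square_px
  cell_h <- rep(square_px, ny)
  cell_h[ny] <- screen_h - (ny - 1) * square_px
  structure(
    list(
      grid = matrix(TRUE, nrow = ny, ncol = nx),
      square_px = square_px,
      screen_w = screen_w, screen_h = screen_h,
      cell_w = cell_w, cell_h = cell_h
    ),
    class = "cover_state"
  )
}

#' Area-weighted uncovered fraction of a cover grid
#'
#' Edge cells are weighted by their true (possibly smaller) area, so the
#' fraction is exact for any screen size: fully covered gives 0, fully
#' cleared gives 1.
#'
#' @param cover a `cover_state`.
#' @return Fraction of screen area uncovered, in \[0, 1\].
#' @export
uncovered_fraction <- function(cover) {
  area <- outer(cover$cell_h, cover$cell_w)
  sum(area[!cover$grid]) / (cover$screen_w * cover$screen_h)
}

#' @export
print.cover_state <- function(x, ...) {
  cat(sprintf("<cover_state> %dx%d cells of %g px, %.1f%% uncovered\n",
              nrow(x$grid), ncol(x$grid), x$square_px,
              100 * uncovered_fraction(x)))
  invisible(x)
}

#' Simulate one trial of the gaze-contingent scratch paradigm
#'
#' Replays a gaze recording through the trial mechanics: a 5 s baseline, a
#' 3 s covering transition, a gaze-contingent phase in which every valid
#' on-screen gaze sample uncovers the cover cell containing it (idempotent),
#' and a 5 s disruption phase with a frozen cover. The contingent phase ends
#' at the first sample whose uncovering brings the uncovered fraction to the
#' stop fraction, or after `contingent_cap_ms`, whichever comes first; the
#' maximum trial length is therefore 5 + 3 + 30 + 5 = 43 s at the defaults.
#' Gaze during baseline, transition and disruption never uncovers cells, and
#' off-screen or invalid samples are ignored.
#'
#' @param recording a `gaze_recording` (see [read_gaze_table()] or
#'   [synth_trial()]).
#' @param stimulus a single row of a `stimulus_set`.
#' @param square_px cover cell side in pixels.
#' @param stop_fraction stop when this fraction of the screen is uncovered.
#' @param contingent_cap_ms maximum contingent-phase duration in ms.
#' @param baseline_ms,transition_ms,disruption_ms phase durations in ms.
#' @return An object of class `trial_record`: the phase `schedule`
#'   (`contingent_on`, `t_stop`, `disruption_off`, ...), the cover state at
#'   disruption onset, `end_reason` (`"fraction_reached"` or `"timeout"`),
#'   the uncover event log, and the final uncovered fraction.
#' @export
simulate_trial <- function(recording, stimulus,
                           square_px = 25, stop_fraction = 0.20,
                           contingent_cap_ms = 30000,
                           baseline_ms = 5000, transition_ms = 3000,
                           disruption_ms = 5000) {
  stopifnot(inherits(recording, "gaze_recording"), nrow(stimulus) == 1)
  w <- stimulus$screen_w
  h <- stimulus$screen_h
  cover <- new_cover(w, h, square_px)
  contingent_on <- baseline_ms + transition_ms
  cap_off <- contingent_on + contingent_cap_ms

  s <- recording$samples
  sel <- s$valid & s$t_ms >= contingent_on & s$t_ms < cap_off &
    s$x_px >= 0 & s$x_px < w & s$y_px >= 0 & s$y_px < h
  sel[is.na(sel)] <- FALSE
  t_stop <- cap_off
  end_reason <- "timeout"
  events <- tibble::tibble(t_ms = numeric(0), cell_x = integer(0),
                           cell_y = integer(0))
  if (any(sel)) {
    t <- s$t_ms[sel]
    cx <- pmin(floor(s$x_px[sel] / square_px), ncol(cover$grid) - 1L)
    cy <- pmin(floor(s$y_px[sel] / square_px), nrow(cover$grid) - 1L)
    first <- !duplicated(cx + ncol(cover$grid) * cy)
    t <- t[first]; cx <- as.integer(cx[first]); cy <- as.integer(cy[first])
    area <- cover$cell_w[cx + 1L] * cover$cell_h[cy + 1L]
    frac <- cumsum(area) / (w * h)
    hit <- which(frac >= stop_fraction)
    if (length(hit)) {
      keep <- seq_len(hit[1])
      t_stop <- t[hit[1]]
      end_reason <- "fraction_reached"
    } else {
      keep <- seq_along(t)
    }
    events <- tibble::tibble(t_ms = t[keep], cell_x = cx[keep],
                             cell_y = cy[keep])
    cover$grid[cbind(events$cell_y + 1L, events$cell_x + 1L)] <- FALSE
  }

  structure(
    list(
      stimulus = stimulus,
      schedule = list(
        baseline_on = 0, transition_on = baseline_ms,
        contingent_on = contingent_on, t_stop = t_stop,
        disruption_off = t_stop + disruption_ms
      ),
      cover_at_disruption = cover,
      end_reason = end_reason,
      uncover_events = events,
      uncovered_fraction = uncovered_fraction(cover)
    ),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "<trial_record> %s | contingent [%g, %g) ms, %s, %.1f%% uncovered, %d uncover events\n",
    x$stimulus$stimulus_id, x$schedule$contingent_on, x$schedule$t_stop,
    x$end_reason, 100 * x$uncovered_fraction, nrow(x$uncover_events)
  ))
  invisible(x)
}

#' Region of object parts currently visible through the cover
#'
#' Intersects the uncovered cover cells with the stimulus' two object
#' rectangles. With a fresh cover the region is empty; with a fully cleared
#' cover its area equals the total object area.
#'
#' @param cover a `cover_state`.
#' @param stimulus a single row of a `stimulus_set`.
#' @return An object of class `visible_region`: a tibble of intersection
#'   rectangles and their total `area` in px^2.
#' @export
visible_object_region <- function(cover, stimulus) {
  open <- which(!cover$grid, arr.ind = TRUE)
  rects <- tibble::tibble(x0 = numeric(0), y0 = numeric(0),
                          x1 = numeric(0), y1 = numeric(0))
  if (nrow(open)) {
    cx0 <- (open[, "col"] - 1) * cover$square_px
    cy0 <- (open[, "row"] - 1) * cover$square_px
    cx1 <- cx0 + cover$cell_w[open[, "col"]]
    cy1 <- cy0 + cover$cell_h[open[, "row"]]
    obj <- object_rects(stimulus)
    for (k in seq_len(nrow(obj))) {
      x0 <- pmax(cx0, obj$x0[k]); x1 <- pmin(cx1, obj$x1[k])
      y0 <- pmax(cy0, obj$y0[k]); y1 <- pmin(cy1, obj$y1[k])
      pos <- x1 > x0 & y1 > y0
      if (any(pos)) {
        rects <- rbind(rects, tibble::tibble(x0 = x0[pos], y0 = y0[pos],
                                             x1 = x1[pos], y1 = y1[pos]))
      }
    }
  }
  structure(list(rects = rects,
                 area = sum((rects$x1 - rects$x0) * (rects$y1 - rects$y0))),
            class = "visible_region")
}

#' @export
print.visible_region <- function(x, ...) {
  cat(sprintf("<visible_region> %d rects, %.0f px^2\n", nrow(x$rects), x$area))
  invisible(x)
}

#' Test whether points fall inside a visible region
#'
#' @param region a [visible_object_region()] result.
#' @param x,y coordinate vectors in pixels.
#' @return Logical vector; half-open rectangle membership.
#' @export
region_contains <- function(region, x, y) {
  out <- rep(FALSE, length(x))
  r <- region$rects
  for (k in seq_len(nrow(r))) {
    out <- out | (x >= r$x0[k] & x < r$x1[k] & y >= r$y0[k] & y < r$y1[k])
  }
  out & !is.na(x) & !is.na(y)
}
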
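#' Build the four-quadrant AOI layout for one image condition
#'
#' The screen is tiled by four half-open rectangles (one per corner), defined
#' by a single vertical and a single horizontal split line. The two quadrants
#' on one diagonal contain the objects: top-left and bottom-right for the
#' `drop` condition, bottom-left and top-right for `rise`. The split lines are
#' shifted symmetrically off-center so that the two object quadrants cover
#' exactly `object_area_fraction` of the screen (default 0.5572, i.e. about
#' half of the screen, slightly more than half).
#'
#' For a requested fraction `f >= 0.5` the relative splits are
#' `a = 1/2 + d` in both x and y with `d = sqrt((f - 1/2)/2)`, giving object
#' quadrant areas `a^2 + (1-a)^2 = f`. For `f < 0.5` the offsets have equal
#' magnitude and opposite sign (`a_x = 1/2 + d`, `a_y = 1/2 - d`), giving
#' `2(1/4 - d^2) = f`. The `rise` layout is the mirror image of `drop` across
#' the vertical midline.
#'
#' @param screen_w,screen_h screen size in pixels (> 0).
#' @param object_area_fraction fraction of screen area covered by the two
#'   object quadrants, in (0, 1).
#' @param condition `"drop"` (objects top-left / bottom-right) or `"rise"`
#'   (bottom-left / top-right).
#' @return An object of class `aoi_layout`: the four quadrant rectangles
#'   (half-open, `[x0, x1) x [y0, y1)`, origin top-left, y down), the object
#'   quadrant names, and the realized object-area fraction.
#' @export
build_aoi_layout <- function(screen_w, screen_h,
                             object_area_fraction = 0.5572,
                             condition = c("drop", "rise")) {
  condition <- match.arg(condition)
  if (screen_w <= 0 || screen_h <= 0) {
    stop("screen dimensions must be positive", call. = FALSE)
  }
  f <- object_area_fraction
  if (!is.finite(f) || f <= 0 || f >= 1) {
    stop("object_area_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (f >= 0.5) {
    d <- sqrt((f - 0.5) / 2)
    ax <- 0.5 + d
    ay <- 0.5 + d
  } else {
    d <- sqrt((0.5 - f) / 2)
    ax <- 0.5 + d
    ay <- 0.5 - d
  }
  # drop: splits at (ax, ay); rise: mirrored across the vertical midline
  if (condition == "drop") {
    xs <- screen_w * ax
  } else {
    xs <- screen_w * (1 - ax)
  }
  ys <- screen_h * ay
  rects <- tibble::tibble(
    quadrant = c("TL", "TR", "BL", "BR"),
    x0 = c(0, xs, 0, xs),
    y0 = c(0, 0, ys, ys),
    x1 = c(xs, screen_w, xs, screen_w),
    y1 = c(ys, ys, screen_h, screen_h)
  )
  object_quadrants <- if (condition == "drop") c("TL", "BR") else c("BL", "TR")
  area <- (rects$x1 - rects$x0) * (rects$y1 - rects$y0)
  realized <- sum(area[rects$quadrant %in% object_quadrants]) / (screen_w * screen_h)
  structure(
    list(
      screen_w = screen_w, screen_h = screen_h,
      condition = condition,
      x_split = xs, y_split = ys,
      rects = rects,
      object_quadrants = object_quadrants,
      object_area_fraction = realized
    ),
    class = "aoi_layout"
  )
}

#' @export
print.aoi_layout <- function(x, ...) {
  cat(sprintf(
    "<aoi_layout> %gx%g px, condition %s, object quadrants %s (%.4f of screen)\n",
    x$screen_w, x$screen_h, x$condition,
    paste(x$object_quadrants, collapse = "+"), x$object_area_fraction
  ))
  invisible(x)
}

#' Assign screen points to AOI quadrants
#'
#' @param layout an [build_aoi_layout()] object.
#' @param x,y coordinate vectors in pixels.
#' @return Character vector of quadrant names (`"TL"`, `"TR"`, `"BL"`, `"BR"`),
#'   `NA` for points off screen. Half-open convention: a point exactly on a
#'   split line belongs to the right/bottom quadrant.
#' @export
aoi_of_point <- function(layout, x, y) {
  on <- !is.na(x) & !is.na(y) &
    x >= 0 & x < layout$screen_w & y >= 0 & y < layout$screen_h
  left <- x < layout$x_split
  top <- y < layout$y_split
  out <- ifelse(top, ifelse(left, "TL", "TR"), ifelse(left, "BL", "BR"))
  out[!on] <- NA_character_
  out
}

#' Generate a counterbalanced stimulus set
#'
#' Creates `2 * n_pairs` stimulus specifications: every object pair occurs
#' once in each condition (drop / rise) with the same background in both.
#' The specs are split into two presentation sets (`A` / `B`) of `n_pairs`
#' stimuli each, with `n_pairs / 2` per condition in each set, so that over
#' the two sets every (pair, condition) combination occurs exactly once.
#' Within a set, conditions alternate in presentation order. With the default
#' 16 pairs and 16 backgrounds this yields the full 32-image design.
#'
#' Object rectangles are squares of `object_square_frac * screen_h` pixels,
#' centered in the two object quadrants of the condition's AOI layout.
#'
#' @param n_pairs,n_backgrounds number of object pairs and backgrounds; must
#'   be equal. An odd `n_pairs` still returns all specs but cannot be split
#'   into balanced sets (`set_id` is `NA`, with a warning).
#' @param seed integer; fixes the pair-background assignment.
#' @param screen_w,screen_h screen size in pixels.
#' @param object_area_fraction passed to [build_aoi_layout()].
#' @param object_square_frac object square side as a fraction of screen height.
#' @return A tibble of class `stimulus_set`, one row per stimulus:
#'   `stimulus_id`, `pair_id`, `background_id`, `condition`, `set_id`,
#'   `order_in_set`, screen geometry, and the two object rectangles
#'   (`obj1_x0` ... `obj2_y1`).
#' @export
generate_stimulus_set <- function(n_pairs = 16, n_backgrounds = 16, seed = 1,
                                  screen_w = 1920, screen_h = 1080,
                                  object_area_fraction = 0.5572,
                                  object_square_frac = 0.15) {
  if (n_pairs != n_backgrounds) {
    stop("n_pairs must equal n_backgrounds (one background per pair)",
         call. = FALSE)
  }
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  bg_of_pair <- with_seed(seed, sample.int(n_backgrounds))

  specs <- tibble::tibble(
    pair_id = rep(seq_len(n_pairs), each = 2),
    background_id = rep(bg_of_pair, each = 2),
    condition = rep(c("drop", "rise"), times = n_pairs)
  )

  balanced <- n_pairs %% 2 == 0
  if (!balanced) {
    warning("odd n_pairs: presentation sets cannot be balanced; set_id is NA",
            call. = FALSE)
    specs$set_id <- NA_character_
    specs$order_in_set <- NA_integer_
  } else {
    # Pair i contributes drop to set A if i is odd, rise if even (and the
    # opposite to set B); ordering by pair index alternates conditions.
    odd <- specs$pair_id %% 2 == 1
    in_a <- (odd & specs$condition == "drop") | (!odd & specs$condition == "rise")
    specs$set_id <- ifelse(in_a, "A", "B")
    specs$order_in_set <- NA_integer_
    for (s in c("A", "B")) {
      idx <- which(specs$set_id == s)
      specs$order_in_set[idx[order(specs$pair_id[idx])]] <- seq_along(idx)
    }
  }

  specs$screen_w <- screen_w
  specs$screen_h <- screen_h
  specs$object_area_fraction <- object_area_fraction

  side <- object_square_frac * screen_h
  o1 <- matrix(NA_real_, nrow(specs), 4)
  o2 <- matrix(NA_real_, nrow(specs), 4)
  for (cond in c("drop", "rise")) {
    lay <- build_aoi_layout(screen_w, screen_h, object_area_fraction, cond)
    rr <- lay$rects[match(lay$object_quadrants, lay$rects$quadrant), ]
    cx <- (rr$x0 + rr$x1) / 2
    cy <- (rr$y0 + rr$y1) / 2
    rows <- specs$condition == cond
    o1[rows, ] <- matrix(c(cx[1] - side / 2, cy[1] - side / 2,
                           cx[1] + side / 2, cy[1] + side / 2),
                         sum(rows), 4, byrow = TRUE)
    o2[rows, ] <- matrix(c(cx[2] - side / 2, cy[2] - side / 2,
                           cx[2] + side / 2, cy[2] + side / 2),
                         sum(rows), 4, byrow = TRUE)
  }
  specs$obj1_x0 <- o1[, 1]; specs$obj1_y0 <- o1[, 2]
  specs$obj1_x1 <- o1[, 3]; specs$obj1_y1 <- o1[, 4]
  specs$obj2_x0 <- o2[, 1]; specs$obj2_y0 <- o2[, 2]
  specs$obj2_x1 <- o2[, 3]; specs$obj2_y1 <- o2[, 4]
  specs$stimulus_id <- sprintf("p%02d_%s", specs$pair_id, specs$condition)
  specs <- specs[, c("stimulus_id", "pair_id", "background_id", "condition",
                     "set_id", "order_in_set", "screen_w", "screen_h",
                     "object_area_fraction",
                     "obj1_x0", "obj1_y0", "obj1_x1", "obj1_y1",
                     "obj2_x0", "obj2_y0", "obj2_x1", "obj2_y1")]
  class(specs) <- c("stimulus_set", class(specs))
  specs
}

#' Object rectangles of one stimulus
#'
#' @param spec a single row of a `stimulus_set`.
#' @return Tibble with columns `x0, y0, x1, y1` (two rows).
#' @export
object_rects <- function(spec) {
  stopifnot(nrow(spec) == 1)
  tibble::tibble(
    x0 = c(spec$obj1_x0, spec$obj2_x0),
    y0 = c(spec$obj1_y0, spec$obj2_y0),
    x1 = c(spec$obj1_x1, spec$obj2_x1),
    y1 = c(spec$obj1_y1, spec$obj2_y1)
  )
}

#' AOI layout for a stimulus row
#' @param spec a single row of a `stimulus_set`.
#' @return The [build_aoi_layout()] object for this stimulus' condition.
#' @export
layout_for_stimulus <- function(spec) {
  stopifnot(nrow(spec) == 1)
  build_aoi_layout(spec$screen_w, spec$screen_h, spec$object_area_fraction,
                   spec$condition)
}
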
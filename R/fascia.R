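# Fascia detection, spline reconnection and sub-fascial ROI restriction.
#
# The appendix sits below the bottom fascia line, so the binarized frame is
# searched for horizontally long thin objects (the fascia/abdominal-wall
# band), their lower boundaries are joined by a cubic spline across gaps, and
# everything at or above the reconstructed line is excluded from the appendix
# search.

#' Keep binarized objects that look like fascia segments
#'
#' Fascia appears as a horizontally long thin object: a segment is kept when
#' its bounding-box width exceeds `min_width_fraction` of the ROI width
#' (length rule) and its elongation (bbox width / height) is at least
#' `min_elongation` (thinness rule).
#'
#' @param objects List of `object_region` (from [label_objects()]).
#' @param roi_width ROI width in pixels (`>= 3`).
#' @param min_width_fraction Length rule threshold, default `1/3`.
#' @param min_elongation Thinness rule threshold, default 4.
#' @return The surviving objects, input order preserved (possibly empty).
#' @export
detect_fascia_segments <- function(objects, roi_width,
                                   min_width_fraction = 1 / 3,
                                   min_elongation = 4) {
  stopifnot(roi_width >= 3)
  keep <- vapply(objects, function(o) {
    o$bbox_width > roi_width * min_width_fraction &&
      o$elongation >= min_elongation
  }, logical(1L))
  objects[keep]
}

# lower boundary of a region: for every column of its bbox with pixels, the
# largest row; returns a data.frame(col, row) ordered by col
lower_boundary <- function(region) {
  rc <- arrayInd(region$pixel_idx, region$dims)
  rows <- tapply(rc[, 1L], rc[, 2L], max)
  data.frame(col = as.integer(names(rows)), row = as.numeric(rows))
}

new_fascia_line <- function(knots, cols, rows) {
  structure(
    list(knots = knots, cols = cols, rows = rows,
         span = c(cols[1L], cols[length(cols)])),
    class = "fascia_line"
  )
}

#' @export
print.fascia_line <- function(x, ...) {
  cat(sprintf("<fascia_line> cols %d..%d, %d knots, mean row %.1f\n",
              x$span[1L], x$span[2L], nrow(x$knots), mean(x$rows)))
  invisible(x)
}

#' Reconnect fascia segments with a cubic spline
#'
#' Knots are sampled along each segment's lower boundary (every `knot_step`
#' columns plus both segment endpoints); a cubic spline through the knots
#' (Forsythe-Malcolm-Moler end conditions, which reproduce polynomial trends
#' up to cubics exactly) fills the gaps between segments. A single segment
#' passes its lower boundary through unchanged.
#'
#' @param segments List of `object_region` fascia segments (`>= 1`).
#' @param knot_step Column step between interior knots, default 10.
#' @return A `fascia_line`: `knots` (data.frame `col`, `row`), per-column
#'   `rows` spanning the leftmost to rightmost segment column, `span`.
#' @export
fit_fascia_spline <- function(segments, knot_step = 10) {
  if (length(segments) == 0L) stop("no fascia found")

  if (length(segments) == 1L) {
    lb <- lower_boundary(segments[[1L]])
    cols <- lb$col[1L]:lb$col[nrow(lb)]
    # fill any missing columns inside the bbox by linear interpolation
    rows <- stats::approx(lb$col, lb$row, xout = cols, rule = 2)$y
    return(new_fascia_line(lb, cols, rows))
  }

  knots <- do.call(rbind, lapply(segments, function(s) {
    lb <- lower_boundary(s)
    n <- nrow(lb)
    take <- sort(unique(c(seq(1L, n, by = knot_step), n)))
    lb[take, , drop = FALSE]
  }))
  # strictly increasing columns: where segments overlap, keep the lowest
  # (largest-row) boundary, since it is the one bounding the appendix region
  row_by_col <- tapply(knots$row, knots$col, max)
  knots <- data.frame(col = as.integer(names(row_by_col)),
                      row = as.numeric(row_by_col))
  knots <- knots[order(knots$col), , drop = FALSE]
  fascia_spline_from_knots(knots)
}

#' Cubic-spline fascia line through given knots
#'
#' The interpolation core of [fit_fascia_spline()]: a cubic spline through
#' `(col, row)` knots, evaluated at every integer column between the first
#' and last knot. The spline passes through every knot exactly and, thanks
#' to the Forsythe-Malcolm-Moler end conditions, reproduces knot data lying
#' on a polynomial of degree up to three exactly.
#'
#' @param knots data.frame with numeric `col` (strictly increasing) and
#'   `row` columns; at least 2 knots.
#' @return A `fascia_line`.
#' @export
fascia_spline_from_knots <- function(knots) {
  stopifnot(is.data.frame(knots), all(c("col", "row") %in% names(knots)))
  knots <- knots[order(knots$col), , drop = FALSE]
  if (nrow(knots) < 2L) stop("not enough fascia knots for interpolation")
  if (any(diff(knots$col) <= 0)) stop("knot columns must be strictly increasing")
  f <- stats::splinefun(knots$col, knots$row, method = "fmm")
  cols <- as.integer(ceiling(knots$col[1L])):as.integer(floor(knots$col[nrow(knots)]))
  new_fascia_line(knots, cols, f(cols))
}

#' Select the bottom fascia line
#'
#' The appendix is searched below the lowest (on screen: largest mean row)
#' fascia line.
#'
#' @param lines Non-empty list of `fascia_line` objects.
#' @return The line with the largest mean row.
#' @export
select_bottom_fascia <- function(lines) {
  if (length(lines) == 0L) stop("no fascia lines given")
  means <- vapply(lines, function(l) mean(l$rows), numeric(1L))
  lines[[which.max(means)]]
}

#' Row of a fascia line at given columns (nearest column outside its span)
#'
#' @param line A `fascia_line`.
#' @param col Column index vector.
#' @export
fascia_row_at <- function(line, col) {
  col <- pmin(pmax(col, line$span[1L]), line$span[2L])
  line$rows[col - line$span[1L] + 1L]
}

#' Restrict the search region to below the fascia line
#'
#' Marks every pixel at or above the fascia line (plus a safety margin) as
#' invalid; columns outside the line's span use the nearest defined fascia
#' row. All later stages only consider valid pixels.
#'
#' @param image A [gray_image()].
#' @param fascia A `fascia_line` (rows within the image).
#' @param margin Extra rows removed below the line, default 3.
#' @return List with `image` (unchanged) and `validity`, a logical matrix
#'   (TRUE = usable pixel).
#' @export
restrict_below_fascia <- function(image, fascia, margin = 3) {
  d <- dim(image$pixels)
  if (any(fascia$rows < 1) || any(fascia$rows > d[1L])) {
    stop("fascia line lies outside the image")
  }
  cut <- fascia_row_at(fascia, seq_len(d[2L])) + margin
  rowidx <- matrix(seq_len(d[1L]), d[1L], d[2L])
  validity <- rowidx > matrix(cut, d[1L], d[2L], byrow = TRUE)
  if (!any(validity)) stop("empty search region below fascia")
  list(image = image, validity = validity)
}
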
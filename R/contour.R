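# 8-directional (Moore) contour tracing and 8-connected object labeling.
#
# Convention used throughout: clockwise tracing (rows increase downward),
# start pixel found by row-major scan (smallest row, then smallest column),
# grid border treated as background so border-touching objects still yield
# closed contours.

# neighbour offsets in clockwise order starting West
.moore_off <- matrix(c(
   0L, -1L,   # W
  -1L, -1L,   # NW
  -1L,  0L,   # N
  -1L,  1L,   # NE
   0L,  1L,   # E
   1L,  1L,   # SE
   1L,  0L,   # S
   1L, -1L),  # SW
  ncol = 2L, byrow = TRUE)

# direction index (1..8) of a unit offset (dr, dc)
.moore_dir <- local({
  m <- matrix(NA_integer_, 3L, 3L)
  for (k in 1:8) m[.moore_off[k, 1L] + 2L, .moore_off[k, 2L] + 2L] <- k
  m
})

new_contour <- function(points, closed) {
  structure(list(points = points, closed = closed), class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d points, %s\n", nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' @export
as.data.frame.contour <- function(x, ...) {
  data.frame(row = x$points[, 1L], col = x$points[, 2L])
}

#' Moore-neighbour contour tracing with Jacob's stopping criterion
#'
#' Follows the boundary of the 8-connected component containing `start`
#' clockwise, scanning the Moore neighbourhood from the backtrack position.
#' Tracing terminates when the start pixel is re-entered from the initial
#' backtrack position (Jacob's criterion), which avoids premature termination
#' on one-pixel spurs. An isolated pixel yields a single-point closed contour.
#'
#' @param mask Logical/0-1 matrix.
#' @param start `(row, col)` of a foreground boundary pixel; defaults to the
#'   first foreground pixel in row-major scan order.
#' @param backtrack Optional `(row, col)` of a background 8-neighbour of
#'   `start` fixing the initial scan position; defaults to the first
#'   background neighbour clockwise from West.
#' @return A `contour` object: `points` (n x 2 matrix of `(row, col)`),
#'   `closed` flag. The traced point set equals the set of component pixels
#'   that touch the outer background; pixels may repeat along spurs.
#' @export
trace_contour <- function(mask, start = NULL, backtrack = NULL) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]

  if (is.null(start)) {
    idx <- which(t(mask))   # row-major scan
    if (!length(idx)) stop("mask has no foreground pixel")
    k <- idx[1L]
    start <- c((k - 1L) %/% nc + 1L, (k - 1L) %% nc + 1L)
  }
  start <- as.integer(start)
  if (!fg(start[1L], start[2L])) stop("start is not a foreground pixel")

  if (is.null(backtrack)) {
    b_dir <- NA_integer_
    for (k in 1:8) {
      nb <- start + .moore_off[k, ]
      if (!fg(nb[1L], nb[2L])) { b_dir <- k; break }
    }
    if (is.na(b_dir)) stop("start is not a boundary pixel (no background 8-neighbour)")
  } else {
    off <- as.integer(backtrack) - start
    b_dir <- .moore_dir[off[1L] + 2L, off[2L] + 2L]
    if (is.na(b_dir)) stop("backtrack must be an 8-neighbour of start")
    if (fg(start[1L] + off[1L], start[2L] + off[2L])) {
      stop("backtrack must be a background pixel")
    }
  }

  # isolated pixel?
  if (!any(vapply(1:8, function(k) {
    nb <- start + .moore_off[k, ]
    fg(nb[1L], nb[2L])
  }, logical(1L)))) {
    return(new_contour(matrix(start, ncol = 2L), closed = TRUE))
  }

  pts_r <- integer(256L); pts_c <- integer(256L); np <- 0L
  push <- function(r, c) {
    np <<- np + 1L
    if (np > length(pts_r)) {
      length(pts_r) <<- 2L * length(pts_r)
      length(pts_c) <<- 2L * length(pts_c)
    }
    pts_r[np] <<- r; pts_c[np] <<- c
  }
  push(start[1L], start[2L])

  p <- start; dir_b <- b_dir
  init_p <- start; init_b <- b_dir
  # Jacob's criterion (re-entering the start from the initial backtrack)
  # is the primary stop; a visited-state set catches the rare case where
  # the trace's cycle passes the start with a different backtrack than the
  # arbitrary initial one.
  seen <- new.env(hash = TRUE, parent = emptyenv())
  state_key <- function(r, c, b) paste(r, c, b, sep = ",")
  assign(state_key(start[1L], start[2L], b_dir), TRUE, envir = seen)
  max_iter <- 8L * (sum(mask) + 4L) + 64L
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) stop("contour tracing failed to terminate")
    found <- FALSE
    for (k in 1:8) {
      d <- ((dir_b - 1L + k) %% 8L) + 1L
      nb_r <- p[1L] + .moore_off[d, 1L]
      nb_c <- p[2L] + .moore_off[d, 2L]
      if (fg(nb_r, nb_c)) {
        d_prev <- ((dir_b - 1L + k - 1L) %% 8L) + 1L
        bt_r <- p[1L] + .moore_off[d_prev, 1L]
        bt_c <- p[2L] + .moore_off[d_prev, 2L]
        # backtrack direction as seen from the new pixel
        new_b <- .moore_dir[bt_r - nb_r + 2L, bt_c - nb_c + 2L]
        p <- c(nb_r, nb_c); dir_b <- new_b
        found <- TRUE
        break
      }
    }
    if (!found) stop("internal error: no foreground neighbour during tracing")
    if (p[1L] == init_p[1L] && p[2L] == init_p[2L] && dir_b == init_b) break
    key <- state_key(p[1L], p[2L], dir_b)
    if (exists(key, envir = seen, inherits = FALSE)) break
    assign(key, TRUE, envir = seen)
    push(p[1L], p[2L])
  }
  new_contour(cbind(row = pts_r[seq_len(np)], col = pts_c[seq_len(np)]),
              closed = TRUE)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels that
# touch diagonally with a union-find pass over the (small) label graph.
label_mask8 <- function(mask) {
  mask <- mask != 0
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(lab)
  if (nlab <= 1L) return(list(labels = lab, n = nlab))
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]    # SE diagonal
  a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]    # SW diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  parent <- seq_len(nlab)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1L]); rb <- find(pairs[i, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1L))
  remap <- match(roots, sort(unique(roots)))
  lab2 <- matrix(0L, nr, nc)
  nz <- lab > 0
  lab2[nz] <- remap[lab[nz]]
  list(labels = lab2, n = max(remap))
}

new_object_region <- function(contour, pixel_idx, bbox, mean_intensity, dims) {
  bbox_width <- bbox[4L] - bbox[2L] + 1L
  bbox_height <- bbox[3L] - bbox[1L] + 1L
  structure(
    list(contour = contour,
         pixel_count = length(pixel_idx),
         bbox = bbox,                       # (row0, col0, row1, col1), closed
         bbox_width = bbox_width,
         bbox_height = bbox_height,
         elongation = bbox_width / bbox_height,
         mean_intensity = mean_intensity,
         pixel_idx = pixel_idx,
         dims = dims),
    class = "object_region"
  )
}

#' @export
print.object_region <- function(x, ...) {
  cat(sprintf(
    "<object_region> %d px, bbox rows %d..%d cols %d..%d (W=%d H=%d, elong %.2f)%s\n",
    x$pixel_count, x$bbox[1L], x$bbox[3L], x$bbox[2L], x$bbox[4L],
    x$bbox_width, x$bbox_height, x$elongation,
    if (is.na(x$mean_intensity)) "" else
      sprintf(", mean intensity %.1f", x$mean_intensity)))
  invisible(x)
}

# logical mask of one region within its frame
region_mask <- function(region) {
  m <- matrix(FALSE, region$dims[1L], region$dims[2L])
  m[region$pixel_idx] <- TRUE
  m
}

#' Label 8-connected foreground objects and compute shape metrics
#'
#' @param mask Logical/0-1 matrix.
#' @param image Optional [gray_image()] (or matrix) from which each object's
#'   mean intensity is taken.
#' @param trace If `TRUE` (default), each object's outer contour is traced
#'   with [trace_contour()]; set `FALSE` to skip tracing when only the
#'   metrics are needed.
#' @return List of `object_region` objects, ordered by bounding-box top row,
#'   then left column. Each has `contour`, `pixel_count`, `bbox`
#'   (`(row0, col0, row1, col1)`, closed), `bbox_width`, `bbox_height`,
#'   `elongation` (= width/height) and `mean_intensity`.
#' @export
label_objects <- function(mask, image = NULL, trace = TRUE) {
  mask <- mask != 0
  lab <- label_mask8(mask)
  if (lab$n == 0L) return(list())
  px <- if (inherits(image, "gray_image")) image$pixels else image
  dims <- dim(mask)

  idx_by_lab <- split(which(lab$labels > 0), lab$labels[lab$labels > 0])
  regions <- lapply(idx_by_lab, function(idx) {
    rc <- arrayInd(idx, dims)
    bbox <- c(min(rc[, 1L]), min(rc[, 2L]), max(rc[, 1L]), max(rc[, 2L]))
    mi <- if (is.null(px)) NA_real_ else mean(px[idx])
    ct <- NULL
    if (trace) {
      # start at the component's topmost-leftmost pixel
      ord <- order(rc[, 1L], rc[, 2L])[1L]
      comp <- matrix(FALSE, dims[1L], dims[2L])
      comp[idx] <- TRUE
      ct <- trace_contour(comp, start = rc[ord, ])
    }
    new_object_region(ct, idx, bbox, mi, dims)
  })
  ord <- order(vapply(regions, function(r) r$bbox[1L], numeric(1L)),
               vapply(regions, function(r) r$bbox[2L], numeric(1L)))
  unname(regions[ord])
}

#' Trace every boundary of every object, including hole boundaries
#'
#' For each 8-connected foreground component, returns the outer contour plus
#' one inner contour per enclosed hole (4-connected background regions not
#' touching the grid border). On jagged 8-connected shapes a single Moore
#' cycle can skip inner-corner pixels (the clockwise scan takes a diagonal
#' shortcut), so any boundary pixel left uncovered seeds a further trace
#' until the union of the traced point sets is exactly the set of foreground
#' pixels with at least one background 8-neighbour.
#'
#' @param mask Logical/0-1 matrix.
#' @return List (one element per component, in [label_objects()] order) of
#'   lists of `contour` objects; the first contour of each component is the
#'   outer boundary.
#' @export
trace_object_boundaries <- function(mask) {
  mask <- mask != 0
  lab <- label_mask8(mask)
  if (lab$n == 0L) return(list())
  dims <- dim(mask)

  # holes: 4-connected background components not touching the border
  bg <- label_mask8_bg4(!mask)
  border_labs <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  hole_labs <- setdiff(setdiff(unique(as.vector(bg)), 0L), border_labs)

  idx_by_lab <- split(which(lab$labels > 0), lab$labels[lab$labels > 0])
  comp_of <- lab$labels
  out <- lapply(idx_by_lab, function(idx) {
    rc <- arrayInd(idx, dims)
    ord <- order(rc[, 1L], rc[, 2L])[1L]
    comp <- matrix(FALSE, dims[1L], dims[2L])
    comp[idx] <- TRUE
    list(trace_contour(comp, start = rc[ord, ]))
  })

  for (h in hole_labs) {
    hidx <- which(bg == h)
    rc <- arrayInd(hidx, dims)
    o <- order(rc[, 1L], rc[, 2L])[1L]
    hr <- rc[o, 1L]; hc <- rc[o, 2L]
    # the pixel above the hole's topmost-leftmost pixel is foreground
    start <- c(hr - 1L, hc)
    comp_lab <- comp_of[start[1L], start[2L]]
    comp <- matrix(FALSE, dims[1L], dims[2L])
    comp[idx_by_lab[[comp_lab]]] <- TRUE
    ct <- trace_contour(comp, start = start, backtrack = c(hr, hc))
    out[[comp_lab]] <- c(out[[comp_lab]], list(ct))
  }

  # restart pass: seed extra traces from boundary pixels the Moore cycles
  # skipped (diagonal shortcuts at inner corners)
  for (comp_lab in seq_along(idx_by_lab)) {
    comp <- matrix(FALSE, dims[1L], dims[2L])
    comp[idx_by_lab[[comp_lab]]] <- TRUE
    target <- boundary_mask(comp)
    covered <- matrix(FALSE, dims[1L], dims[2L])
    for (ct in out[[comp_lab]]) covered[ct$points] <- TRUE
    repeat {
      left <- which(t(target & !covered))   # row-major
      if (!length(left)) break
      k <- left[1L]
      start <- c((k - 1L) %/% dims[2L] + 1L, (k - 1L) %% dims[2L] + 1L)
      ct <- trace_contour(comp, start = start)
      covered[ct$points] <- TRUE
      out[[comp_lab]] <- c(out[[comp_lab]], list(ct))
    }
  }

  ord <- order(
    vapply(idx_by_lab, function(idx) min(arrayInd(idx, dims)[, 1L]), numeric(1L)),
    vapply(idx_by_lab, function(idx) min(arrayInd(idx, dims)[, 2L]), numeric(1L)))
  unname(out[ord])
}

# plain 4-connected labeling of a logical mask (for hole detection)
label_mask8_bg4 <- function(mask) {
  EBImage::imageData(EBImage::bwlabel(EBImage::Image((mask != 0) * 1)))
}
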
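# Appendix candidate selection, measurement and shape-brightness
# classification on the quantized sub-fascial region.

#' Select the hypoechoic band of a quantized image
#'
#' The appendix lumen is hypoechoic (dark) in all four clinically observed
#' shape-brightness patterns, so the candidate foreground is the set of valid
#' pixels whose quantized level is among the `n_levels` darkest codebook
#' levels present in the valid region. When fewer distinct levels than
#' `n_levels` are present, all levels below the median level are used; a
#' uniform region yields an empty mask with a warning.
#'
#' @param quantized A [gray_image()] from [som_quantize()].
#' @param validity Logical matrix of usable pixels.
#' @param n_levels Number of darkest levels to keep, default 4.
#' @return Logical foreground mask.
#' @export
select_appendix_band <- function(quantized, validity, n_levels = 4) {
  px <- quantized$pixels
  stopifnot(identical(dim(validity), dim(px)))
  vals <- px[validity]
  levels <- sort(unique(vals))
  if (length(levels) < n_levels) {
    sel <- levels[levels < stats::median(levels)]
  } else {
    sel <- levels[seq_len(n_levels)]
  }
  if (length(sel) == 0L) {
    warning("quantized region has too few levels; empty candidate mask")
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  validity & matrix(px %in% sel, nrow(px), ncol(px))
}

# convex-hull solidity of a pixel set: pixel count over hull area, with the
# hull polygon area corrected from vertex-center to pixel coverage (Pick)
region_solidity <- function(region) {
  rc <- arrayInd(region$pixel_idx, region$dims)
  if (nrow(rc) < 3L) return(1)
  pts <- unique(rc)
  if (nrow(pts) < 3L) return(1)
  h <- grDevices::chull(pts[, 2L], pts[, 1L])
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3L) return(1)
  x <- hp[, 2L]; y <- hp[, 1L]
  area <- abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  per <- sum(sqrt(diff(c(x, x[1L]))^2 + diff(c(y, y[1L]))^2))
  min(1, region$pixel_count / max(1, area + per / 2 + 1))
}

#' Filter candidate objects by physical size and shape
#'
#' The appendix outer diameter is typically 6-12 mm and its shape a circle or
#' flat oval, so candidates are kept when their minor bounding-box dimension
#' in millimetres lies in `[min_d_mm, max_d_mm]` (padded around the clinical
#' range to tolerate segmentation bias), their pixel area reaches
#' `min_area_px`, and their convex solidity reaches `min_solidity`.
#'
#' @param objects List of `object_region`.
#' @param spacing Pixel spacing in mm/pixel, `> 0`.
#' @param min_d_mm,max_d_mm Bounds on the minor bbox dimension, default 3-15.
#' @param min_area_px Minimum pixel count, default 100.
#' @param min_solidity Minimum convex solidity, default 0.4.
#' @return Survivors ranked by pixel area, largest first.
#' @export
filter_candidates <- function(objects, spacing, min_d_mm = 3, max_d_mm = 15,
                              min_area_px = 100, min_solidity = 0.4) {
  stopifnot(spacing > 0)
  keep <- vapply(objects, function(o) {
    if (o$pixel_count < min_area_px) return(FALSE)
    minor_mm <- min(o$bbox_width, o$bbox_height) * spacing
    if (minor_mm < min_d_mm || minor_mm > max_d_mm) return(FALSE)
    region_solidity(o) >= min_solidity
  }, logical(1L))
  kept <- objects[keep]
  kept[order(vapply(kept, function(o) o$pixel_count, numeric(1L)),
             decreasing = TRUE)]
}

new_appendix_result <- function(mask = NULL, contour = NULL,
                                diameter_mm = NA_real_, length_mm = NA_real_,
                                over_6mm = NA, pattern = "unknown",
                                success = FALSE, failure_reason = NA_character_) {
  structure(
    list(mask = mask, contour = contour, diameter_mm = diameter_mm,
         length_mm = length_mm, over_6mm = over_6mm, pattern = pattern,
         success = success, failure_reason = failure_reason),
    class = "appendix_result"
  )
}

#' @export
print.appendix_result <- function(x, ...) {
  if (x$success) {
    cat(sprintf(
      "<appendix_result> diameter %.2f mm, length %.2f mm, %s 6 mm criterion, pattern %s\n",
      x$diameter_mm, x$length_mm,
      if (isTRUE(x$over_6mm)) "MEETS" else "below", x$pattern))
  } else {
    cat(sprintf("<appendix_result> extraction failed: %s\n",
                x$failure_reason))
  }
  invisible(x)
}

#' Serialize an appendix result as JSON
#'
#' @param x An `appendix_result`.
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
result_json <- function(x, path = NULL) {
  rec <- list(success = x$success, diameter_mm = x$diameter_mm,
              length_mm = x$length_mm, over_6mm = x$over_6mm,
              pattern = x$pattern, failure_reason = x$failure_reason)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Refine a candidate and measure it in millimetres
#'
#' Fills holes in the candidate component (the appendix wall can binarize as
#' a ring), re-traces its boundary with [trace_contour()], and measures the
#' best-fit ellipse from the second moments of the filled pixel set: with
#' eigenvalues `l1 >= l2` of the coordinate covariance, the full axis lengths
#' are `4 sqrt(l1)` and `4 sqrt(l2)` pixels. `diameter_mm` is the minor axis
#' times the pixel spacing (robust on hooked shapes, where the tube width -
#' not the bend extent - is the clinical diameter), `length_mm` the major
#' axis. `over_6mm` is set when `diameter_mm >= 6`.
#'
#' @param candidate An `object_region` from [filter_candidates()].
#' @param mask The binary grid the candidate came from (unused beyond shape
#'   checking; the candidate's own pixel set is measured).
#' @param spacing Pixel spacing in mm/pixel.
#' @return An `appendix_result`; `success = FALSE` with a reason for
#'   degenerate (line-like) candidates.
#' @export
refine_and_measure <- function(candidate, mask = NULL, spacing) {
  stopifnot(spacing > 0)
  comp <- region_mask(candidate)
  if (!is.null(mask) && !identical(dim(mask), dim(comp))) {
    stop("mask dimensions do not match the candidate's frame")
  }
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp * 1))) > 0
  rc <- which(filled, arr.ind = TRUE)
  n <- nrow(rc)
  ctr <- colMeans(rc)
  dc <- sweep(rc, 2L, ctr)
  cov2 <- crossprod(dc) / n
  ev <- eigen(cov2, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2L] < 1e-9) {
    return(new_appendix_result(
      success = FALSE,
      failure_reason = "degenerate candidate (line-like, zero minor moment)"))
  }
  major_px <- 4 * sqrt(ev[1L])
  minor_px <- 4 * sqrt(ev[2L])
  contour <- trace_contour(filled)
  diameter_mm <- minor_px * spacing
  new_appendix_result(
    mask = filled, contour = contour,
    diameter_mm = diameter_mm, length_mm = major_px * spacing,
    over_6mm = diameter_mm >= 6.0, success = TRUE)
}

# Zhang-Suen thinning to a one-pixel-wide skeleton (vectorized over shifted
# neighbour matrices); operates on a logical matrix
skeletonize <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1L, 1L - dr):min(nr, nr - dr)
    cs <- max(1L, 1L - dc):min(nc, nc - dc)
    out[rs, cs] <- x[rs + dr, cs + dc]
    out
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift(m, -1L, 0L); p3 <- shift(m, -1L, 1L)
      p4 <- shift(m, 0L, 1L);  p5 <- shift(m, 1L, 1L)
      p6 <- shift(m, 1L, 0L);  p7 <- shift(m, 1L, -1L)
      p8 <- shift(m, 0L, -1L); p9 <- shift(m, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- m & b >= 2 & b <= 6 & a == 1
      cond <- if (sub == 1L) {
        cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# longest 8-connected path through a skeleton by double BFS; returns an
# ordered n x 2 matrix of (row, col)
skeleton_path <- function(skel) {
  pts <- which(skel, arr.ind = TRUE)
  n <- nrow(pts)
  if (n < 2L) return(pts)
  key <- pts[, 1L] + (pts[, 2L] - 1L) * nrow(skel)
  idx_of <- match(seq_len(nrow(skel) * ncol(skel)), key)
  nbr_off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  nbr_off <- nbr_off[rowSums(abs(nbr_off)) > 0, ]
  bfs <- function(src) {
    dist <- rep(NA_integer_, n); par <- rep(NA_integer_, n)
    dist[src] <- 0L
    queue <- src; head <- 1L
    while (head <= length(queue)) {
      u <- queue[head]; head <- head + 1L
      for (k in seq_len(nrow(nbr_off))) {
        r <- pts[u, 1L] + nbr_off[k, 1L]; c <- pts[u, 2L] + nbr_off[k, 2L]
        if (r < 1L || r > nrow(skel) || c < 1L || c > ncol(skel)) next
        v <- idx_of[r + (c - 1L) * nrow(skel)]
        if (!is.na(v) && is.na(dist[v])) {
          dist[v] <- dist[u] + 1L; par[v] <- u
          queue <- c(queue, v)
        }
      }
    }
    list(dist = dist, par = par)
  }
  b1 <- bfs(1L)
  u <- which.max(b1$dist)
  b2 <- bfs(u)
  v <- which.max(b2$dist)
  path <- v
  while (!is.na(b2$par[path[1L]])) path <- c(b2$par[path[1L]], path)
  pts[path, , drop = FALSE]
}

# bend angle (degrees) of a shape's medial path: the mask is thinned to its
# skeleton, the longest skeleton path extracted, and the directions of its
# first and last quarters compared. Straight ovals give ~0, hooked tubes
# approximately the hook's bend angle.
centerline_bend <- function(mask) {
  rc <- which(mask != 0, arr.ind = TRUE)
  if (nrow(rc) < 10L) return(0)
  # work on the bounding box only (padded so smoothing has room)
  r0 <- max(1L, min(rc[, 1L]) - 4L); r1 <- min(nrow(mask), max(rc[, 1L]) + 4L)
  c0 <- max(1L, min(rc[, 2L]) - 4L); c1 <- min(ncol(mask), max(rc[, 2L]) + 4L)
  sub <- mask[r0:r1, c0:c1, drop = FALSE] != 0
  # light morphological opening removes speckle fringe that would otherwise
  # grow spurious skeleton branches
  sub <- EBImage::imageData(EBImage::opening(
    EBImage::Image(sub * 1), EBImage::makeBrush(7L, "disc"))) > 0
  if (sum(sub) < 10L) return(0)
  path <- skeleton_path(skeletonize(sub))
  k <- nrow(path)
  if (k < 8L) return(0)
  q <- max(3L, round(k / 4))
  d1 <- path[q, ] - path[1L, ]
  d2 <- path[k, ] - path[k - q + 1L, ]
  cosang <- sum(d1 * d2) / (sqrt(sum(d1^2)) * sqrt(sum(d2^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Classify the shape-brightness pattern of an extracted appendix
#'
#' Operationalizes the four clinically observed patterns: contrast is the
#' mean intensity of a 5-pixel dilation ring outside the mask minus the mean
#' inside; elongation is `length_mm / diameter_mm`; the bend angle comes from
#' the centreline. Rules, in order: elongation `>= 3` with contrast `<= 25`
#' is D (long oval, very low contrast); bend `>= 60` degrees is B (hooked);
#' contrast `>= 60` is C (much darker than surroundings); otherwise A (oval
#' in brighter surroundings). Intensities should come from the unstretched
#' image so the thresholds keep the acquisition scale.
#'
#' @param result An `appendix_result`.
#' @param image The [gray_image()] the mask lives in (same dimensions).
#' @return One of `"A"`, `"B"`, `"C"`, `"D"`, `"unknown"`.
#' @export
classify_pattern <- function(result, image) {
  if (!isTRUE(result$success)) return("unknown")
  px <- image$pixels
  mask <- result$mask
  stopifnot(identical(dim(mask), dim(px)))
  brush <- EBImage::makeBrush(11L, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), brush)) > 0
  ring <- dil & !mask
  if (!any(ring)) return("unknown")
  contrast <- mean(px[ring]) - mean(px[mask])
  elong <- result$length_mm / result$diameter_mm
  bend <- centerline_bend(mask)
  if (elong >= 3 && contrast <= 25) return("D")
  if (bend >= 60) return("B")
  if (contrast >= 60) return("C")
  "A"
}
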
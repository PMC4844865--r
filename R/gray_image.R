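#' Grayscale image with physical pixel spacing
#'
#' The carrier object for every pipeline stage: an integer matrix of 8-bit
#' intensities together with the physical size of a pixel in millimetres.
#' Coordinates are 1-based `(row, col)` with the origin at the top-left and
#' rows increasing downward; ranges are closed. `origin` records where this
#' view sits inside the original frame (both components are 1 for an uncropped
#' frame), so that coordinates measured on a cropped view can be mapped back.
#'
#' @param pixels Numeric or integer matrix with values in `[0, 255]`.
#' @param spacing Pixel spacing in mm/pixel (isotropic), `> 0`.
#' @param origin Integer `(row, col)` of this view's top-left pixel within the
#'   original frame.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, spacing, origin = c(1L, 1L)) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be non-empty")
  if (anyNA(pixels)) stop("pixels contain NA")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]")
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("pixel spacing must be a single positive number (mm/pixel)")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, spacing = as.numeric(spacing),
         origin = as.integer(origin)),
    class = "gray_image"
  )
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
as.matrix.gray_image <- function(x, ...) x$pixels

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<gray_image> %d x %d px, %.4g mm/px, origin (%d, %d)\n",
              d[1L], d[2L], x$spacing, x$origin[1L], x$origin[2L]))
  cat(sprintf("  intensity range [%d, %d]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Display a gray_image (optionally with a mask outline)
#'
#' @param x A [gray_image()].
#' @param mask Optional logical matrix; its boundary is drawn on top.
#' @param ... Passed to [graphics::image()].
#' @export
plot.gray_image <- function(x, mask = NULL, ...) {
  px <- x$pixels
  nr <- nrow(px); nc <- ncol(px)
  # transpose + flip so the display matches (row down, col right)
  z <- t(px[nr:1, , drop = FALSE])
  graphics::image(seq_len(nc), seq_len(nr), z, col = grDevices::gray.colors(256, 0, 1),
                  useRaster = TRUE, xlab = "col", ylab = "row (flipped)",
                  asp = 1, ...)
  if (!is.null(mask)) {
    b <- which(boundary_mask(mask), arr.ind = TRUE)
    if (nrow(b)) graphics::points(b[, 2L], nr - b[, 1L] + 1L, pch = ".",
                                  col = "red", cex = 2)
  }
  invisible(x)
}

#' Map view coordinates back to the original frame
#'
#' @param image A [gray_image()] view (e.g. the output of
#'   [crop_scan_region()]).
#' @param coords Matrix or vector of `(row, col)` coordinates in the view.
#' @return Coordinates in the original full frame.
#' @export
map_to_frame <- function(image, coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 2L)
  sweep(coords, 2L, image$origin - 1L, "+")
}
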
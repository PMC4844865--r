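#' Read an ultrasound frame from DICOM, PNG or TIFF
#'
#' DICOM files use the embedded pixel-spacing attribute when present; a
#' `spacing_override` always wins. PNG/TIFF carry no physical calibration, so
#' for them the override is mandatory. RGB input is converted to luminance
#' (Rec. 601 weights).
#'
#' @param path Path to a DICOM, PNG or TIFF file.
#' @param spacing_override Optional pixel spacing in mm/pixel.
#' @return A [gray_image()].
#' @export
read_image <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  magic <- readBin(path, "raw", n = 132L)
  is_dicom <- length(magic) >= 132L &&
    rawToChar(magic[129:132]) == "DICM"
  ext <- tolower(tools::file_ext(path))

  if (is_dicom || ext %in% c("dcm", "dicom")) {
    d <- read_dicom(path)
    spacing <- if (!is.null(spacing_override)) spacing_override else d$spacing
    if (is.null(spacing)) {
      stop("pixel spacing unknown: DICOM has no PixelSpacing attribute ",
           "and no spacing_override was given")
    }
    return(gray_image(d$pixels, spacing))
  }

  arr <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  px <- luminance(arr)
  if (is.null(spacing_override)) {
    stop("pixel spacing unknown: raster formats carry no calibration, ",
         "supply spacing_override (mm/pixel)")
  }
  gray_image(px, spacing_override)
}

# [0,1] array (possibly RGB/RGBA) -> integer 0..255 matrix
luminance <- function(arr) {
  if (length(dim(arr)) == 3L) {
    ch <- dim(arr)[3L]
    arr <- if (ch >= 3L) {
      0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr[, , 1L]
    }
  }
  round_half_up(arr * 255)
}

round_half_up <- function(x) {
  out <- floor(x + 0.5)
  storage.mode(out) <- "integer"   # keeps matrix dimensions
  out
}

#' Crop away non-scan furniture (header, measurement ruler)
#'
#' Abdominal ultrasound frames carry filming information at the top and a
#' measurement ruler at the right; the scan content sits in the interior.
#' Margins below 1 are interpreted as fractions of the corresponding
#' dimension, values `>= 1` as pixel counts.
#'
#' @param image A [gray_image()].
#' @param top,right,bottom,left Margin to remove on each side (fraction or
#'   pixels). Defaults remove the top 10 percent and right 12 percent.
#' @return The interior [gray_image()] view with `origin` updated.
#' @export
crop_scan_region <- function(image, top = 0.10, right = 0.12,
                             bottom = 0, left = 0) {
  d <- dim(image$pixels)
  px_of <- function(m, extent) {
    if (m < 0) stop("margins must be non-negative")
    if (m < 1) as.integer(round(m * extent)) else as.integer(round(m))
  }
  t_px <- px_of(top, d[1L]); b_px <- px_of(bottom, d[1L])
  l_px <- px_of(left, d[2L]); r_px <- px_of(right, d[2L])
  r0 <- t_px + 1L; r1 <- d[1L] - b_px
  c0 <- l_px + 1L; c1 <- d[2L] - r_px
  if (r0 > r1 || c0 > c1) stop("margins consume the entire image")
  gray_image(image$pixels[r0:r1, c0:c1, drop = FALSE], image$spacing,
             origin = image$origin + c(t_px, l_px))
}

#' Write an 8-bit grayscale PNG
#'
#' @param image A [gray_image()] or a numeric/logical matrix (logical masks
#'   are written as 0/255).
#' @param path Output path.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "gray_image")) image$pixels else image
  if (is.logical(px)) px <- px * 255L
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Write a segmentation result as mask and overlay PNGs
#'
#' Writes `<stem>_mask.png` (0/255 mask) and `<stem>_overlay.png` (the image
#' with the mask boundary burnt in as a bright outline).
#'
#' @param image A [gray_image()].
#' @param mask Logical matrix of the same dimensions.
#' @param stem Output path stem (without extension).
#' @return Invisibly, the two paths written.
#' @export
write_result <- function(image, mask, stem) {
  if (!identical(dim(mask), dim(image$pixels))) {
    stop("mask dimensions must match the image")
  }
  mask <- mask != 0
  mask_path <- paste0(stem, "_mask.png")
  over_path <- paste0(stem, "_overlay.png")
  write_image(mask, mask_path)
  g <- image$pixels / 255
  r <- g; b <- g
  border <- boundary_mask(mask)
  r[border] <- 1; g[border] <- 1; b[border] <- 0
  png::writePNG(array(c(r, g, b), dim = c(dim(g), 3L)), over_path)
  invisible(c(mask_path, over_path))
}

# foreground pixels with at least one background 8-neighbour
# (the grid border counts as background) -- vectorized via padding
boundary_mask <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  all_nb <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    all_nb <- all_nb & pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  mask & !all_nb
}

#' Dice overlap coefficient between two masks
#'
#' `2|A ∩ B| / (|A| + |B|)`; returns 0 when both masks are empty.
#'
#' @param a,b Logical matrices of identical dimensions.
#' @export
dice <- function(a, b) {
  a <- a != 0; b <- b != 0
  s <- sum(a) + sum(b)
  if (s == 0) return(0)
  2 * sum(a & b) / s
}
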
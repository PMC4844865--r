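# Seeded synthetic ultrasound phantoms with ground truth.
#
# Each phantom emulates the anatomy the extraction pipeline relies on: an
# abdominal-wall band above a bright fascia line, interrupted by dark
# acoustic shadow gaps (rib-shadow style) that fragment the wall band and
# anchor the dark end of the frame's histogram, sub-fascial tissue, and an
# appendix in one of four clinically observed shape-brightness patterns:
#   A - oval appendix, surroundings brighter than the appendix;
#   B - hooked appendix;
#   C - oval appendix much darker than its surroundings;
#   D - long oval appendix with very low brightness contrast (the hardest).
# Speckle is multiplicative: a Rayleigh-derived, Gaussian-correlated noise
# field applied to the piecewise-constant anatomy template, then clipped to
# [0, 255]. Ground truth is the noiseless shape, not a human tracing.

# fixed template intensities (the per-type contrast lives in the
# appendix/surround fields of the spec)
.wall_intensity <- 100
.fascia_intensity <- 235
.gap_intensity <- 40

#' Specification of one synthetic phantom
#'
#' @param pattern_type One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param image_size `(rows, cols)` in pixels.
#' @param pixel_spacing mm/pixel.
#' @param appendix_center `(row, col)` of the appendix centre.
#' @param appendix_axes `(minor_mm, major_mm)`; for type B the minor axis is
#'   the tube width and the major axis the centreline arc length.
#' @param appendix_rotation Degrees (for B: rotation of the hook opening).
#' @param hook_curvature Total bend angle of the hook in degrees (type B).
#' @param appendix_mean_intensity,surround_mean_intensity Template
#'   intensities, 0-255.
#' @param fascia_row Pixel row of the fascia band centre.
#' @param fascia_thickness Band thickness in pixels.
#' @param fascia_gap_columns List of `(start, end)` column intervals where
#'   the fascia is missing (dark shadow gaps).
#' @param speckle_scale Amplitude of the multiplicative speckle (0 disables).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `phantom_spec` (validated).
#' @export
phantom_spec <- function(pattern_type, image_size = c(400L, 500L),
                         pixel_spacing = 0.1,
                         appendix_center = c(260, 250),
                         appendix_axes = c(8, 12),
                         appendix_rotation = 0,
                         hook_curvature = 0,
                         appendix_mean_intensity = 90,
                         surround_mean_intensity = 150,
                         fascia_row = 80, fascia_thickness = 10,
                         fascia_gap_columns = list(c(40, 80), c(120, 160),
                                                   c(200, 240), c(400, 440)),
                         speckle_scale = 0.25, seed = 1L) {
  spec <- structure(
    list(pattern_type = pattern_type,
         image_size = as.integer(image_size),
         pixel_spacing = pixel_spacing,
         appendix_center = appendix_center,
         appendix_axes = appendix_axes,
         appendix_rotation = appendix_rotation,
         hook_curvature = hook_curvature,
         appendix_mean_intensity = appendix_mean_intensity,
         surround_mean_intensity = surround_mean_intensity,
         fascia_row = as.integer(fascia_row),
         fascia_thickness = as.integer(fascia_thickness),
         fascia_gap_columns = fascia_gap_columns,
         speckle_scale = speckle_scale,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (!spec$pattern_type %in% c("A", "B", "C", "D")) {
    stop("pattern_type must be one of A, B, C, D")
  }
  minor <- spec$appendix_axes[1L]; major <- spec$appendix_axes[2L]
  if (minor < 6 || minor > 12) {
    stop("appendix minor axis must lie within the clinical 6-12 mm range, got ",
         minor, " mm")
  }
  if (major < minor) stop("major axis must be >= minor axis")
  app <- spec$appendix_mean_intensity
  sur <- spec$surround_mean_intensity
  if (app < 0 || app > 255 || sur < 0 || sur > 255) {
    stop("intensities must lie in [0, 255]")
  }
  if (spec$pattern_type == "A" && sur <= app) {
    stop("type A requires surroundings brighter than the appendix ",
         "(surround_mean_intensity > appendix_mean_intensity)")
  }
  if (spec$pattern_type == "B" && spec$hook_curvature <= 0) {
    stop("type B requires a positive hook_curvature (bend angle, degrees)")
  }
  if (spec$pattern_type == "C" && sur - app < 60) {
    stop("type C requires the appendix to be much darker than its ",
         "surroundings (surround - appendix >= 60), got ", sur - app)
  }
  if (spec$pattern_type == "D") {
    if (major / minor < 3) {
      stop("type D requires a long oval (major/minor >= 3), got ratio ",
           round(major / minor, 2))
    }
    if (sur - app > 25) {
      stop("type D requires very low brightness contrast ",
           "(surround - appendix <= 25), got ", sur - app)
    }
  }
  if (spec$fascia_thickness < 1) stop("fascia_thickness must be >= 1")
  invisible(spec)
}

#' Default phantom specification per pattern type
#'
#' The four defaults differ only in the appendix shape and contrast fields;
#' geometry, fascia layout and speckle are shared.
#'
#' @param pattern_type One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param seed Integer seed.
#' @return A valid [phantom_spec()].
#' @export
default_phantom_spec <- function(pattern_type = c("A", "B", "C", "D"),
                                 seed = 1L) {
  pattern_type <- match.arg(pattern_type)
  switch(pattern_type,
    A = phantom_spec("A", appendix_center = c(260, 220),
                     appendix_axes = c(8, 11), appendix_rotation = 20,
                     appendix_mean_intensity = 95,
                     surround_mean_intensity = 140, seed = seed),
    B = phantom_spec("B", appendix_center = c(250, 250),
                     appendix_axes = c(7, 22), hook_curvature = 140,
                     appendix_mean_intensity = 75,
                     surround_mean_intensity = 150, seed = seed),
    C = phantom_spec("C", appendix_center = c(250, 260),
                     appendix_axes = c(9, 13), appendix_rotation = -10,
                     appendix_mean_intensity = 55,
                     surround_mean_intensity = 170, seed = seed),
    D = phantom_spec("D", appendix_center = c(255, 250),
                     appendix_axes = c(6.5, 24), appendix_rotation = 8,
                     appendix_mean_intensity = 100,
                     surround_mean_intensity = 120, seed = seed))
}

# rasterize the appendix shape: rotated ellipse (A/C/D) or constant-width
# tube along a circular arc (B)
appendix_shape_mask <- function(spec) {
  nr <- spec$image_size[1L]; nc <- spec$image_size[2L]
  sp <- spec$pixel_spacing
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cr <- spec$appendix_center[1L]; cc <- spec$appendix_center[2L]

  if (spec$pattern_type == "B") {
    kappa <- spec$hook_curvature * pi / 180
    w <- spec$appendix_axes[1L] / sp          # tube width, px
    r <- (spec$appendix_axes[2L] / sp) / kappa  # arc radius, px
    # centre of curvature above the shape so the hook opens upward and the
    # tube bulges downward; rotation turns the opening direction
    th0 <- spec$appendix_rotation * pi / 180
    o_r <- cr - 0.8 * r * cos(th0)
    o_c <- cc - 0.8 * r * sin(th0)
    dr <- row - o_r; dc <- col - o_c
    dist <- sqrt(dr^2 + dc^2)
    ang <- atan2(dc, dr) - th0              # 0 = straight down from centre
    ang <- (ang + pi) %% (2 * pi) - pi
    abs(dist - r) <= w / 2 & abs(ang) <= kappa / 2
  } else {
    a <- spec$appendix_axes[2L] / (2 * sp)  # semi-major, px
    b <- spec$appendix_axes[1L] / (2 * sp)  # semi-minor, px
    th <- spec$appendix_rotation * pi / 180
    u <- (col - cc) * cos(th) + (row - cr) * sin(th)
    v <- -(col - cc) * sin(th) + (row - cr) * cos(th)
    (u / a)^2 + (v / b)^2 <= 1
  }
}

fascia_band_rows <- function(spec) {
  top <- spec$fascia_row - spec$fascia_thickness %/% 2L
  top:(top + spec$fascia_thickness - 1L)
}

#' Generate a synthetic phantom with ground truth
#'
#' Builds the piecewise-constant anatomy template (wall band, bright fascia
#' with dark shadow gaps, sub-fascial tissue, appendix), applies seeded
#' multiplicative speckle, and returns the image together with the noiseless
#' ground-truth masks. Bit-identical for identical specs.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (a [gray_image()]), `truth` (list of logical
#'   `appendix_mask` and `fascia_mask`, disjoint), and `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  nr <- spec$image_size[1L]; nc <- spec$image_size[2L]
  band <- fascia_band_rows(spec)
  if (min(band) < 2L || max(band) > nr - 1L) {
    stop("fascia band must lie inside the image")
  }

  gap_cols <- integer(0)
  for (g in spec$fascia_gap_columns) {
    gap_cols <- c(gap_cols, max(1L, as.integer(g[1L])):min(nc, as.integer(g[2L])))
  }
  gap_cols <- sort(unique(gap_cols))

  template <- matrix(spec$surround_mean_intensity, nr, nc)
  template[seq_len(min(band) - 1L), ] <- .wall_intensity
  template[band, ] <- .fascia_intensity
  if (length(gap_cols)) {
    template[seq_len(max(band)), gap_cols] <- .gap_intensity
  }

  app_mask <- appendix_shape_mask(spec)
  if (!any(app_mask)) stop("appendix shape lies outside the image")
  if (min(which(app_mask, arr.ind = TRUE)[, 1L]) <=
      spec$fascia_row + spec$fascia_thickness) {
    stop("appendix must lie strictly below fascia_row + fascia_thickness")
  }
  template[app_mask] <- spec$appendix_mean_intensity

  fascia_mask <- matrix(FALSE, nr, nc)
  fascia_mask[band, ] <- TRUE
  if (length(gap_cols)) fascia_mask[, gap_cols] <- FALSE

  pixels <- with_seed(spec$seed, {
    f <- speckle_field(nr, nc, spec$speckle_scale)
    pmin(pmax(round_half_up(template * f), 0L), 255L)
  })

  list(image = gray_image(matrix(pixels, nr, nc), spec$pixel_spacing),
       truth = list(appendix_mask = app_mask, fascia_mask = fascia_mask),
       spec = spec)
}

# multiplicative speckle factor field: unit-mean Rayleigh draws, spatially
# correlated by a Gaussian kernel (grain ~1.5 px), rescaled to keep the
# requested amplitude, mean 1
speckle_field <- function(nr, nc, scale, grain_sigma = 1.5) {
  if (scale <= 0) return(matrix(1, nr, nc))
  sigma_r <- sqrt(2 / pi)                      # Rayleigh with mean 1
  r <- matrix(sigma_r * sqrt(-2 * log(stats::runif(nr * nc))), nr, nc)
  g <- r - mean(r)
  gs <- EBImage::imageData(EBImage::gblur(EBImage::Image(g),
                                          sigma = grain_sigma))
  gs <- gs * (stats::sd(g) / stats::sd(gs))
  pmax(1 + scale * gs, 0)
}

#' Write a phantom to disk
#'
#' Writes `<stem>_image.png`, `<stem>_appendix_mask.png`,
#' `<stem>_fascia_mask.png` (0/255) and `<stem>_spec.yaml`.
#'
#' @param phantom Output of [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @param stem File stem; defaults to `<type>_<seed>`.
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir, stem = NULL) {
  if (is.null(stem)) {
    stem <- sprintf("%s_%03d", phantom$spec$pattern_type, phantom$spec$seed)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, stem)
  write_image(phantom$image, paste0(p, "_image.png"))
  write_image(phantom$truth$appendix_mask, paste0(p, "_appendix_mask.png"))
  write_image(phantom$truth$fascia_mask, paste0(p, "_fascia_mask.png"))
  sp <- phantom$spec
  sp$image_size <- as.list(sp$image_size)
  yaml::write_yaml(unclass(sp), paste0(p, "_spec.yaml"))
  invisible(paste0(p, c("_image.png", "_appendix_mask.png",
                        "_fascia_mask.png", "_spec.yaml")))
}
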
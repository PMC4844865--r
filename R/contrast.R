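#' Ends-in search contrast stretching
#'
#' Linearly maps the inner intensity range of the histogram onto the full
#' 8-bit range: with `L` the intensity at the `low_fraction` quantile and `H`
#' at the `1 - high_fraction` quantile, intensities are clipped to `[L, H]`
#' and rescaled to `[0, 255]` (rounding half up). The map is monotone
#' non-decreasing, so pixel ordering is preserved up to ties.
#'
#' @param image A [gray_image()].
#' @param low_fraction,high_fraction Histogram tail fractions clipped at the
#'   dark and bright end. Their sum must be `< 1`.
#' @return The stretched [gray_image()].
#' @export
ends_in_stretch <- function(image, low_fraction = 0.05, high_fraction = 0.05) {
  stopifnot(low_fraction >= 0, high_fraction >= 0)
  if (low_fraction + high_fraction >= 1) {
    stop("low_fraction + high_fraction must be < 1")
  }
  v <- as.numeric(image$pixels)
  L <- as.numeric(stats::quantile(v, low_fraction, type = 1, names = FALSE))
  H <- as.numeric(stats::quantile(v, 1 - high_fraction, type = 1,
                                  names = FALSE))
  if (H <= L) {
    warning("flat intensity range; image returned unchanged")
    return(image)
  }
  out <- round_half_up((pmin(pmax(v, L), H) - L) * (255 / (H - L)))
  gray_image(matrix(out, nrow(image$pixels), ncol(image$pixels)),
             image$spacing, image$origin)
}

#' Trapezoidal fuzzy-membership parameters of a region of interest
#'
#' From the darkest (`i_min`) and brightest (`i_max`) pixel of the ROI, the
#' reference level is their mean `t = (i_min + i_max) / 2`, and the plateau of
#' the trapezoid (membership 1) is the interval `[i_s, i_e]` with
#' `i_s = t / 3` and `i_e = 2 i_s`. All arithmetic is kept real-valued. The
#' parameters are degenerate when the ROI is flat or the four abscissae do not
#' form a proper trapezoid (`i_min <= i_s < i_e <= i_max`).
#'
#' @param image A [gray_image()] (the ROI).
#' @param alpha Membership cut in `[0, 1]` used by [fuzzy_binarize()].
#' @return An object of class `fuzzy_params` with fields `i_min`, `i_max`,
#'   `t`, `i_s`, `i_e`, `alpha`, `degenerate`.
#' @export
compute_fuzzy_params <- function(image, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  px <- if (inherits(image, "gray_image")) image$pixels else image
  if (length(px) == 0L) stop("empty image")
  i_min <- as.numeric(min(px))
  i_max <- as.numeric(max(px))
  t_ref <- (i_min + i_max) / 2
  i_s <- t_ref / 3
  i_e <- 2 * i_s
  degenerate <- (i_min == i_max) ||
    !(i_min <= i_s && i_s < i_e && i_e <= i_max)
  structure(
    list(i_min = i_min, i_max = i_max, t = t_ref, i_s = i_s, i_e = i_e,
         alpha = alpha, degenerate = degenerate),
    class = "fuzzy_params"
  )
}

#' @export
print.fuzzy_params <- function(x, ...) {
  cat(sprintf(
    "<fuzzy_params> I_Min=%.6g I_Max=%.6g T=%.6g I_s=%.6g I_e=%.6g alpha=%.3g%s\n",
    x$i_min, x$i_max, x$t, x$i_s, x$i_e, x$alpha,
    if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Trapezoidal membership degree
#'
#' Piecewise-linear trapezoid over `[i_min, i_s, i_e, i_max]`: zero at and
#' below `i_min`, rising linearly to 1 at `i_s`, 1 on `[i_s, i_e]`, falling
#' linearly to zero at `i_max`, zero above. The falling shoulder is the
#' decreasing mirror of the rising one, so the brightest ROI pixel always has
#' membership 0. Values are clamped to `[0, 1]`.
#'
#' @param i Intensity value(s), vectorized.
#' @param p A [compute_fuzzy_params()] object.
#' @return Membership degree(s) in `[0, 1]`.
#' @export
membership <- function(i, p) {
  stopifnot(inherits(p, "fuzzy_params"))
  if (p$degenerate) stop("degenerate fuzzy parameters (flat ROI)")
  i <- as.numeric(i)
  mu <- numeric(length(i))
  left <- i > p$i_min & i <= p$i_s
  if (p$i_s > p$i_min) {
    mu[left] <- (i[left] - p$i_s) / (p$i_s - p$i_min) + 1
  }
  mu[i > p$i_s & i <= p$i_e] <- 1
  right <- i > p$i_e & i <= p$i_max
  mu[right] <- 1 - (i[right] - p$i_e) / (p$i_max - p$i_e)
  pmin(pmax(mu, 0), 1)
}

#' Fuzzy binarization by alpha-cut
#'
#' A pixel is foreground iff its trapezoidal membership is `>= alpha` (ties at
#' the cut are foreground). The foreground is therefore an intensity band
#' around the dark-to-mid plateau `[i_s, i_e]`, where fascia and appendix
#' structure boundaries concentrate after stretching. Degenerate parameters
#' (flat ROI) yield an all-background mask with a warning, so batch runs can
#' continue and log the frame as an extraction failure.
#'
#' @param image A [gray_image()].
#' @param p A [compute_fuzzy_params()] object for the same ROI.
#' @return A logical matrix (TRUE = foreground).
#' @export
fuzzy_binarize <- function(image, p) {
  stopifnot(inherits(p, "fuzzy_params"))
  px <- if (inherits(image, "gray_image")) image$pixels else image
  if (length(px) == 0L) stop("empty image")
  if (p$degenerate) {
    warning("degenerate fuzzy parameters; returning all-background mask")
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  # evaluate on the 0..255 codebook once, then index
  lut <- membership(0:255, p) >= p$alpha
  matrix(lut[px + 1L], nrow(px), ncol(px))
}
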
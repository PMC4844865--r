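# Hexagonal-grid self-organizing map for pixel-intensity quantization.
#
# The SOM posterizes the sub-fascial region into at most rows*cols intensity
# levels: each pixel is replaced by the weight of its best-matching node. The
# input feature is the scalar intensity only; spatial position is already
# encoded by the fascia gating.

#' Training schedule for the intensity SOM
#'
#' Learning rate and neighbourhood radius decay exponentially from their
#' start to end values over all update steps. All randomness (weight jitter,
#' per-epoch sample shuffling/subsampling) flows from `seed`.
#'
#' @param epochs Number of passes, `>= 1`.
#' @param lr_start,lr_end Learning rates, `0 < lr_end <= lr_start < 1`.
#' @param radius_start,radius_end Neighbourhood radii in hex-lattice distance
#'   units, `radius_end <= radius_start`.
#' @param seed Integer seed.
#' @param sample_cap Maximum pixels sampled per epoch.
#' @return An object of class `som_config`.
#' @export
som_config <- function(epochs = 20, lr_start = 0.5, lr_end = 0.02,
                       radius_start = 2, radius_end = 0.1,
                       seed = 1L, sample_cap = 20000L) {
  stopifnot(epochs >= 1, lr_end > 0, lr_end <= lr_start, lr_start < 1,
            radius_end <= radius_start, radius_end >= 0, sample_cap >= 1)
  structure(
    list(epochs = as.integer(epochs), lr_start = lr_start, lr_end = lr_end,
         radius_start = radius_start, radius_end = radius_end,
         seed = as.integer(seed), sample_cap = as.integer(sample_cap)),
    class = "som_config"
  )
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# node positions for the neighbourhood metric: offset hex rows (every second
# grid row shifted half a column, row pitch sqrt(3)/2) or plain rectangular
node_positions <- function(rows, cols, arrangement) {
  i <- rep(seq_len(rows) - 1L, each = cols)   # grid row, 0-based
  j <- rep(seq_len(cols) - 1L, times = rows)  # grid col, 0-based
  if (arrangement == "hexagonal") {
    cbind(x = j + 0.5 * (i %% 2), y = i * sqrt(3) / 2)
  } else {
    cbind(x = as.numeric(j), y = as.numeric(i))
  }
}

#' Initialize a SOM grid
#'
#' Node weights are spaced uniformly over `[0, 255]` in node index order
#' (row-major over the grid), then jittered by seeded uniform noise of
#' amplitude 2 and clamped to `[0, 255]`.
#'
#' @param rows,cols Grid dimensions, `rows * cols >= 2`.
#' @param cfg A [som_config()].
#' @param arrangement `"hexagonal"` (default) or `"rectangular"`.
#' @return An object of class `som_grid` with `weights`, `positions`
#'   (Cartesian node coordinates used for the neighbourhood distance),
#'   `arrangement`, `trained` flag.
#' @export
init_som <- function(rows = 4, cols = 4, cfg = som_config(),
                     arrangement = c("hexagonal", "rectangular")) {
  arrangement <- match.arg(arrangement)
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- rows * cols
  if (n < 2L) stop("SOM needs at least 2 nodes (rows * cols >= 2)")
  w <- seq(0, 255, length.out = n)
  w <- with_seed(cfg$seed, w + stats::runif(n, -2, 2))
  structure(
    list(rows = rows, cols = cols,
         weights = pmin(pmax(w, 0), 255),
         positions = node_positions(rows, cols, arrangement),
         arrangement = arrangement,
         trained = FALSE, qe_history = numeric(0)),
    class = "som_grid"
  )
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("<som_grid> %d x %d %s, %s\n", x$rows, x$cols, x$arrangement,
              if (x$trained) "trained" else "untrained"))
  cat("  weights:", paste(sprintf("%.1f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Best-matching unit for an intensity
#'
#' @param grid A `som_grid`.
#' @param x A single intensity.
#' @return Node index (1-based) of the weight closest to `x`; ties go to the
#'   lowest index.
#' @export
find_bmu <- function(grid, x) which.min(abs(grid$weights - x))

#' Train the SOM on intensity samples (online Kohonen updates)
#'
#' For each sample `x` (seeded shuffled order, at most `sample_cap` per
#' epoch), every node `n` is updated as
#' `w_n <- w_n + lr(t) * h(n, bmu, t) * (x - w_n)` with a Gaussian
#' neighbourhood `h = exp(-d^2 / (2 radius(t)^2))` over the lattice distance
#' `d`; `lr` and `radius` decay exponentially across all steps. Deterministic
#' for a fixed `cfg$seed`.
#'
#' @param grid A `som_grid` from [init_som()].
#' @param samples Non-empty numeric vector of intensities in `[0, 255]`.
#' @param cfg A [som_config()].
#' @return The trained `som_grid`; `qe_history` holds the mean quantization
#'   error of each epoch's sample measured after that epoch.
#' @export
som_train <- function(grid, samples, cfg = som_config()) {
  if (length(samples) == 0L) stop("no training samples")
  samples <- as.numeric(samples)
  n_nodes <- length(grid$weights)
  d2 <- as.matrix(stats::dist(grid$positions))^2

  epochs <- cfg$epochs
  cap <- min(cfg$sample_cap, length(samples))
  total <- epochs * cap
  step0 <- 0L
  decay <- function(start, end, t) {
    if (total <= 1L) return(start)
    start * (end / start)^((t - 1) / (total - 1))
  }

  w <- grid$weights
  qe <- numeric(epochs)
  with_seed(cfg$seed, {
    for (e in seq_len(epochs)) {
      x <- samples[sample.int(length(samples), cap)]
      t <- step0 + seq_len(cap)
      lr <- decay(cfg$lr_start, cfg$lr_end, t)
      # radius_end may be 0; keep the decay well-defined with a tiny floor
      rad <- decay(cfg$radius_start, max(cfg$radius_end, 1e-6), t)
      w <- som_train_cpp(w, d2, x, lr, rad)
      qe[e] <- mean(apply(abs(outer(x, w, "-")), 1L, min))
      step0 <- step0 + cap
    }
  })
  grid$weights <- pmin(pmax(w, 0), 255)
  grid$trained <- TRUE
  grid$qe_history <- qe
  grid
}

#' Quantize an image through a trained SOM codebook
#'
#' Every valid pixel is replaced by the (half-up rounded) weight of its
#' best-matching node; invalid pixels are set to 0. The output contains at
#' most `rows * cols` distinct nonzero values.
#'
#' @param image A [gray_image()].
#' @param validity Logical matrix marking usable pixels (e.g. from
#'   [restrict_below_fascia()]); `NULL` means all pixels.
#' @param grid A trained `som_grid`.
#' @return The quantized [gray_image()].
#' @export
som_quantize <- function(image, validity, grid) {
  px <- image$pixels
  if (is.null(validity)) validity <- matrix(TRUE, nrow(px), ncol(px))
  stopifnot(identical(dim(validity), dim(px)))
  # nearest-codebook lookup table over the 8-bit intensity range
  lut <- vapply(0:255, function(v) {
    round_half_up(grid$weights[find_bmu(grid, v)])
  }, integer(1L))
  out <- matrix(0L, nrow(px), ncol(px))
  out[validity] <- lut[px[validity] + 1L]
  gray_image(out, image$spacing, image$origin)
}
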
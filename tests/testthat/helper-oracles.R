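# Independent brute-force oracles used to check the package's algorithms.
# These are deliberately naive (double loops, literal definitions) and share
# no code with the implementation.

# boundary pixels: foreground with at least one background 8-neighbour,
# grid border counting as background
oracle_boundary <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc]) {
        out[r, c] <- TRUE
      }
    }
  }
  out
}

# 8-connected labeling by flood fill over linear indices (padded frame so
# neighbour arithmetic never wraps); breadth-first with an integer queue
oracle_label <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  npr <- nr + 2L
  offs <- c(-npr - 1L, -npr, -npr + 1L, -1L, 1L, npr - 1L, npr, npr + 1L)
  labp <- matrix(0L, npr, nc + 2L)
  cur <- 0L
  for (seed_idx in which(pad)) {
    if (labp[seed_idx] > 0L) next
    cur <- cur + 1L
    queue <- integer(64L); queue[1L] <- seed_idx; head <- 1L; tail <- 1L
    labp[seed_idx] <- cur
    while (head <= tail) {
      u <- queue[head]; head <- head + 1L
      for (o in offs) {
        v <- u + o
        if (pad[v] && labp[v] == 0L) {
          labp[v] <- cur
          tail <- tail + 1L
          if (tail > length(queue)) length(queue) <- 2L * length(queue)
          queue[tail] <- v
        }
      }
    }
  }
  labp[2:(nr + 1L), 2:(nc + 1L)]
}

# direct scalar evaluation of the trapezoidal membership formula
oracle_membership <- function(i, i_min, i_max) {
  t_ref <- (i_min + i_max) / 2
  i_s <- t_ref / 3
  i_e <- 2 * i_s
  mu <- if (i <= i_min) {
    0
  } else if (i <= i_s) {
    (i - i_s) / (i_s - i_min) + 1
  } else if (i <= i_e) {
    1
  } else if (i <= i_max) {
    1 - (i - i_e) / (i_max - i_e)
  } else {
    0
  }
  min(max(mu, 0), 1)
}

# analytic filled-ellipse mask (axis lengths in pixels, rotation in degrees)
ellipse_mask <- function(nr, nc, center, minor_px, major_px, theta_deg = 0) {
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  th <- theta_deg * pi / 180
  u <- (col - center[2]) * cos(th) + (row - center[1]) * sin(th)
  v <- -(col - center[2]) * sin(th) + (row - center[1]) * cos(th)
  (u / (major_px / 2))^2 + (v / (minor_px / 2))^2 <= 1
}

# a gray_image wrapper for plain matrices
gi <- function(m, spacing = 0.1) gray_image(m, spacing)
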
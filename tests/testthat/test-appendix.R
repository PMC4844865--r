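# Hypoechoic band selection, candidate filtering, measurement, pattern rules.

test_that("the darkest quantized levels are selected as the candidate band", {
  # 2-level image: the darker level wins with n_levels = 1
  q <- gi(matrix(c(40, 200, 40, 200, 40, 200), 2, 3))
  v <- matrix(TRUE, 2, 3)
  band <- select_appendix_band(q, v, n_levels = 1)
  expect_identical(band, q$pixels == 40)

  # uniform region: empty mask with a warning
  expect_warning(b <- select_appendix_band(gi(matrix(9L, 3, 3)),
                                           matrix(TRUE, 3, 3), 4),
                 "levels")
  expect_false(any(b))

  # 16-level image, n_levels = 4: brute-force membership in the 4 smallest
  set.seed(3)
  levels <- sort(sample(0:255, 16))
  px <- matrix(sample(levels, 400, replace = TRUE), 20, 20)
  v <- matrix(runif(400) < 0.9, 20, 20)
  band <- select_appendix_band(gi(px), v, 4)
  present <- sort(unique(px[v]))
  want <- v & matrix(px %in% present[1:4], 20, 20)
  expect_identical(band, want)
  # invalid pixels are never selected
  expect_false(any(band & !v))
})

test_that("candidates are filtered on physical size and ranked by area", {
  mk <- function(w, h, at = c(10, 10), nr = 200, nc = 200) {
    m <- matrix(FALSE, nr, nc)
    m[at[1]:(at[1] + h - 1), at[2]:(at[2] + w - 1)] <- TRUE
    label_objects(m, trace = FALSE)[[1]]
  }
  # 60 px minor dimension at 0.1 mm/px = 6 mm: kept
  expect_length(filter_candidates(list(mk(100, 60)), 0.1), 1L)
  # 10 px = 1 mm: below the minimum plausible diameter
  expect_length(filter_candidates(list(mk(100, 10)), 0.1), 0L)
  # tiny blob: area gate
  expect_length(filter_candidates(list(mk(40, 40)), 0.1, min_area_px = 2000), 0L)
  # ranking: larger survivor first
  o1 <- mk(50, 45)               # 2250 px
  o2 <- mk(90, 60, at = c(100, 50))   # 5400 px
  got <- filter_candidates(list(o1, o2), 0.1)
  expect_equal(vapply(got, function(o) o$pixel_count, numeric(1)),
               c(5400, 2250))
})

test_that("second-moment measurement recovers analytic ellipse axes", {
  # 60 x 100 px ellipse at 0.1 mm/px: 6 x 10 mm, meets the 6 mm criterion
  m <- ellipse_mask(200, 220, c(100, 110), 60, 100, theta_deg = 25)
  obj <- label_objects(m, trace = FALSE)[[1]]
  res <- refine_and_measure(obj, spacing = 0.1)
  expect_true(res$success)
  expect_equal(res$diameter_mm, 6, tolerance = 0.2 / 6)
  expect_equal(res$length_mm, 10, tolerance = 0.2 / 10)
  expect_true(res$over_6mm)
  expect_true(res$contour$closed)

  # circle of radius 25 px: diameter = length = 5 mm, below the criterion
  mc <- ellipse_mask(120, 120, c(60, 60), 50, 50)
  res <- refine_and_measure(label_objects(mc, trace = FALSE)[[1]], spacing = 0.1)
  expect_equal(res$diameter_mm, 5, tolerance = 0.05)
  expect_equal(res$length_mm, 5, tolerance = 0.05)
  expect_false(res$over_6mm)

  # one-pixel-wide line: degenerate
  ml <- matrix(FALSE, 50, 50); ml[25, 5:45] <- TRUE
  res <- refine_and_measure(label_objects(ml, trace = FALSE)[[1]], spacing = 0.1)
  expect_false(res$success)
  expect_match(res$failure_reason, "degenerate")

  # holes are filled before measuring (ring binarization of the wall)
  ring <- ellipse_mask(150, 150, c(75, 75), 80, 80) &
    !ellipse_mask(150, 150, c(75, 75), 50, 50)
  res <- refine_and_measure(label_objects(ring, trace = FALSE)[[1]], spacing = 0.1)
  expect_equal(res$diameter_mm, 8, tolerance = 0.2 / 8)
  expect_equal(sum(res$mask), sum(ellipse_mask(150, 150, c(75, 75), 80, 80)))
})

test_that("diameter recovery stays within 5 percent across sizes and spacings", {
  for (spacing in c(0.08, 0.1, 0.15)) {
    for (minor_mm in c(4, 6, 8, 12)) {
      minor_px <- minor_mm / spacing
      major_px <- 1.5 * minor_px
      n <- ceiling(major_px) + 20
      m <- ellipse_mask(n, n, c(n / 2, n / 2), minor_px, major_px,
                        theta_deg = 15)
      res <- refine_and_measure(label_objects(m, trace = FALSE)[[1]],
                                spacing = spacing)
      expect_lt(abs(res$diameter_mm - minor_mm) / minor_mm, 0.05)
    }
  }
})

test_that("the 6 mm flag flips exactly at the measured threshold", {
  m <- ellipse_mask(160, 200, c(80, 100), 80, 120)
  obj <- label_objects(m, trace = FALSE)[[1]]
  minor_px <- refine_and_measure(obj, spacing = 1)$diameter_mm  # pixels
  for (target in c(5.99, 6.00, 6.01)) {
    res <- refine_and_measure(obj, spacing = target / minor_px)
    expect_identical(res$over_6mm, res$diameter_mm >= 6.0)
  }
  expect_false(refine_and_measure(obj, spacing = 5.99 / minor_px)$over_6mm)
  expect_true(refine_and_measure(obj, spacing = 6.01 / minor_px)$over_6mm)
})

test_that("shape-brightness rules separate the default phantom patterns", {
  # failed extraction gates to unknown
  failed <- refine_and_measure(
    label_objects(matrix(c(rep(FALSE, 40), TRUE, rep(FALSE, 40)), 9, 9),
                  trace = FALSE)[[1]], spacing = 0.1)
  expect_equal(classify_pattern(failed, gi(matrix(0L, 9, 9))), "unknown")

  # end-to-end on seeded default phantoms: C classifies C, D classifies D
  for (ty in c("C", "D")) {
    ph <- generate_phantom(default_phantom_spec(ty, seed = 1))
    res <- run_pipeline(ph$image, pipeline_config(seed = 1))
    expect_true(res$success)
    expect_equal(res$pattern, ty)
  }
})
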
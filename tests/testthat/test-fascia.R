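# Fascia segment filtering, spline reconnection, ROI restriction.

rect_mask_object <- function(w, h, nr = 60, nc = 400) {
  m <- matrix(FALSE, nr, nc)
  m[10:(10 + h - 1), 5:(5 + w - 1)] <- TRUE
  label_objects(m, trace = FALSE)[[1]]
}

test_that("fascia rule keeps long thin objects only", {
  # longer than a third of the ROI width and thin: kept
  keep <- detect_fascia_segments(list(rect_mask_object(120, 10)), 300)
  expect_length(keep, 1L)
  # too short: discarded
  expect_length(detect_fascia_segments(list(rect_mask_object(80, 10)), 300), 0L)
  # long but blobby (elongation < 4): discarded
  expect_length(detect_fascia_segments(list(rect_mask_object(150, 125, nr = 200)), 300), 0L)
})

test_that("spline passes through knots and reproduces low-order polynomials", {
  # collinear knots: the spline is that line
  kn <- data.frame(col = c(10, 40, 90, 140), row = 5 + 0.25 * c(10, 40, 90, 140))
  fl <- fascia_spline_from_knots(kn)
  expect_equal(fascia_row_at(fl, kn$col), kn$row, tolerance = 1e-12)
  expect_equal(fl$rows, 5 + 0.25 * fl$cols, tolerance = 1e-9)

  # quadratic knot data: reproduced within 1e-9 at and between knots
  kn <- data.frame(col = c(10, 60, 110, 160), row = 0.001 * c(10, 60, 110, 160)^2)
  fl <- fascia_spline_from_knots(kn)
  expect_equal(fl$rows, 0.001 * fl$cols^2, tolerance = 1e-9)
  expect_equal(fascia_row_at(fl, kn$col), kn$row, tolerance = 1e-9)

  expect_error(fit_fascia_spline(list()), "no fascia")
})

test_that("a single segment passes its lower boundary through", {
  m <- matrix(FALSE, 30, 100)
  m[10:12, 20:80] <- TRUE
  m[13, 40:60] <- TRUE       # bump in the lower boundary
  seg <- label_objects(m, trace = FALSE)[[1]]
  fl <- fit_fascia_spline(list(seg))
  expect_equal(fl$span, c(20, 80))
  expect_equal(fascia_row_at(fl, 30), 12)
  expect_equal(fascia_row_at(fl, 50), 13)
})

test_that("bottom fascia line is the one with the largest mean row", {
  l1 <- fascia_spline_from_knots(data.frame(col = c(1, 100), row = c(50, 50)))
  l2 <- fascia_spline_from_knots(data.frame(col = c(1, 100), row = c(120, 120)))
  expect_equal(mean(select_bottom_fascia(list(l1, l2))$rows), 120)
  expect_equal(mean(select_bottom_fascia(list(l1))$rows), 50)
  # crossing lines: decided by the mean
  l3 <- fascia_spline_from_knots(data.frame(col = c(1, 100), row = c(200, 30)))
  expect_equal(select_bottom_fascia(list(l1, l3)), l3)
  expect_error(select_bottom_fascia(list()), "no fascia")
})

test_that("restriction below the fascia line is per column with margin", {
  img <- gi(matrix(100L, 400, 200))
  flat <- fascia_spline_from_knots(data.frame(col = c(1, 200), row = c(100, 100)))
  roi <- restrict_below_fascia(img, flat, margin = 5)
  expect_true(all(roi$validity[106:400, ]))
  expect_false(any(roi$validity[1:105, ]))

  # sloped line: per-column cut, columns outside the span use the nearest row
  sl <- fascia_spline_from_knots(data.frame(col = c(51, 150), row = c(60, 160)))
  roi <- restrict_below_fascia(img, sl, margin = 0)
  cut <- fascia_row_at(sl, 1:200)
  for (cc in c(1, 51, 100, 150, 200)) {
    expect_equal(unname(which(roi$validity[, cc])[1]), floor(cut[cc]) + 1L)
  }

  bottom <- fascia_spline_from_knots(data.frame(col = c(1, 200), row = c(400, 400)))
  expect_error(restrict_below_fascia(img, bottom, 3), "empty search region")
})

test_that("phantom fascia is reconstructed near the true band", {
  # two wide wall segments (one central shadow) so the spline bridges a gap
  spec <- phantom_spec("C", appendix_mean_intensity = 55,
                       surround_mean_intensity = 170,
                       appendix_axes = c(9, 13), appendix_center = c(250, 260),
                       fascia_gap_columns = list(c(170, 210)), seed = 3)
  ph <- generate_phantom(spec)
  crp <- crop_scan_region(ph$image)
  st <- ends_in_stretch(crp)
  bin <- fuzzy_binarize(st, compute_fuzzy_params(st))
  segs <- detect_fascia_segments(label_objects(bin, trace = FALSE), ncol(bin))
  expect_gte(length(segs), 2L)
  fl <- fit_fascia_spline(segs)
  # map back to full-frame rows and compare to the known fascia centre row
  rows_full <- fl$rows + crp$origin[1] - 1
  err <- mean(abs(rows_full - spec$fascia_row))
  expect_lte(err, spec$fascia_thickness)
})

test_that("restriction never discards ground-truth appendix pixels", {
  for (ty in c("A", "C")) for (s in 1:3) {
    ph <- generate_phantom(default_phantom_spec(ty, seed = s))
    crp <- crop_scan_region(ph$image)
    st <- ends_in_stretch(crp)
    bin <- fuzzy_binarize(st, compute_fuzzy_params(st))
    segs <- detect_fascia_segments(label_objects(bin, trace = FALSE), ncol(bin))
    fl <- fit_fascia_spline(segs)
    roi <- restrict_below_fascia(st, fl, margin = 3)
    truth_crop <- ph$truth$appendix_mask[
      crp$origin[1] - 1 + seq_len(nrow(crp$pixels)),
      crp$origin[2] - 1 + seq_len(ncol(crp$pixels))]
    expect_false(any(truth_crop & !roi$validity))
  }
})
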
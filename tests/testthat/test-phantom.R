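# Synthetic phantom generator: determinism, invariants, ground truth.

test_that("specs violating a pattern invariant are rejected by name", {
  expect_error(phantom_spec("D", appendix_axes = c(7, 10),
                            appendix_mean_intensity = 100,
                            surround_mean_intensity = 110),
               "long oval")
  expect_error(phantom_spec("A", appendix_mean_intensity = 150,
                            surround_mean_intensity = 120),
               "brighter")
  expect_error(phantom_spec("C", appendix_mean_intensity = 120,
                            surround_mean_intensity = 150),
               "darker")
  expect_error(phantom_spec("D", appendix_axes = c(6.5, 24),
                            appendix_mean_intensity = 60,
                            surround_mean_intensity = 150),
               "low brightness contrast")
  expect_error(phantom_spec("B", hook_curvature = 0), "hook_curvature")
  expect_error(phantom_spec("A", appendix_axes = c(4, 10),
                            appendix_mean_intensity = 90,
                            surround_mean_intensity = 140),
               "6-12 mm")
  expect_error(phantom_spec("E"), "pattern_type")
})

test_that("defaults are valid per type and differ only where expected", {
  for (ty in c("A", "B", "C", "D")) {
    spec <- default_phantom_spec(ty, seed = 1)
    expect_s3_class(spec, "phantom_spec")
    ph <- generate_phantom(spec)   # round-trips without error
    expect_s3_class(ph$image, "gray_image")
  }
  expect_gt(default_phantom_spec("A")$surround_mean_intensity,
            default_phantom_spec("A")$appendix_mean_intensity)
  expect_gt(default_phantom_spec("B")$hook_curvature, 0)
})

test_that("generation is bit-identical for identical specs", {
  s <- default_phantom_spec("B", seed = 11)
  p1 <- generate_phantom(s)
  p2 <- generate_phantom(s)
  expect_identical(p1$image$pixels, p2$image$pixels)
  expect_identical(p1$truth, p2$truth)
  p3 <- generate_phantom(default_phantom_spec("B", seed = 12))
  expect_false(identical(p1$image$pixels, p3$image$pixels))
})

test_that("ground-truth masks satisfy their invariants across types and seeds", {
  for (ty in c("A", "B", "C", "D")) {
    for (s in 1:10) {
      ph <- generate_phantom(default_phantom_spec(ty, seed = s))
      am <- ph$truth$appendix_mask
      fm <- ph$truth$fascia_mask
      expect_false(any(am & fm))                    # disjoint
      # connectivity checks on the appendix neighbourhood (one ring of
      # background around the bounding box keeps the outer region connected)
      rc <- which(am, arr.ind = TRUE)
      sub <- am[(min(rc[, 1]) - 1):(max(rc[, 1]) + 1),
                (min(rc[, 2]) - 1):(max(rc[, 2]) + 1)]
      expect_equal(max(oracle_label(sub)), 1L)      # 8-connected
      # simply connected: every background component touches the border
      bg <- oracle_label(!sub)
      border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
      expect_setequal(setdiff(unique(as.vector(bg)), 0L), setdiff(border_labs, 0L))
      # appendix strictly below the fascia band
      spec <- ph$spec
      expect_gt(min(rc[, 1]), spec$fascia_row + spec$fascia_thickness)
    }
  }
})

test_that("appendix interior intensity matches the spec within 10 levels", {
  for (ty in c("A", "B", "C", "D")) {
    ph <- generate_phantom(default_phantom_spec(ty, seed = 3))
    expect_lt(abs(mean(ph$image$pixels[ph$truth$appendix_mask]) -
                  ph$spec$appendix_mean_intensity), 10)
  }
  # type C: appendix much darker than a 5-px dilation ring outside it
  ph <- generate_phantom(default_phantom_spec("C", seed = 7))
  am <- ph$truth$appendix_mask
  ring <- EBImage::imageData(EBImage::dilate(EBImage::Image(am * 1),
                                             EBImage::makeBrush(11, "disc"))) > 0 & !am
  expect_lt(mean(ph$image$pixels[am]), mean(ph$image$pixels[ring]))
})

test_that("minor axis is recoverable from the ground-truth mask", {
  for (ty in c("A", "C", "D")) {
    spec <- default_phantom_spec(ty, seed = 2)
    ph <- generate_phantom(spec)
    obj <- label_objects(ph$truth$appendix_mask, trace = FALSE)[[1]]
    res <- refine_and_measure(obj, spacing = spec$pixel_spacing)
    expect_lt(abs(res$diameter_mm - spec$appendix_axes[1]), 0.5)
  }
})

test_that("fascia gaps control the number of fascia segments", {
  spec <- phantom_spec("C", image_size = c(200, 300),
                       appendix_center = c(150, 150),
                       appendix_axes = c(9, 12),
                       appendix_mean_intensity = 55,
                       surround_mean_intensity = 170,
                       fascia_row = 60,
                       fascia_gap_columns = list(c(130, 169)), seed = 1)
  ph <- generate_phantom(spec)
  segs <- label_objects(ph$truth$fascia_mask, trace = FALSE)
  expect_length(segs, 2L)
})

test_that("phantoms serialize to PNG + YAML and read back identically", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom(default_phantom_spec("A", seed = 4))
  paths <- write_phantom(ph, dir)
  expect_true(all(file.exists(paths)))
  back <- read_image(paths[1], spacing_override = ph$spec$pixel_spacing)
  expect_identical(back$pixels, ph$image$pixels)
  mask_back <- png::readPNG(paths[2]) > 0.5
  expect_identical(mask_back, ph$truth$appendix_mask)
  y <- yaml::read_yaml(paths[4])
  expect_equal(y$pattern_type, "A")
  expect_equal(y$seed, 4)
})
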
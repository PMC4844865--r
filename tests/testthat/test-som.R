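# Hexagonal SOM: initialization, BMU search, training, quantization.

make_grid <- function(weights, positions = NULL) {
  # hand-built grid for oracle tests (bypasses init_som's >= 2 node guard)
  n <- length(weights)
  if (is.null(positions)) positions <- cbind(x = seq_len(n) - 1, y = 0)
  structure(list(rows = 1L, cols = n, weights = weights,
                 positions = positions, arrangement = "rectangular",
                 trained = TRUE, qe_history = numeric(0)),
            class = "som_grid")
}

test_that("initial weights are uniformly spaced with seeded jitter", {
  cfg <- som_config(seed = 9)
  g <- init_som(1, 4, cfg)
  expect_equal(g$weights, c(0, 85, 170, 255), tolerance = 2.1)
  g2 <- init_som(1, 4, cfg)
  expect_identical(g$weights, g2$weights)
  g3 <- init_som(1, 4, som_config(seed = 10))
  expect_false(identical(g$weights, g3$weights))
  expect_error(init_som(1, 1, cfg), "at least 2 nodes")
})

test_that("hexagonal arrangement gives interior nodes six unit neighbours", {
  g <- init_som(3, 3, som_config(seed = 1))
  d <- as.matrix(dist(g$positions))
  centre <- 5L  # node (row 2, col 2) in row-major order
  expect_equal(sum(abs(d[centre, ] - 1) < 1e-9), 6L)
  # rectangular arrangement has only 4 at unit distance
  gr <- init_som(3, 3, som_config(seed = 1), arrangement = "rectangular")
  dr <- as.matrix(dist(gr$positions))
  expect_equal(sum(abs(dr[centre, ] - 1) < 1e-9), 4L)
})

test_that("BMU is the brute-force nearest weight with low-index ties", {
  g <- make_grid(c(0, 128, 255))
  expect_equal(find_bmu(g, 100), 2L)
  expect_equal(find_bmu(g, 255), 3L)
  expect_equal(find_bmu(g, 64), 1L)   # equidistant 0/128: lower index wins

  set.seed(21)
  g16 <- init_som(4, 4, som_config(seed = 3))
  xs <- runif(10000, 0, 255)
  got <- vapply(xs, function(x) find_bmu(g16, x), integer(1))
  oracle <- apply(abs(outer(xs, g16$weights, "-")), 1, which.min)
  expect_identical(got, as.integer(oracle))
})

test_that("training converges to sample statistics and is reproducible", {
  # single node: fixed point is the (constant) sample value
  g1 <- make_grid(128, positions = cbind(x = 0, y = 0))
  tr <- som_train(g1, rep(90, 500), som_config(epochs = 20, seed = 4))
  expect_equal(tr$weights, 90, tolerance = 0.5)

  # 1x2 grid on a bimodal sample vs k-means centroids from the same start
  set.seed(8)
  samples <- c(rnorm(600, 40, 3), rnorm(600, 200, 3))
  samples <- pmin(pmax(samples, 0), 255)
  cfg <- som_config(epochs = 25, radius_start = 1, radius_end = 1e-4, seed = 5)
  g2 <- init_som(1, 2, cfg)
  init_w <- g2$weights
  tr2 <- som_train(g2, samples, cfg)
  km <- stats::kmeans(samples, centers = matrix(init_w), iter.max = 100,
                      algorithm = "Lloyd")
  expect_equal(sort(tr2$weights), sort(as.vector(km$centers)), tolerance = 5)

  # determinism: same seed, same result; different seed differs
  tr2b <- som_train(init_som(1, 2, cfg), samples, cfg)
  expect_identical(tr2$weights, tr2b$weights)

  # weights stay within the 8-bit range
  expect_true(all(tr2$weights >= 0 & tr2$weights <= 255))
})

test_that("mean quantization error trends downward over training", {
  set.seed(13)
  samples <- pmin(pmax(c(rnorm(2000, 60, 15), rnorm(2000, 180, 20)), 0), 255)
  cfg <- som_config(epochs = 20, seed = 6)
  tr <- som_train(init_som(4, 4, cfg), samples, cfg)
  qe <- tr$qe_history
  second_half <- qe[(length(qe) %/% 2):length(qe)]
  expect_true(all(diff(second_half) <= 1.0))
})

test_that("quantization replaces pixels by their BMU weight", {
  g <- make_grid(c(40, 200))
  img <- gi(matrix(c(10, 60, 150, 240), 2, 2))
  v <- matrix(TRUE, 2, 2)
  q <- som_quantize(img, v, g)
  expect_identical(as.vector(q$pixels), c(40L, 40L, 200L, 200L))
  expect_lte(length(unique(q$pixels[v])), 2L)

  # pixels already on the codebook are unchanged
  imgc <- gi(matrix(c(40, 200, 40, 200), 2, 2))
  expect_identical(som_quantize(imgc, v, g)$pixels, imgc$pixels)

  # invalid pixels become 0
  v2 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  q2 <- som_quantize(img, v2, g)
  expect_identical(as.vector(q2$pixels), c(40L, 0L, 200L, 0L))

  # per-pixel output equals the exhaustive nearest-codebook assignment
  set.seed(17)
  cfg <- som_config(seed = 2)
  g9 <- init_som(3, 3, cfg)
  img9 <- gi(matrix(sample(0:255, 300, replace = TRUE), 15, 20))
  v9 <- matrix(runif(300) < 0.8, 15, 20)
  q9 <- som_quantize(img9, v9, g9)
  oracle <- vapply(img9$pixels[v9], function(x) {
    floor(g9$weights[which.min(abs(g9$weights - x))] + 0.5)
  }, numeric(1))
  expect_identical(as.numeric(q9$pixels[v9]), oracle)
  expect_true(all(q9$pixels[!v9] == 0L))

  # idempotence: quantizing a quantized image is the identity
  qq <- som_quantize(q9, v9, g9)
  expect_identical(qq$pixels, q9$pixels)
})
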
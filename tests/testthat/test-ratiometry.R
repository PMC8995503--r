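make_pair <- function(h, w, gfun, rfun) {
  channel_image_pair(matrix(gfun(h * w), h, w), matrix(rfun(h * w), h, w))
}

test_that("tiling splits exactly, discards remainders, and is lossless", {
  pair <- make_pair(100, 100, function(n) runif(n, 0, 100),
                    function(n) runif(n, 0, 100))
  tiles <- subdivide_tiles(pair, 10)
  expect_length(tiles, 100)
  expect_true(all(vapply(tiles, function(t) all(dim(t$green) == c(10, 10)),
                         logical(1))))
  # 948-pixel composites tile into 100 sub-images of 94 x 94
  big <- make_pair(948, 948, function(n) runif(n), function(n) runif(n))
  bt <- subdivide_tiles(big, 10)
  expect_length(bt, 100)
  expect_identical(dim(bt[[1]]$green), c(94L, 94L))
  # reassembling the tiles reproduces the cropped composite exactly
  rows <- lapply(1:10, function(i) {
    do.call(cbind, lapply(bt[((i - 1) * 10 + 1):(i * 10)], `[[`, "green"))
  })
  expect_identical(do.call(rbind, rows), big$green[1:940, 1:940])
  # 1x1 grid is the identity
  small <- make_pair(5, 5, function(n) 1:n, function(n) 1:n)
  expect_identical(subdivide_tiles(small, 1)[[1]]$green, small$green)
  expect_error(subdivide_tiles(small, 6), "smaller than 1 pixel")
})

test_that("masks follow the dual-threshold rule", {
  zero <- make_pair(8, 8, function(n) rep(0, n), function(n) rep(0, n))
  expect_false(any(pixel_mask(zero, 0, 0)))
  pos <- make_pair(8, 8, function(n) runif(n, 1, 2), function(n) runif(n, 1, 2))
  expect_true(all(pixel_mask(pos, 0, 0)))
  pair <- channel_image_pair(matrix(c(5, 0, 5, 0), 2), matrix(c(5, 5, 0, 0), 2))
  expect_identical(sum(pixel_mask(pair, 1, 1)), 1L)
  expect_identical(sum(pixel_mask(pair, 1, mode = "red_only")), 2L)
  expect_error(pixel_mask(pair, -1), ">= 0")
})

test_that("pixelwise ratio equals the naive double-loop implementation", {
  set.seed(5)
  for (i in 1:10) {
    pair <- make_pair(17, 13, function(n) runif(n, 0, 300),
                      function(n) runif(n, 1, 300))
    mask <- matrix(runif(17 * 13) > 0.4, 17, 13)
    m <- pixelwise_ratio(pair, mask)
    expect_equal(m$mean_ratio,
                 brute_mean_ratio(pair$green, pair$red, mask),
                 tolerance = 1e-12)
    expect_identical(m$pixel_count, sum(mask))
  }
})

test_that("ratio identities: equality, scaling, channel-rescale invariance,
          empty mask", {
  r <- matrix(runif(100, 10, 50), 10, 10)
  same <- channel_image_pair(r, r)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(pixelwise_ratio(same, mask)$mean_ratio, 1.0)
  half <- channel_image_pair(0.5 * r, r)
  expect_equal(pixelwise_ratio(half, mask)$mean_ratio, 0.5)
  # simultaneous rescaling of both channels leaves the ratio unchanged
  g2 <- matrix(runif(100, 5, 40), 10, 10)
  a <- pixelwise_ratio(channel_image_pair(g2, r), mask)
  b <- pixelwise_ratio(channel_image_pair(7.3 * g2, 7.3 * r), mask)
  expect_equal(a$mean_ratio, b$mean_ratio)
  none <- pixelwise_ratio(same, matrix(FALSE, 10, 10))
  expect_identical(none$pixel_count, 0L)
  expect_true(is.na(none$mean_ratio))
  # ratio-of-sums alternative estimator
  ros <- pixelwise_ratio(channel_image_pair(g2, r), mask,
                         estimator = "ratio_of_sums")
  expect_equal(ros$mean_ratio, sum(g2) / sum(r))
})

test_that("percent of control behaves as a ratio of ratios", {
  r <- matrix(runif(64, 10, 50), 8, 8)
  mask <- matrix(TRUE, 8, 8)
  ctrl <- pixelwise_ratio(channel_image_pair(r, r), mask)
  expect_equal(percent_of_control(ctrl, ctrl), 100)
  halfm <- pixelwise_ratio(channel_image_pair(0.5 * r, r), mask)
  expect_equal(percent_of_control(halfm, ctrl), 50)
  none <- pixelwise_ratio(channel_image_pair(r, r), matrix(FALSE, 8, 8))
  expect_error(percent_of_control(halfm, none), "control")
})

test_that("replicate aggregation is pixel-weighted within and unweighted
          across replicates", {
  mk <- function(ratio, px) structure(list(mean_ratio = ratio,
                                           pixel_count = px,
                                           tile_id = NA),
                                      class = "ratio_measurement")
  one <- aggregate_replicates(list(a = list(list(mk(0.5, 100)))))
  expect_equal(one$mean_ratio, 0.5)
  expect_identical(one$n_replicates, 1L)
  two <- aggregate_replicates(list(a = list(list(mk(0.4, 10)),
                                            list(mk(0.4, 99)))))
  expect_equal(two$mean_ratio, 0.4)
  expect_equal(two$sem, 0)
  # within-replicate weighting: 3:1 pixel weights
  w <- aggregate_replicates(list(a = list(list(mk(1, 30), mk(0.5, 10)))))
  expect_equal(w$mean_ratio, (1 * 30 + 0.5 * 10) / 40)
  expect_equal(w$total_pixels, 40)
})

test_that("aggregation recovers a known inter-replicate SD in simulation", {
  set.seed(99)
  sems <- replicate(500, {
    ratios <- rnorm(3, mean = 0.35, sd = 0.02)
    ms <- lapply(ratios, function(r) {
      structure(list(mean_ratio = r, pixel_count = 1000, tile_id = NA),
                class = "ratio_measurement")
    })
    aggregate_replicates(list(cond = as.list(ms)))$sem
  })
  expect_equal(mean(sems), 0.02 / sqrt(3), tolerance = 0.05 * 4)
})

test_that("synthetic scenes are seed-deterministic down to TIFF bytes", {
  sc <- synthetic_scene(n_cells = 8, seed = 3)
  r1 <- generate_synthetic_pair(sc)
  r2 <- generate_synthetic_pair(sc)
  expect_identical(r1$pair$green, r2$pair$green)
  expect_identical(r1$pair$red, r2$pair$red)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_synthetic_pair(r1, d1)
  p2 <- write_synthetic_pair(r2, d2)
  for (ch in c("green", "red")) {
    expect_identical(readBin(p1[[ch]], "raw", 4e6),
                     readBin(p2[[ch]], "raw", 4e6))
  }
  # sidecar parses and carries the ground truth
  truth <- jsonlite::read_json(p1[["truth"]])
  expect_equal(truth$n_foreground_pixels, r1$truth$n_foreground_pixels)
  # written TIFFs read back to the same intensities
  back <- read_image_pair(p1[["green"]], p1[["red"]])
  expect_equal(back$green, r1$pair$green)
})

test_that("synthetic scene edge cases: empty scene, noiseless equality,
          infeasible packing", {
  bg <- generate_synthetic_pair(synthetic_scene(n_cells = 0, seed = 1,
                                                background_mean = 0,
                                                background_sd = 0))
  expect_true(all(bg$pair$green == 0) && all(bg$pair$red == 0))
  clean <- generate_synthetic_pair(
    synthetic_scene(n_cells = 5, true_fraction = 1, noise_sd = 0,
                    background_mean = 0, background_sd = 0, seed = 2))
  fg <- clean$truth$foreground
  expect_identical(clean$pair$green[fg], clean$pair$red[fg])
  expect_error(generate_synthetic_pair(
    synthetic_scene(n_cells = 500, width = 64, height = 64, seed = 1)),
    "infeasible packing")
})

test_that("foreground masks recover painted cells at background + 3 SD", {
  r <- generate_synthetic_pair(synthetic_scene(n_cells = 20, seed = 17))
  thr <- r$truth$suggested_threshold
  mask <- pixel_mask(r$pair, thr, thr)
  recall <- sum(mask & r$truth$foreground) / sum(r$truth$foreground)
  expect_gte(recall, 0.99)
})

test_that("the closed loop recovers a known attenuation fraction", {
  ctrl <- generate_synthetic_pair(synthetic_scene(true_fraction = 1,
                                                  seed = 400))
  thr <- ctrl$truth$suggested_threshold
  mc <- pixelwise_ratio(ctrl$pair, pixel_mask(ctrl$pair, thr, thr))
  samp <- generate_synthetic_pair(synthetic_scene(true_fraction = 0.35,
                                                  seed = 401))
  ms <- pixelwise_ratio(samp$pair, pixel_mask(samp$pair, thr, thr))
  expect_gte(samp$truth$n_foreground_pixels, 1000)
  expect_lt(abs(percent_of_control(ms, mc) - 35), 2)
})
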
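test_that("pipeline_config validates levels and kernel size", {
  expect_error(pipeline_config(101, 40), "scale_level")
  expect_error(pipeline_config(90, -1), "merge_level")
  expect_error(pipeline_config(90, 40, kernel_size = 4), "odd")
  expect_error(pipeline_config(90, 40, kernel_size = 21), "odd|19")
  cfg <- pipeline_config(90, 40)
  expect_equal(cfg$segment_algorithm, "EDGE")
  expect_equal(cfg$merge_algorithm, "FAST_LAMBDA")
})

test_that("gradient is zero on constants and maximal along a step edge", {
  t <- raster_tile(matrix(4, 8, 8))
  expect_true(all(gradient_map(t)$pixels == 0))
  px <- matrix(0, 10, 10); px[, 6:10] <- 7
  g <- gradient_map(raster_tile(px), smooth = FALSE)$pixels
  expect_true(all(g[, c(1:3, 8:10)] == 0))
  expect_true(all(g[, 5:6] > 0))
  expect_equal(which.max(colSums(g)), 5)
})

test_that("raw gradient matches the direct Sobel stencil", {
  for (seed in 1:10) {
    t <- random_tile(seed + 200, nodata_frac = if (seed %% 2) 0.1 else 0)
    expect_equal(gradient_map(t, smooth = FALSE)$pixels, oracle_sobel(t),
                 tolerance = 1e-9)
  }
})

test_that("watershed labels every valid pixel with consecutive 4-connected ids", {
  sc <- random_segmented_scene(3)
  expect_valid_segment_map(sc$seg, sc$hp)
})

test_that("constant-zero gradient yields a single segment", {
  g <- raster_tile(matrix(0, 12, 12))
  seg <- watershed_segment(g, 50)
  expect_equal(seg$n_segments, 1L)
  expect_true(all(seg$labels == 1L))
  expect_error(watershed_segment(tile_like(g, matrix(NA_real_, 12, 12)), 50),
               "all-nodata")
})

test_that("two separated bright blobs produce two distinct blob segments", {
  px <- matrix(0, 40, 40)
  for (d in -2:2) for (e in -2:2) {
    if (d^2 + e^2 <= 5) { px[10 + d, 10 + e] <- 50; px[28 + d, 30 + e] <- 50 }
  }
  t <- raster_tile(px, pixel_size = 1, origin = c(0, 40))
  hp <- high_pass_filter(t)
  seg <- watershed_segment(gradient_map(hp), 50, intensity = hp)
  lab1 <- seg$labels[10, 10]; lab2 <- seg$labels[28, 30]
  expect_true(lab1 != seg$labels[20, 20])
  expect_true(lab2 != seg$labels[20, 20])
  expect_true(lab1 != lab2)
})

test_that("segment count is nonincreasing in the scale level", {
  for (seed in 1:4) {
    sc <- generate_scene(scene_spec(width_px = 120L, height_px = 120L,
                                    n_whales = 6L, seed = seed))
    hp <- high_pass_filter(sc$tile)
    g <- gradient_map(hp)
    ns <- vapply(c(0, 30, 60, 90),
                 function(s) watershed_segment(g, s, intensity = hp)$n_segments, 0L)
    expect_true(all(diff(ns) <= 0))
  }
})

test_that("merge cost has the lambda-schedule functional form", {
  expect_equal(merge_cost(3, 3, 10, 20, 4), 0)  # equal means merge free
  expect_equal(merge_cost(0, 2, 1, 1, 1), 2.0)
  # symmetry and border scaling
  expect_equal(merge_cost(1, 5, 7, 3, 4), merge_cost(5, 1, 3, 7, 4))
  expect_equal(merge_cost(1, 5, 7, 3, 8), merge_cost(1, 5, 7, 3, 4) / 2)
  expect_error(merge_cost(1, 2, 0, 1, 1), "sizes")
  expect_error(merge_cost(1, 2, 1, 1, 0), "adjacent")
})

test_that("merge level 0 is the identity and level 100 merges everything", {
  sc <- random_segmented_scene(8)
  seg0 <- watershed_segment(gradient_map(sc$hp), 90, intensity = sc$hp)
  expect_identical(fast_lambda_merge(seg0, sc$hp, 0)$labels, seg0$labels)
  merged <- fast_lambda_merge(seg0, sc$hp, 100)
  expect_equal(merged$n_segments, 1L)
})

test_that("segment count is nonincreasing in the merge level", {
  for (seed in 1:4) {
    sc <- random_segmented_scene(seed + 30)
    seg0 <- watershed_segment(gradient_map(sc$hp), 90, intensity = sc$hp)
    ns <- vapply(c(0, 20, 40, 70, 100),
                 function(m) fast_lambda_merge(seg0, sc$hp, m)$n_segments, 0L)
    expect_true(all(diff(ns) <= 0))
  }
})

test_that("pixel count is conserved and maps stay valid through merging", {
  sc <- random_segmented_scene(12)
  seg0 <- watershed_segment(gradient_map(sc$hp), 90, intensity = sc$hp)
  n_valid <- sum(!sc$hp$nodata_mask)
  expect_equal(sum(segment_sizes(seg0)), n_valid)
  merged <- fast_lambda_merge(seg0, sc$hp, 40)
  expect_equal(sum(segment_sizes(merged)), n_valid)
  expect_valid_segment_map(merged, sc$hp)
})

test_that("zero-noise blob scenes are recovered exactly by the default pipeline", {
  for (seed in 1:3) {
    sc <- generate_scene(scene_spec(n_whales = 6L, noise_sigma = 0,
                                    swell_amplitude = 0, seed = seed))
    res <- run_detect(sc$tile, default_ruleset())
    cc <- match_detections(res$objects, sc$truth, buffer_m = 1)
    expect_equal(length(res$objects), 6L)
    expect_equal(cc$fp, 0L)
    expect_equal(cc$fn, 0L)
  }
})
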
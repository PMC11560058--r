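test_that("scene specs validate their parameters", {
  expect_error(scene_spec(n_whales = -1), "n_whales")
  expect_error(scene_spec(whale_length_m = c(0.5, 4.5)), "whale_length_m")
  expect_error(scene_spec(submerged_fraction = 1.5), "submerged_fraction")
  expect_error(scene_spec(noise_sigma = -1), "noise_sigma")
})

test_that("a whale-free noise-free spec renders a constant background", {
  sc <- generate_scene(scene_spec(n_whales = 0L, noise_sigma = 0,
                                  swell_amplitude = 0, seed = 3))
  expect_equal(nrow(sc$truth$points), 0)
  expect_true(all(sc$tile$pixels == sc$tile$pixels[1, 1]))
})

test_that("the same seed reproduces the scene bit for bit", {
  s1 <- generate_scene(scene_spec(seed = 17, group_fraction = 0.4,
                                  submerged_fraction = 0.3))
  s2 <- generate_scene(scene_spec(seed = 17, group_fraction = 0.4,
                                  submerged_fraction = 0.3))
  expect_identical(s1$tile$pixels, s2$tile$pixels)
  expect_identical(s1$truth$points, s2$truth$points)
  expect_identical(s1$truth$confidence, s2$truth$confidence)
})

test_that("placement produces the requested count of separated whales", {
  sc <- generate_scene(scene_spec(n_whales = 25L, group_fraction = 0, seed = 5))
  expect_equal(nrow(sc$truth$points), 25)
  d <- as.matrix(dist(sc$truth$points))
  diag(d) <- Inf
  expect_gt(min(d), 0)  # no coincident whales
  # all centroids inside the scene
  ext <- 280 * 0.31
  expect_true(all(sc$truth$points[, 1] > 0 & sc$truth$points[, 1] < ext))
  expect_true(all(sc$truth$points[, 2] > 0 & sc$truth$points[, 2] < ext))
})

test_that("infeasible placement fails with a clear error", {
  expect_error(generate_scene(scene_spec(width_px = 40L, height_px = 40L,
                                         n_whales = 60L, seed = 1)),
               "infeasible")
})

test_that("submerged whales are dimmer and rated probable", {
  spec <- scene_spec(submerged_fraction = 0.5, seed = 9)
  sc <- generate_scene(spec)
  expect_equal(sum(sc$truth$confidence == 1L), round(0.5 * 25))
  surf <- generate_scene(scene_spec(submerged_fraction = 0, seed = 9))
  expect_lt(max(sc$tile$pixels), max(surf$tile$pixels) + 1e-9)
})

test_that("every scenario preset renders and round-trips through raster io", {
  suite <- scenario_suite(seed = 2)
  expect_setequal(names(suite),
                  c("clean", "grouped", "submerged", "no_whale", "near_land"))
  for (nm in names(suite)) {
    sc <- generate_scene(suite[[nm]])
    f <- tempfile(fileext = ".tif")
    write_raster(sc$tile, f)
    r <- read_raster(f)
    expect_identical(r$pixels, sc$tile$pixels, label = nm)
  }
  expect_equal(nrow(generate_scene(suite$no_whale)$truth$points), 0)
})

test_that("grouped scenes contain touching or crossing pairs", {
  sc <- generate_scene(scene_spec(group_fraction = 0.4, seed = 11))
  d <- as.matrix(dist(sc$truth$points))
  diag(d) <- Inf
  # at least one pair of centroids closer than a whale length
  expect_lt(min(d), 4.5)
})

test_that("near-land scenes mask out the bright landmass", {
  suite <- scenario_suite(seed = 4)
  sc <- generate_scene(suite$near_land)
  masked <- apply_land_mask(sc$tile, sc$masks)
  expect_gt(sum(masked$nodata_mask), 0.05 * length(masked$pixels))
  # land is brighter than open water before masking
  expect_gt(mean(sc$tile$pixels[masked$nodata_mask]),
            mean(sc$tile$pixels[!masked$nodata_mask]))
})
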
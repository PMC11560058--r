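test_that("texture statistics are exact on degenerate windows", {
  # constant tile: variance 0, range 0, entropy 0 (single occupied bin)
  t <- raster_tile(matrix(4, 8, 8))
  tx <- texture_rasters(t)
  expect_true(all(tx$variance$pixels == 0))
  expect_true(all(tx$range$pixels == 0))
  expect_true(all(tx$entropy$pixels == 0))
  expect_true(all(tx$mean$pixels == 4))
})

test_that("nine equidistinct window values give entropy -log2(9)", {
  # 3x3 tile whose values land in 9 distinct histogram bins
  t <- raster_tile(matrix(seq(0, 80, by = 10), 3, 3))
  tx <- texture_rasters(t, 3, nbins = 64)
  expect_equal(tx$entropy$pixels[2, 2], -log2(9), tolerance = 1e-12)
  expect_equal(tx$mean$pixels[2, 2], 40)
  expect_equal(tx$range$pixels[2, 2], 80)
})

test_that("texture rasters match the sliding-window oracle", {
  for (seed in 1:8) {
    t <- random_tile(seed + 300, h = 14, w = 14,
                     nodata_frac = if (seed %% 2) 0.1 else 0)
    got <- texture_rasters(t)
    want <- oracle_texture(t)
    for (nm in names(want)) {
      expect_equal(got[[nm]]$pixels, want[[nm]], tolerance = 1e-9,
                   label = paste("texture", nm, "seed", seed))
    }
  }
  expect_error(texture_rasters(random_tile(1, h = 4, w = 4), 5), "larger|odd")
})

test_that("spectral statistics of a 2x2 square segment are exact", {
  px <- matrix(0, 5, 5)
  px[2:3, 2:3] <- c(1, 2, 3, 4)
  t <- raster_tile(px, pixel_size = 1, origin = c(0, 5))
  lab <- matrix(1L, 5, 5); lab[2:3, 2:3] <- 2L
  rec <- compute_attributes(segment_map(lab), t)
  expect_equal(rec$spectral_mean[2], 2.5)
  expect_equal(rec$spectral_min[2], 1)
  expect_equal(rec$spectral_max[2], 4)
  expect_equal(rec$spectral_std[2], sqrt(mean((1:4 - 2.5)^2)))
  expect_equal(rec$area_px[2], 4)
  expect_equal(rec$area_m2[2], 4)
  expect_equal(rec$centroid_x[2], 2)
  expect_equal(rec$centroid_y[2], 5 - 2)
  expect_equal(rec$elongation[2], 1)
})

test_that("a thin horizontal bar has direction ~0 and high elongation", {
  px <- matrix(0, 8, 14); px[4, 3:12] <- 9
  t <- raster_tile(px, pixel_size = 1, origin = c(0, 8))
  lab <- matrix(1L, 8, 14); lab[4, 3:12] <- 2L
  rec <- compute_attributes(segment_map(lab), t)
  bar <- rec[2, ]
  expect_lt(min(bar$main_direction_deg, 180 - bar$main_direction_deg), 1)
  expect_gt(bar$elongation, 5)
  expect_equal(bar$major_length_m, 4 * sqrt(99 / 12 + 1 / 12), tolerance = 1e-9)
  expect_equal(bar$n_holes, 0)
})

test_that("a filled disk approaches elongation 1 and roundness 1", {
  h <- 41
  px <- matrix(0, h, h)
  disk <- (row(px) - 21)^2 + (col(px) - 21)^2 <= 15^2
  px[disk] <- 5
  lab <- matrix(1L, h, h); lab[disk] <- 2L
  rec <- compute_attributes(segment_map(lab), raster_tile(px, pixel_size = 1))
  expect_equal(rec$elongation[2], 1, tolerance = 0.02)
  expect_equal(rec$roundness[2], 1, tolerance = 0.06)
  expect_equal(rec$solidity[2], 1, tolerance = 0.07)
})

test_that("holes are counted and hole_solid_ratio reflects them", {
  px <- matrix(0, 6, 6)
  ring <- rbind(c(2,2), c(2,3), c(2,4), c(3,2), c(3,4), c(4,2), c(4,3), c(4,4))
  lab <- matrix(1L, 6, 6); lab[ring] <- 2L
  rec <- compute_attributes(segment_map(lab), raster_tile(px, pixel_size = 1))
  expect_equal(rec$n_holes[2], 1)
  expect_equal(rec$hole_solid_ratio[2], 8 / 9)
})

test_that("attributes match per-segment brute-force recomputation", {
  checked <- c("area_px", "area_m2", "perimeter_m", "spectral_mean",
               "spectral_min", "spectral_max", "spectral_std", "tx_mean",
               "tx_variance", "tx_entropy", "tx_range", "major_length_m",
               "minor_length_m", "elongation", "centroid_x", "centroid_y")
  for (seed in 1:5) {
    sc <- random_segmented_scene(seed + 50, n_whales = 2L, size = 48L)
    tx <- texture_rasters(sc$hp)
    rec <- compute_attributes(sc$seg, sc$hp, textures = tx)
    lab <- sc$seg$labels
    for (s in sample(seq_len(sc$seg$n_segments), min(6, sc$seg$n_segments))) {
      idx <- which(lab == s)
      rs <- (idx - 1) %% nrow(lab) + 1
      cs <- (idx - 1) %/% nrow(lab) + 1
      want <- oracle_segment_attrs(
        rs, cs, sc$hp$pixels[idx],
        lapply(tx, function(t) t$pixels[idx]),
        sc$hp$pixel_size, sc$hp$origin)
      for (nm in checked) {
        expect_equal(rec[[nm]][s], want[[nm]], tolerance = 1e-6,
                     label = paste("attr", nm, "seed", seed, "seg", s))
      }
    }
  }
})

test_that("attributes are invariant to segment relabeling", {
  sc <- random_segmented_scene(61, n_whales = 2L, size = 48L)
  rec <- compute_attributes(sc$seg, sc$hp)
  n <- sc$seg$n_segments
  perm <- sample(n)
  lab2 <- matrix(0L, nrow(sc$seg$labels), ncol(sc$seg$labels))
  lab2[sc$seg$labels > 0] <- perm[sc$seg$labels[sc$seg$labels > 0]]
  rec2 <- compute_attributes(segment_map(lab2), sc$hp)
  for (s in seq_len(n)) {
    expect_equal(rec2$spectral_mean[perm[s]], rec$spectral_mean[s])
    expect_equal(rec2$area_px[perm[s]], rec$area_px[s])
    expect_equal(rec2$elongation[perm[s]], rec$elongation[s])
  }
})

test_that("size-weighted mean of segment means recovers the global mean", {
  sc <- random_segmented_scene(71, n_whales = 2L, size = 48L)
  rec <- compute_attributes(sc$seg, sc$hp)
  global <- mean(sc$hp$pixels[!sc$hp$nodata_mask])
  expect_equal(sum(rec$spectral_mean * rec$area_px) / sum(rec$area_px),
               global, tolerance = 1e-9)
})
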
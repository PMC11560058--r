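cc <- function(tp, fp, fn) confusion_counts(tp = tp, fp = fp, fn = fn)

test_that("confusion counts enforce tp + fn = identified and nonnegativity", {
  expect_error(confusion_counts(3, 0, 1, identified = 5), "identified")
  expect_error(confusion_counts(-1, 0, 0), "nonnegative")
  x <- confusion_counts(30, 15, 2)
  expect_equal(x$identified, 32L)
  expect_equal(x$total_count, 45L)
})

test_that("rates reproduce the published training-tile values", {
  expect_equal(fnr(cc(30, 15, 2)), 6.25)
  expect_equal(fpr(cc(30, 15, 2)), 46.88)
  expect_equal(acd(cc(30, 15, 2)), 53.13)
  expect_equal(fpr(cc(32, 1, 0)), 3.13)
})

test_that("rates reproduce the published test-tile values", {
  expect_equal(fnr(cc(184, 0, 6)), 3.16)
  expect_equal(acd(cc(187, 6, 3)), 4.74)
  expect_equal(fnr(cc(190, 0, 0)), 0)
  expect_equal(fpr(cc(190, 0, 0)), 0)
})

test_that("metrics are undefined without observer-identified whales", {
  empty <- confusion_counts(0, 3, 0)
  expect_error(fnr(empty), "undefined")
  expect_error(fpr(empty), "undefined")
  expect_error(acd(empty), "undefined")
})

test_that("acd equals fnr plus fpr within rounding for random counts", {
  set.seed(7)
  for (rep in 1:50) {
    x <- cc(sample(0:200, 1), sample(0:50, 1), sample(0:50, 1))
    if (x$identified == 0) next
    expect_lte(abs(acd(x) - (fnr(x) + fpr(x))), 0.01 + 1e-9)
    expect_gte(fnr(x), 0); expect_lte(fnr(x), 100)
  }
})

test_that("matching covers points inside or within the buffer of footprints", {
  ps <- 0.31
  objs <- lapply(1:3, function(k) {
    detection_object(k, k, cbind(5, 5 + 10 * (k - 1)),
                     origin = c(0, 20 * ps), pixel_size = ps)
  })
  pts <- t(vapply(objs, function(o) o$centroid_xy, numeric(2)))
  gt <- ground_truth_set(pts)
  m <- match_detections(objs, gt, buffer_m = 1)
  expect_equal(c(m$tp, m$fp, m$fn), c(3L, 0L, 0L))
  # no objects: every point is a miss, no false positives
  m0 <- match_detections(list(), ground_truth_set(cbind(1:5, 1:5)), 1)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0L, 0L, 5L))
  # one object covering two points counts two TPs and no FP
  big <- list(detection_object(1, 1, cbind(rep(3:6, each = 4), rep(3:6, 4)),
                               origin = c(0, 10), pixel_size = 1))
  two <- ground_truth_set(cbind(c(3.5, 5.5), c(6.5, 5.0)))
  m2 <- match_detections(big, two, buffer_m = 1)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(2L, 0L, 0L))
})

test_that("matching agrees with the all-pairs distance oracle", {
  for (seed in 1:10) {
    objs <- random_objects(seed + 600, n_obj = sample(2:6, 1))
    set.seed(seed + 900)
    gt <- ground_truth_set(cbind(runif(8, 0, 12), runif(8, 0, 12)))
    for (buf in c(0.5, 1, 2)) {
      got <- match_detections(objs, gt, buffer_m = buf)
      want <- oracle_match(objs, gt, buf)
      expect_equal(got$tp, want$tp)
      expect_equal(got$fp, want$fp)
      expect_equal(got$fn, want$fn)
    }
  }
})

test_that("metrics are invariant to permutation of objects and points", {
  objs <- random_objects(33, n_obj = 5)
  set.seed(34)
  gt <- ground_truth_set(cbind(runif(6, 0, 12), runif(6, 0, 12)))
  a <- match_detections(objs, gt, 1)
  b <- match_detections(rev(objs), ground_truth_set(gt$points[6:1, ]), 1)
  expect_equal(unclass(a)[c("tp", "fp", "fn")], unclass(b)[c("tp", "fp", "fn")])
})

test_that("metrics_report composes the accuracy-matrix row", {
  objs <- random_objects(71, n_obj = 3)
  pts <- t(vapply(objs, function(o) o$centroid_xy, numeric(2)))
  rep <- metrics_report(objs, ground_truth_set(pts), "CA#10", "synthetic")
  expect_equal(rep$total_count, 3L)
  expect_equal(rep$fnr_pct, 0)
  expect_equal(rep$fpr_pct, 0)
  expect_equal(rep$acd_pct, 0)
  expect_equal(rep$algorithm_id, "CA#10")
})

test_that("confidence filtering restricts matching to obvious whales", {
  objs <- random_objects(81, n_obj = 2)
  pts <- rbind(objs[[1]]$centroid_xy, c(100, 100))
  gt <- ground_truth_set(pts, confidence = c(2L, 1L))
  all_pts <- match_detections(objs, gt, 1, min_confidence = 1L)
  only_sure <- match_detections(objs, gt, 1, min_confidence = 2L)
  expect_equal(all_pts$identified, 2L)
  expect_equal(only_sure$identified, 1L)
})

test_that("consensus truth keeps points agreed by both observers", {
  g1 <- ground_truth_set(cbind(c(0, 10, 20), c(0, 0, 0)))
  g2 <- ground_truth_set(cbind(c(0.4, 30), c(0.3, 0)))
  cons <- consensus_truth(g1, g2, buffer_m = 1)
  expect_equal(nrow(cons$points), 1)
  expect_equal(cons$points[1, ], c(x = 0, y = 0))
})
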
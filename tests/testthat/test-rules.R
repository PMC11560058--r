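test_that("the eleven published candidate algorithms are reproduced", {
  expect_length(candidate_ids(), 11)
  ca10 <- candidate_algorithm("CA#10")
  expect_equal(ca10$config$scale_level, 90)
  expect_equal(ca10$config$merge_level, 40)
  expect_equal(ca10$config$kernel_size, 3L)
  expect_equal(vapply(ca10$rules, `[[`, "", "attribute"),
               c("spectral_mean", "tx_variance"))
  expect_equal(vapply(ca10$rules, `[[`, 0, "lower"), c(35, 1500))
  ca2 <- candidate_algorithm("CA#2")
  expect_equal(ca2$config$scale_level, 80)
  expect_equal(ca2$config$merge_level, 70)
  expect_length(ca2$rules, 1)
  expect_equal(ca2$rules[[1]]$lower, 40)
  ca4 <- candidate_algorithm("CA#4")
  expect_equal(c(ca4$config$scale_level, ca4$config$merge_level), c(30, 10))
  expect_equal(ca4$rules[[2]]$lower, -0.80)
  expect_equal(ca4$rules[[2]]$upper, -0.44)
  expect_true(ca4$rules[[2]]$lower_closed && ca4$rules[[2]]$upper_closed)
  expect_error(candidate_algorithm("CA#12"), "unknown")
})

test_that("classification applies strict open bounds and inclusive ranges", {
  rec <- data.frame(segment_id = 1:4,
                    spectral_mean = c(36, 35, 40, 34),
                    tx_variance = c(1501, 1501, 1500, 2000),
                    tx_entropy = c(-0.80, -0.44, -0.435, -0.81))
  ca10 <- candidate_algorithm("CA#10")
  expect_equal(classify_segments(rec, ca10), 1L)  # strict > on both rules
  rng <- rule_set("rng", list(rule("tx_entropy", -0.80, -0.44,
                                   lower_closed = TRUE, upper_closed = TRUE)),
                  pipeline_config(90, 40))
  expect_equal(classify_segments(rec, rng), c(1L, 2L))  # endpoints included
  bad <- rule_set("bad", list(rule("no_such_attr", 0)), pipeline_config(1, 1))
  expect_error(classify_segments(rec, bad), "unknown attribute")
})

test_that("classification agrees with direct filter evaluation and is monotone", {
  set.seed(404)
  for (rep in 1:10) {
    rec <- data.frame(segment_id = 1:50,
                      spectral_mean = rnorm(50, 40, 20),
                      tx_variance = runif(50, 0, 4000))
    thr_m <- runif(1, 20, 60); thr_v <- runif(1, 500, 3000)
    rs <- rule_set("r", list(rule("spectral_mean", thr_m),
                             rule("tx_variance", thr_v)),
                   pipeline_config(90, 40))
    want <- rec$segment_id[rec$spectral_mean > thr_m & rec$tx_variance > thr_v]
    got <- classify_segments(rec, rs)
    expect_identical(got, as.integer(want))
    # relaxing a bound never removes a detection
    rs2 <- rule_set("r2", list(rule("spectral_mean", thr_m - 10),
                               rule("tx_variance", thr_v)),
                    pipeline_config(90, 40))
    expect_true(all(got %in% classify_segments(rec, rs2)))
  }
})

test_that("rule bounds must be ordered", {
  expect_error(rule("x", lower = 2, upper = 1), "lower <= upper")
})

test_that("grouping joins touching segments and separates distant ones", {
  fps <- list(cbind(c(5, 5), c(5, 6)),     # A
              cbind(7, 6),                 # shares a corner gap with A
              cbind(30, 30))               # far away
  objs <- group_segments(fps, gap_px = 2, pixel_size = 1, origin = c(0, 40))
  expect_length(objs, 2)
  expect_equal(objs[[1]]$member_segments, c(1L, 2L))
  # gap 0: only direct contact joins
  objs0 <- group_segments(fps, gap_px = 0, pixel_size = 1)
  expect_length(objs0, 3)
  # two segments 50 px apart stay apart at gap 2
  far <- list(cbind(5, 5), cbind(5, 55))
  expect_length(group_segments(far, gap_px = 2), 2)
  expect_error(group_segments(far, gap_px = -1), ">= 0")
  expect_length(group_segments(list(), 2), 0)
})

test_that("grouping matches the union-find oracle and ignores input order", {
  skip_if_not_installed("igraph")
  set.seed(505)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    fps <- lapply(seq_len(n), function(k) {
      r0 <- sample(1:30, 1); c0 <- sample(1:30, 1)
      cbind(r0 + sample(0:2, 2, TRUE), c0 + sample(0:2, 2, TRUE))
    })
    gap <- sample(c(0, 1, 2, 3), 1)
    objs <- group_segments(fps, gap_px = gap, pixel_size = 1)
    want <- oracle_group_partition(fps, gap)
    got <- integer(n)
    for (k in seq_along(objs)) got[objs[[k]]$member_segments] <- k
    # same partition up to label names
    expect_equal(length(unique(got)), length(unique(want)))
    for (a in seq_len(n)) for (b in seq_len(n)) {
      expect_equal(got[a] == got[b], want[a] == want[b])
    }
    # permutation invariance
    perm <- sample(n)
    objs_p <- group_segments(fps[perm], gap_px = gap, pixel_size = 1,
                             segment_ids = perm)
    got_p <- integer(n)
    for (k in seq_along(objs_p)) got_p[objs_p[[k]]$member_segments] <- k
    for (a in seq_len(n)) for (b in seq_len(n)) {
      expect_equal(got_p[a] == got_p[b], got[a] == got[b])
    }
    expect_lte(length(objs), n)
  }
})
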
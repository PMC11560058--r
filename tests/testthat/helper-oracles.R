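# Brute-force reference implementations used to cross-check the package's
# compiled kernels, plus small fixture builders. Everything here is written
# as plainly as possible (double loops, no shared code with the package
# internals) so the two routes are independent.

random_tile <- function(seed, h = NULL, w = NULL, nodata_frac = 0,
                        pixel_size = 0.31) {
  set.seed(seed)
  if (is.null(h)) h <- sample(8:32, 1)
  if (is.null(w)) w <- sample(8:32, 1)
  px <- matrix(rnorm(h * w, mean = 50, sd = 30), h, w)
  mask <- matrix(runif(h * w) < nodata_frac, h, w)
  raster_tile(px, mask, pixel_size = pixel_size, origin = c(0, h * pixel_size))
}

# high-pass: center weight = n valid neighbours, neighbours -1, replicated
# edges, nodata skipped
oracle_highpass <- function(tile, w = 3) {
  px <- tile$pixels
  nd <- tile$nodata_mask
  h <- nrow(px); wd <- ncol(px); r <- w %/% 2
  out <- matrix(NA_real_, h, wd)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  for (i in seq_len(h)) for (j in seq_len(wd)) {
    if (nd[i, j]) next
    s <- 0; n <- 0
    for (di in -r:r) for (dj in -r:r) {
      if (di == 0 && dj == 0) next
      ii <- clamp(i + di, 1, h); jj <- clamp(j + dj, 1, wd)
      if (!nd[ii, jj]) { s <- s + px[ii, jj]; n <- n + 1 }
    }
    out[i, j] <- n * px[i, j] - s
  }
  out
}

# Sobel magnitude, replicate edges, nodata neighbours replaced by center
oracle_sobel <- function(tile) {
  px <- tile$pixels
  nd <- tile$nodata_mask
  h <- nrow(px); wd <- ncol(px)
  out <- matrix(NA_real_, h, wd)
  clamp <- function(v, lo, hi) min(max(v, lo), hi)
  for (i in seq_len(h)) for (j in seq_len(wd)) {
    if (nd[i, j]) next
    v <- matrix(0, 3, 3)
    for (di in -1:1) for (dj in -1:1) {
      ii <- clamp(i + di, 1, h); jj <- clamp(j + dj, 1, wd)
      v[di + 2, dj + 2] <- if (nd[ii, jj]) px[i, j] else px[ii, jj]
    }
    gx <- sum(v[, 3] * c(1, 2, 1)) - sum(v[, 1] * c(1, 2, 1))
    gy <- sum(v[3, ] * c(1, 2, 1)) - sum(v[1, ] * c(1, 2, 1))
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

# moving-window texture statistics, window clipped to the image
oracle_texture <- function(tile, k = 3, nbins = 64) {
  px <- tile$pixels
  nd <- tile$nodata_mask
  h <- nrow(px); wd <- ncol(px); r <- k %/% 2
  v <- px[!nd]
  gmin <- min(v); gmax <- max(v)
  out <- list(mean = matrix(NA_real_, h, wd), variance = matrix(NA_real_, h, wd),
              entropy = matrix(NA_real_, h, wd), range = matrix(NA_real_, h, wd))
  for (i in seq_len(h)) for (j in seq_len(wd)) {
    if (nd[i, j]) next
    ri <- max(1, i - r):min(h, i + r)
    ci <- max(1, j - r):min(wd, j + r)
    vals <- px[ri, ci][!nd[ri, ci]]
    out$mean[i, j] <- mean(vals)
    out$variance[i, j] <- mean((vals - mean(vals))^2)
    out$range[i, j] <- max(vals) - min(vals)
    b <- if (gmax > gmin) {
      pmin(pmax(floor((vals - gmin) / (gmax - gmin) * nbins), 0), nbins - 1)
    } else rep(0, length(vals))
    p <- table(b) / length(vals)
    out$entropy[i, j] <- sum(p * log2(p))
  }
  out
}

# per-segment attributes recomputed independently from the pixel list
oracle_segment_attrs <- function(rs, cs, vals, tx_list, pixel_size, origin) {
  n <- length(rs)
  x <- cs - 0.5; y <- -(rs - 0.5)
  # perimeter: exposed 4-edges by direct neighbour lookup
  key <- paste(rs, cs)
  perim <- 0
  for (q in seq_len(n)) {
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      if (!(paste(rs[q] + d[1], cs[q] + d[2]) %in% key)) perim <- perim + 1
    }
  }
  # moment ellipse via eigen decomposition
  covm <- matrix(c(mean(x^2) - mean(x)^2 + 1 / 12,
                   mean(x * y) - mean(x) * mean(y),
                   mean(x * y) - mean(x) * mean(y),
                   mean(y^2) - mean(y)^2 + 1 / 12), 2, 2)
  ev <- eigen(covm, symmetric = TRUE)
  major <- 4 * sqrt(ev$values[1]); minor <- 4 * sqrt(ev$values[2])
  dir_deg <- (atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi) %% 180
  list(area_px = n,
       area_m2 = n * pixel_size^2,
       perimeter_m = perim * pixel_size,
       spectral_mean = mean(vals),
       spectral_min = min(vals),
       spectral_max = max(vals),
       spectral_std = sqrt(mean((vals - mean(vals))^2)),
       tx_mean = mean(tx_list$mean), tx_variance = mean(tx_list$variance),
       tx_entropy = mean(tx_list$entropy), tx_range = mean(tx_list$range),
       major_length_m = major * pixel_size,
       minor_length_m = minor * pixel_size,
       elongation = major / minor,
       main_direction_deg = dir_deg,
       centroid_x = origin[1] + mean(x) * pixel_size,
       centroid_y = origin[2] + mean(y) * pixel_size)
}

# all-pairs detection matching from scratch
oracle_match <- function(objects, gt, buffer_m) {
  n_pts <- nrow(gt$points)
  covered <- rep(FALSE, n_pts)
  used <- rep(FALSE, length(objects))
  for (i in seq_len(n_pts)) {
    for (j in seq_along(objects)) {
      o <- objects[[j]]
      ps <- o$pixel_size
      dmin <- Inf
      for (q in seq_len(nrow(o$pixels))) {
        cx <- o$origin[1] + (o$pixels[q, 2] - 0.5) * ps
        cy <- o$origin[2] - (o$pixels[q, 1] - 0.5) * ps
        dx <- max(abs(gt$points[i, 1] - cx) - ps / 2, 0)
        dy <- max(abs(gt$points[i, 2] - cy) - ps / 2, 0)
        dmin <- min(dmin, sqrt(dx^2 + dy^2))
      }
      if (dmin <= buffer_m) { covered[i] <- TRUE; used[j] <- TRUE }
    }
  }
  list(tp = sum(covered), fn = sum(!covered), fp = sum(!used))
}

# grouping partition via pairwise distances and graph components
oracle_group_partition <- function(footprints, gap_px) {
  n <- length(footprints)
  if (n == 0) return(integer(0))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dmin <- Inf
    for (a in seq_len(nrow(footprints[[i]]))) {
      for (b in seq_len(nrow(footprints[[j]]))) {
        dr <- max(abs(footprints[[i]][a, 1] - footprints[[j]][b, 1]) - 1, 0)
        dc <- max(abs(footprints[[i]][a, 2] - footprints[[j]][b, 2]) - 1, 0)
        dmin <- min(dmin, sqrt(dr^2 + dc^2))
      }
    }
    adj[i, j] <- dmin <= gap_px
  }
  igraph::components(igraph::graph_from_adjacency_matrix(adj, "undirected"))$membership
}

# even-odd point-in-polygon test, independently coded (angle-free crossing)
oracle_point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  crossings <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# a valid segment map on a small random scene, for attribute tests
random_segmented_scene <- function(seed, n_whales = 4L, size = 64L) {
  sc <- generate_scene(scene_spec(width_px = size, height_px = size,
                                  n_whales = n_whales, seed = seed))
  hp <- high_pass_filter(sc$tile)
  seg <- watershed_segment(gradient_map(hp), 90, intensity = hp)
  seg <- fast_lambda_merge(seg, hp, 40)
  list(scene = sc, hp = hp, seg = seg)
}

# random detection objects: scattered small pixel clusters
random_objects <- function(seed, n_obj, h = 40, w = 40, pixel_size = 0.31) {
  set.seed(seed)
  origin <- c(0, h * pixel_size)
  lapply(seq_len(n_obj), function(k) {
    r0 <- sample(3:(h - 3), 1); c0 <- sample(3:(w - 3), 1)
    px <- unique(rbind(c(r0, c0),
                       cbind(r0 + sample(-1:1, 3, TRUE),
                             c0 + sample(-1:1, 3, TRUE))))
    detection_object(k, k, px, origin = origin, pixel_size = pixel_size)
  })
}

expect_valid_segment_map <- function(seg, tile) {
  lab <- seg$labels
  expect_true(all(lab[!tile$nodata_mask] >= 1L))
  expect_true(all(lab[tile$nodata_mask] == 0L))
  ids <- sort(unique(lab[lab > 0]))
  expect_identical(ids, seq_len(seg$n_segments))
  # 4-connectivity of every label
  for (s in ids) {
    comp <- belugadetect:::cpp_label4(lab == s)
    expect_equal(max(comp), 1L)
  }
}
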
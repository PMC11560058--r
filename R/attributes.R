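#' Kernel texture rasters
#'
#' Per-pixel moving-window statistics over the k x k neighbourhood (the
#' "kernel") of the input image, clipped at the image border: mean,
#' population variance, entropy and range (max - min). Entropy uses the
#' convention `sum_b p_b log2 p_b` over an `nbins`-bin histogram of the
#' window values scaled to the tile's global min-max, so it is always <= 0
#' (0 for a constant window). Windows intersecting nodata renormalize over
#' the valid pixels; nodata centers stay nodata.
#'
#' @param tile a [raster_tile()] (normally the high-pass image).
#' @param kernel_size odd window width >= 3.
#' @param nbins number of histogram bins for entropy (default 64).
#' @return named list of four `raster_tile`s: `mean`, `variance`,
#'   `entropy`, `range`.
#' @export
texture_rasters <- function(tile, kernel_size = 3L, nbins = 64L) {
  stopifnot(inherits(tile, "raster_tile"))
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 3L || kernel_size %% 2L == 0L)
    stop("kernel_size must be an odd integer >= 3")
  if (kernel_size > nrow(tile$pixels) || kernel_size > ncol(tile$pixels))
    stop("kernel larger than tile")
  v <- tile$pixels[!tile$nodata_mask]
  if (length(v) == 0) stop("all-nodata tile")
  gmin <- min(v); gmax <- max(v)
  px <- tile$pixels
  px[is.na(px)] <- 0
  res <- cpp_texture(px, tile$nodata_mask, kernel_size, as.integer(nbins),
                     gmin, gmax)
  lapply(res, function(m) tile_like(tile, m, tile$nodata_mask))
}

# spatial attributes of one segment from its (row, col) pixel list
spatial_attrs <- function(rs, cs, pixel_size, origin) {
  n <- length(rs)
  ps <- pixel_size
  r0 <- min(rs); c0 <- min(cs)
  h2 <- max(rs) - r0 + 1L; w2 <- max(cs) - c0 + 1L
  m <- matrix(FALSE, h2, w2)
  m[cbind(rs - r0 + 1L, cs - c0 + 1L)] <- TRUE
  # perimeter: count of exposed pixel edges
  pad <- matrix(FALSE, h2 + 2L, w2 + 2L)
  pad[2:(h2 + 1L), 2:(w2 + 1L)] <- m
  core <- pad[2:(h2 + 1L), 2:(w2 + 1L)]
  exposed <- (core & !pad[1:h2, 2:(w2 + 1L)]) +
             (core & !pad[3:(h2 + 2L), 2:(w2 + 1L)]) +
             (core & !pad[2:(h2 + 1L), 1:w2]) +
             (core & !pad[2:(h2 + 1L), 3:(w2 + 2L)])
  perim_px <- sum(exposed)
  # holes: 4-connected components of the complement (padded so the outside
  # is a single component touching the border)
  comp <- cpp_label4(!pad)
  border_ids <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1],
                         comp[, ncol(comp)]))
  hole_ids <- setdiff(unique(comp[comp > 0]), border_ids)
  n_holes <- length(hole_ids)
  hole_px <- if (n_holes) sum(comp %in% hole_ids) else 0L
  # second-moment ellipse in pixel units (y up so directions are world-like)
  x <- cs - 0.5
  y <- -(rs - 0.5)
  mx <- mean(x); my <- mean(y)
  mu20 <- mean((x - mx)^2) + 1 / 12
  mu02 <- mean((y - my)^2) + 1 / 12
  mu11 <- mean((x - mx) * (y - my))
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  major_px <- 4 * sqrt(max(l1, 0))
  minor_px <- 4 * sqrt(max(l2, 0))
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  # convex hull over the 4 corner points of every pixel
  corners <- unique(rbind(cbind(x - 0.5, y - 0.5), cbind(x + 0.5, y - 0.5),
                          cbind(x - 0.5, y + 0.5), cbind(x + 0.5, y + 0.5)))
  hull <- corners[chull(corners), , drop = FALSE]
  hull_area <- abs(ring_area(hull))
  dxy <- hull[c(seq_len(nrow(hull))[-1], 1), , drop = FALSE] - hull
  hull_perim <- sum(sqrt(rowSums(dxy^2)))
  c(area_px = n,
    area_m2 = n * ps^2,
    perimeter_m = perim_px * ps,
    major_length_m = major_px * ps,
    minor_length_m = minor_px * ps,
    elongation = major_px / minor_px,
    compactness = sqrt(4 * n / pi) / perim_px,
    form_factor = 4 * pi * n / perim_px^2,
    solidity = n / hull_area,
    convexity = hull_perim / perim_px,
    roundness = 4 * n / (pi * major_px^2),
    rect_fit = n / (major_px * minor_px),
    main_direction_deg = (theta * 180 / pi) %% 180,
    n_holes = n_holes,
    hole_solid_ratio = n / (n + hole_px),
    centroid_x = origin[1] + mx * ps,
    centroid_y = origin[2] + my * ps)
}

#' Per-segment attribute table
#'
#' Computes, for every segment, the four spectral attributes (mean, min,
#' max, standard deviation of the segment's pixels on the supplied image),
#' the four texture attributes (segment means of the kernel texture
#' rasters), and the spatial attributes of the pixel region (area,
#' perimeter, moment-ellipse axes, elongation, compactness, solidity,
#' roundness, form factor, rectangular fit, convexity, main direction,
#' holes, centroid). In the standard pipeline the image is the high-pass
#' filtered tile, so spectral values can be negative. The spectral standard
#' deviation is the population value (0 for single-pixel segments).
#'
#' @param segmap a [segment_map()].
#' @param tile the congruent `raster_tile` (high-pass image).
#' @param textures optional result of [texture_rasters()]; computed with
#'   `kernel_size` when omitted.
#' @param kernel_size kernel width used when `textures` is NULL.
#' @return data.frame of class `segment_records`, one row per segment id.
#' @export
compute_attributes <- function(segmap, tile, textures = NULL,
                               kernel_size = 3L) {
  stopifnot(inherits(segmap, "segment_map"), inherits(tile, "raster_tile"))
  if (!identical(dim(segmap$labels), dim(tile$pixels)))
    stop("segment map and tile are not congruent")
  if (is.null(textures)) textures <- texture_rasters(tile, kernel_size)
  lab <- segmap$labels
  keep <- lab > 0L
  ids <- lab[keep]
  vals <- tile$pixels[keep]
  f <- factor(ids, levels = seq_len(segmap$n_segments))
  seg_n <- as.integer(table(f))
  s1 <- tapply(vals, f, sum)
  s2 <- tapply(vals^2, f, sum)
  mu <- as.numeric(s1) / seg_n
  spectral_std <- sqrt(pmax(as.numeric(s2) / seg_n - mu^2, 0))
  tx <- lapply(textures, function(t) {
    as.numeric(tapply(t$pixels[keep], f, sum)) / seg_n
  })
  rows <- row(lab)[keep]
  cols <- col(lab)[keep]
  idx_by_seg <- split(seq_along(ids), f)
  sp <- t(vapply(seq_len(segmap$n_segments), function(s) {
    ii <- idx_by_seg[[s]]
    spatial_attrs(rows[ii], cols[ii], tile$pixel_size, tile$origin)
  }, numeric(17)))
  out <- data.frame(
    segment_id = seq_len(segmap$n_segments),
    spectral_mean = mu,
    spectral_min = as.numeric(tapply(vals, f, min)),
    spectral_max = as.numeric(tapply(vals, f, max)),
    spectral_std = spectral_std,
    tx_mean = tx$mean, tx_variance = tx$variance,
    tx_entropy = tx$entropy, tx_range = tx$range,
    sp)
  class(out) <- c("segment_records", "data.frame")
  out
}

#' Write a segment attribute table to CSV
#'
#' @param records a `segment_records` data.frame from [compute_attributes()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_attributes <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
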
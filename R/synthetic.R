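#' Synthetic ocean scene specification
#'
#' Describes a synthetic panchromatic scene emulating the imaging
#' conditions of the study: a dark, mildly textured open-water background
#' (base level plus low-frequency swell plus Gaussian sensor/sea noise)
#' with bright, roughly oval whale-sized targets 1-4.5 m long, optionally
#' submerged (reduced contrast), grouped (touching pairs, including
#' perpendicular pairs) or near bright textured land.
#'
#' Default radiometry: surface whales sit `surface_contrast = 40` intensity
#' units above the water at `noise_sigma = 2.5`, i.e. 16 sigma - belugas
#' are stark white against calm dark water in panchromatic imagery, and the
#' study scene had a low Beaufort state. Swell amplitude 5 gives the
#' high-pass filter a nontrivial low-frequency component to remove.
#'
#' @param width_px,height_px scene size in pixels.
#' @param pixel_size meters per pixel (default 0.31).
#' @param n_whales number of whales.
#' @param whale_length_m length range in meters (default c(1, 4.5)).
#' @param aspect_ratio length/width range (default c(2.5, 4)).
#' @param surface_contrast mean brightness of a surfaced whale above the
#'   water background, raw intensity units.
#' @param submerged_fraction fraction of whales rendered submerged.
#' @param submerged_contrast_factor contrast multiplier in (0, 1) for
#'   submerged whales.
#' @param group_fraction fraction of whales placed in touching pairs (half
#'   of the pairs perpendicular).
#' @param noise_sigma Gaussian noise standard deviation (>= 0).
#' @param swell_amplitude total amplitude of the low-frequency background
#'   sinusoids (>= 0).
#' @param base_level water background intensity.
#' @param land_polygons optional [mask_set()] rendered as bright textured
#'   land.
#' @param seed integer RNG seed; scenes are fully reproducible from it.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width_px = 280L, height_px = 280L, pixel_size = 0.31,
                       n_whales = 25L, whale_length_m = c(1.0, 4.5),
                       aspect_ratio = c(2.5, 4.0), surface_contrast = 40,
                       submerged_fraction = 0,
                       submerged_contrast_factor = 0.25,
                       group_fraction = 0, noise_sigma = 2.5,
                       swell_amplitude = 5, base_level = 100,
                       land_polygons = NULL, seed = 1L) {
  stopifnot(width_px >= 8, height_px >= 8, pixel_size > 0, n_whales >= 0,
            length(whale_length_m) == 2, whale_length_m[1] <= whale_length_m[2],
            whale_length_m[1] / pixel_size >= 3,
            length(aspect_ratio) == 2, aspect_ratio[1] >= 1,
            submerged_fraction >= 0, submerged_fraction <= 1,
            submerged_contrast_factor > 0, submerged_contrast_factor < 1,
            group_fraction >= 0, group_fraction <= 1,
            noise_sigma >= 0, swell_amplitude >= 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size = pixel_size, n_whales = as.integer(n_whales),
                 whale_length_m = whale_length_m, aspect_ratio = aspect_ratio,
                 surface_contrast = surface_contrast,
                 submerged_fraction = submerged_fraction,
                 submerged_contrast_factor = submerged_contrast_factor,
                 group_fraction = group_fraction, noise_sigma = noise_sigma,
                 swell_amplitude = swell_amplitude, base_level = base_level,
                 land_polygons = land_polygons, seed = as.integer(seed)),
            class = "scene_spec")
}

# anti-aliased coverage rendering of one elliptical whale; modifies px
render_ellipse <- function(px, cr, cc, len_px, wid_px, theta_deg, amount,
                           supersample = 4L) {
  h <- nrow(px); w <- ncol(px)
  a <- len_px / 2; b <- wid_px / 2
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  half <- ceiling(a) + 1L
  rows <- max(1L, floor(cr - half)):min(h, ceiling(cr + half))
  cols <- max(1L, floor(cc - half)):min(w, ceiling(cc + half))
  ss <- (seq_len(supersample) - 0.5) / supersample
  for (r in rows) {
    for (cl in cols) {
      # subpixel sample points of pixel (r, cl); pixel spans (r-1, r)
      dy <- (r - 1) + rep(ss, each = supersample) - cr
      dx <- (cl - 1) + rep(ss, supersample) - cc
      u <- (dx * ct + dy * st) / a
      v <- (-dx * st + dy * ct) / b
      cov <- mean(u^2 + v^2 <= 1)
      if (cov > 0) px[r, cl] <- px[r, cl] + amount * cov
    }
  }
  px
}

#' Generate a synthetic scene with known ground truth
#'
#' Renders the scene described by a [scene_spec()]: background (base level
#' + 3 low-frequency swell sinusoids + Gaussian noise), anti-aliased
#' elliptical whales at random positions and orientations (placed without
#' overlap except within designated groups: grouped whales touch, and
#' perpendicular pairs cross at about 90 degrees), and optionally bright
#' textured land. Ground truth has one point per whale centroid, confidence
#' 2 for surfaced whales and 1 for submerged ones. Bit-identical output for
#' identical specs.
#'
#' @param spec a [scene_spec()].
#' @return list with elements `tile` ([raster_tile()]), `truth`
#'   ([ground_truth_set()]) and `masks` ([mask_set()] or NULL).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  h <- spec$height_px; w <- spec$width_px; ps <- spec$pixel_size
  px <- matrix(spec$base_level, h, w)
  if (spec$swell_amplitude > 0) {
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (q in 1:3) {
      wavelength <- runif(1, 30, 80)
      th <- runif(1, 0, pi)
      phase <- runif(1, 0, 2 * pi)
      px <- px + (spec$swell_amplitude / 3) *
        sin(2 * pi * (cos(th) * cols + sin(th) * rows) / wavelength + phase)
    }
  }
  if (spec$noise_sigma > 0)
    px <- px + matrix(rnorm(h * w, sd = spec$noise_sigma), h, w)
  # whale placement
  n <- spec$n_whales
  centers <- matrix(numeric(0), 0, 2)  # (row, col) in pixel units
  lens <- wids <- dirs <- numeric(0)
  pairmate <- integer(0)  # index of group mate or 0
  n_grouped <- round(spec$group_fraction * n)
  n_pairs <- n_grouped %/% 2
  placed <- 0L
  min_gap_px <- 4  # open water required between distinct whales/groups
  tries <- 0L
  max_tries <- 400L * max(n, 1L)
  while (placed < n) {
    if (tries > max_tries)
      stop("infeasible whale placement: scene too small for ", n, " whales")
    tries <- tries + 1L
    len <- runif(1, spec$whale_length_m[1], spec$whale_length_m[2]) / ps
    asp <- runif(1, spec$aspect_ratio[1], spec$aspect_ratio[2])
    wid <- len / asp
    th <- runif(1, 0, 180)
    margin <- len / 2 + min_gap_px + 1
    cr <- runif(1, margin, h - margin)
    cc <- runif(1, margin, w - margin)
    # conservative separation: sum of half-lengths plus required gap
    if (nrow(centers)) {
      d <- sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2)
      if (any(d < (lens / 2 + len / 2 + min_gap_px))) next
    }
    is_pair_lead <- placed < 2L * n_pairs && placed %% 2L == 0L
    centers <- rbind(centers, c(cr, cc))
    lens <- c(lens, len); wids <- c(wids, wid); dirs <- c(dirs, th)
    pairmate <- c(pairmate, 0L)
    placed <- placed + 1L
    if (is_pair_lead && placed < n) {
      # place the group mate immediately: touching, parallel or crossing
      len2 <- runif(1, spec$whale_length_m[1], spec$whale_length_m[2]) / ps
      wid2 <- len2 / runif(1, spec$aspect_ratio[1], spec$aspect_ratio[2])
      perpendicular <- runif(1) < 0.5
      if (perpendicular) {
        th2 <- (th + 90) %% 180
        off <- len / 4  # cross near the first whale's flank
        cr2 <- cr + off * sin(th * pi / 180)
        cc2 <- cc + off * cos(th * pi / 180)
      } else {
        th2 <- th
        off <- (wid + wid2) / 2 + 0.5  # flank to flank, within 1 px
        cr2 <- cr + off * cos(th * pi / 180)
        cc2 <- cc - off * sin(th * pi / 180)
      }
      m2 <- len2 / 2 + 2
      cr2 <- min(max(cr2, m2), h - m2)
      cc2 <- min(max(cc2, m2), w - m2)
      centers <- rbind(centers, c(cr2, cc2))
      lens <- c(lens, len2); wids <- c(wids, wid2); dirs <- c(dirs, th2)
      pairmate[placed] <- placed + 1L
      pairmate <- c(pairmate, placed)
      placed <- placed + 1L
    }
  }
  submerged <- rep(FALSE, n)
  if (n > 0 && spec$submerged_fraction > 0) {
    n_sub <- round(spec$submerged_fraction * n)
    submerged[sample.int(n, n_sub)] <- TRUE
  }
  for (i in seq_len(n)) {
    amount <- spec$surface_contrast *
      if (submerged[i]) spec$submerged_contrast_factor else 1
    px <- render_ellipse(px, centers[i, 1], centers[i, 2], lens[i], wids[i],
                         dirs[i], amount)
  }
  origin <- c(0, h * ps)  # world y decreases with row; top-left corner at y = h*ps
  tile <- raster_tile(px, pixel_size = ps, origin = origin, crs_id = "none",
                      tile_id = sprintf("synthetic_seed%d", spec$seed))
  # land rendered after georeferencing is fixed: bright, strongly textured
  if (!is.null(spec$land_polygons)) {
    land <- apply_land_mask(tile, spec$land_polygons)$nodata_mask
    n_land <- sum(land)
    if (n_land > 0) {
      px[land] <- spec$base_level + 60 + rnorm(n_land, sd = 12)
      tile <- raster_tile(px, pixel_size = ps, origin = origin,
                          crs_id = "none", tile_id = tile$tile_id)
    }
  }
  truth <- if (n > 0) {
    # centers are continuous pixel coordinates (pixel k spans k-1..k)
    ground_truth_set(cbind(origin[1] + centers[, 2] * ps,
                           origin[2] - centers[, 1] * ps),
                     confidence = ifelse(submerged, 1L, 2L),
                     source_label = "synthetic")
  } else ground_truth_set(source_label = "synthetic")
  list(tile = tile, truth = truth, masks = spec$land_polygons)
}

#' Named scenario presets
#'
#' The study's characteristic situations as ready-made scene specs:
#' `clean` (surfaced, well-separated whales), `grouped` (whale pairs
#' touching or crossing at 90 degrees), `submerged` (half the whales at a
#' quarter contrast), `no_whale` (open water only, mirroring the tile that
#' contained no visible whales), and `near_land` (a bright textured
#' landmass to be masked out).
#'
#' @param seed seed stored in every returned spec.
#' @return named list of [scene_spec()].
#' @export
scenario_suite <- function(seed = 1L) {
  land <- mask_set(list(cbind(c(0, 26, 26, 0), c(0, 0, 86.8, 86.8))))
  list(
    clean = scene_spec(seed = seed),
    grouped = scene_spec(group_fraction = 0.4, seed = seed),
    submerged = scene_spec(submerged_fraction = 0.5,
                           submerged_contrast_factor = 0.25, seed = seed),
    no_whale = scene_spec(n_whales = 0L, seed = seed),
    near_land = scene_spec(n_whales = 15L, land_polygons = land, seed = seed))
}
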
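#' Ground-truth whale point set
#'
#' Observer-verified whale locations. Each point carries a confidence
#' rating: 2 for an obvious whale (right shape and size), 1 for a probable
#' whale (approximate shape and size).
#'
#' @param points two-column matrix of world (x, y) coordinates (may have 0
#'   rows).
#' @param confidence integer vector in \{1, 2\}, one per point. Default all 2.
#' @param source_label observer / provenance label.
#' @return object of class `ground_truth_set`.
#' @export
ground_truth_set <- function(points = matrix(numeric(0), 0, 2),
                             confidence = rep(2L, nrow(points)),
                             source_label = "observer") {
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  confidence <- as.integer(confidence)
  if (length(confidence) != nrow(points))
    stop("confidence must have one value per point")
  if (length(confidence) && !all(confidence %in% c(1L, 2L)))
    stop("confidence values must be 1 (probable) or 2 (obvious)")
  structure(list(points = points, confidence = confidence,
                 source_label = as.character(source_label)),
            class = "ground_truth_set")
}

#' @export
print.ground_truth_set <- function(x, ...) {
  cat(sprintf("<ground_truth_set '%s'> %d points (%d obvious, %d probable)\n",
              x$source_label, nrow(x$points), sum(x$confidence == 2L),
              sum(x$confidence == 1L)))
  invisible(x)
}

#' Land-mask polygon set
#'
#' @param polygons list of closed rings, each an n x 2 matrix of world
#'   (x, y) vertices (n >= 3, nonzero area). Rings need not repeat the first
#'   vertex.
#' @param semantic what the polygons mask (only `"land"` is used).
#' @return object of class `mask_set`.
#' @export
mask_set <- function(polygons = list(), semantic = "land") {
  polygons <- lapply(polygons, function(p) {
    p <- matrix(as.numeric(p), ncol = 2)
    # drop an explicitly closed duplicate last vertex
    if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (nrow(p) < 3) stop("mask polygon rings need at least 3 vertices")
    if (abs(ring_area(p)) <= 0) stop("mask polygon ring has zero area")
    p
  })
  structure(list(polygons = polygons, semantic = semantic), class = "mask_set")
}

# shoelace signed area of an open ring
ring_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

read_geojson <- function(path) {
  if (!file.exists(path)) stop("vector file not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Read ground-truth points from GeoJSON
#'
#' Accepts a FeatureCollection of Point features with an optional
#' `confidence` property (defaults to 2). Non-point geometries are rejected.
#'
#' @param path GeoJSON file path.
#' @return a [ground_truth_set()].
#' @export
read_points <- function(path) {
  gj <- read_geojson(path)
  feats <- gj$features %||% list()
  pts <- matrix(numeric(0), 0, 2)
  conf <- integer(0)
  for (f in feats) {
    g <- f$geometry
    if (is.null(g) || !identical(g$type, "Point"))
      stop("points layer contains non-point geometry: ",
           g$type %||% "missing")
    pts <- rbind(pts, c(g$coordinates[[1]], g$coordinates[[2]]))
    conf <- c(conf, as.integer(f$properties$confidence %||% 2L))
  }
  ground_truth_set(pts, conf,
                   source_label = gj$name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write ground-truth points to GeoJSON
#'
#' @param gt a [ground_truth_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_points <- function(gt, path) {
  feats <- lapply(seq_len(nrow(gt$points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = as.numeric(gt$points[i, ])),
         properties = list(confidence = gt$confidence[i]))
  })
  gj <- list(type = "FeatureCollection", name = gt$source_label,
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read land-mask polygons from GeoJSON
#'
#' Exterior rings of Polygon and MultiPolygon features are read; interior
#' rings (holes) are ignored, which is conservative for a land mask.
#'
#' @param path GeoJSON file path.
#' @return a [mask_set()].
#' @export
read_mask_polygons <- function(path) {
  gj <- read_geojson(path)
  polys <- list()
  for (f in gj$features %||% list()) {
    g <- f$geometry
    if (is.null(g) || !g$type %in% c("Polygon", "MultiPolygon"))
      stop("mask layer contains non-polygon geometry: ", g$type %||% "missing")
    ringsets <- if (g$type == "Polygon") list(g$coordinates) else g$coordinates
    for (rs in ringsets) {
      ext <- rs[[1]]
      m <- do.call(rbind, lapply(ext, function(v) c(v[[1]], v[[2]])))
      polys <- c(polys, list(m))
    }
  }
  mask_set(polys)
}

#' Write land-mask polygons to GeoJSON
#'
#' @param masks a [mask_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_polygons <- function(masks, path) {
  feats <- lapply(masks$polygons, function(p) {
    ring <- rbind(p, p[1, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ])))),
         properties = list(semantic = masks$semantic))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Detection object: one putative whale
#'
#' One or more classified segments grouped into a single detection, carrying
#' the union pixel footprint. Handles the body-and-fluke case where the
#' segmentation splits one whale into multiple segments.
#'
#' @param object_id integer id.
#' @param member_segments integer ids of the member segments.
#' @param pixels n x 2 matrix of (row, col) pixel indices (1-based) of the
#'   union footprint.
#' @param origin,pixel_size,crs_id georeferencing of the parent raster.
#' @return object of class `detection_object` with centroid and area fields.
#' @export
detection_object <- function(object_id, member_segments, pixels,
                             origin = c(0, 0), pixel_size = 0.31,
                             crs_id = "none") {
  stopifnot(nrow(pixels) >= 1)
  xy <- cbind(origin[1] + (pixels[, 2] - 0.5) * pixel_size,
              origin[2] - (pixels[, 1] - 0.5) * pixel_size)
  structure(list(object_id = as.integer(object_id),
                 member_segments = as.integer(member_segments),
                 pixels = pixels,
                 origin = as.numeric(origin),
                 pixel_size = as.numeric(pixel_size),
                 crs_id = as.character(crs_id),
                 area_m2 = nrow(pixels) * pixel_size^2,
                 centroid_xy = colMeans(xy)),
            class = "detection_object")
}

# Trace the boundary of a pixel set into closed rings (grid coordinates:
# x = column, y = row, both 0-based corners). Exterior rings come out
# counter-clockwise in world coordinates (y up), holes clockwise. At
# checkerboard corners the walk takes the turn toward the interior, which
# keeps rings simple.
trace_rings <- function(pixels) {
  px_key <- paste(pixels[, 1], pixels[, 2])
  in_set <- new.env(hash = TRUE, size = max(16L, nrow(pixels)))
  for (k in px_key) assign(k, TRUE, envir = in_set)
  has_px <- function(r, c) !is.null(in_set[[paste(r, c)]])
  from <- matrix(numeric(0), 0, 2); to <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(pixels))) {
    r <- pixels[i, 1]; cc <- pixels[i, 2]
    # corners in grid coords
    tl <- c(cc - 1, r - 1); tr <- c(cc, r - 1)
    br <- c(cc, r); bl <- c(cc - 1, r)
    if (!has_px(r - 1, cc)) { from <- rbind(from, tr); to <- rbind(to, tl) }
    if (!has_px(r, cc + 1)) { from <- rbind(from, br); to <- rbind(to, tr) }
    if (!has_px(r + 1, cc)) { from <- rbind(from, bl); to <- rbind(to, br) }
    if (!has_px(r, cc - 1)) { from <- rbind(from, tl); to <- rbind(to, bl) }
  }
  n <- nrow(from)
  used <- rep(FALSE, n)
  start_key <- paste(from[, 1], from[, 2])
  by_start <- split(seq_len(n), start_key)
  rings <- list()
  for (e0 in seq_len(n)) {
    if (used[e0]) next
    ring <- list(from[e0, ])
    cur <- e0
    repeat {
      used[cur] <- TRUE
      v <- to[cur, ]
      ring[[length(ring) + 1L]] <- v
      if (all(v == from[e0, ])) break
      cand <- by_start[[paste(v[1], v[2])]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) stop("boundary tracing failed (open chain)")
      if (length(cand) > 1) {
        # checkerboard vertex: prefer the turn that hugs the pixel we came
        # along, keeping rings simple
        d <- v - from[cur, ]
        pref <- rbind(c(d[2], -d[1]), d, c(-d[2], d[1]))
        pick <- NA_integer_
        for (p in seq_len(nrow(pref))) {
          m <- cand[to[cand, 1] == v[1] + pref[p, 1] &
                    to[cand, 2] == v[2] + pref[p, 2]]
          if (length(m)) { pick <- m[1]; break }
        }
        cur <- if (is.na(pick)) cand[1] else pick
      } else cur <- cand
    }
    rings[[length(rings) + 1L]] <- do.call(rbind, ring)
  }
  rings
}

# rings of a detection object in world coordinates, grouped as
# list(list(exterior, holes...)) suitable for GeoJSON MultiPolygon
footprint_polygons <- function(obj) {
  rings <- trace_rings(obj$pixels)
  world <- lapply(rings, function(rg) {
    cbind(obj$origin[1] + rg[, 1] * obj$pixel_size,
          obj$origin[2] - rg[, 2] * obj$pixel_size)
  })
  areas <- vapply(world, function(rg) ring_area(rg[-nrow(rg), , drop = FALSE]), 0)
  ext_idx <- which(areas > 0)
  hole_idx <- which(areas < 0)
  polys <- lapply(ext_idx, function(i) list(world[[i]]))
  if (length(hole_idx) && length(ext_idx)) {
    for (hi in hole_idx) {
      pt <- world[[hi]][1, ]
      owner <- 1L
      for (q in seq_along(ext_idx)) {
        er <- world[[ext_idx[q]]]
        if (point_in_ring(pt[1], pt[2], er)) { owner <- q; break }
      }
      polys[[owner]] <- c(polys[[owner]], list(world[[hi]]))
    }
  }
  polys
}

# even-odd ray crossing; vertices on the boundary count as inside
point_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((y[i] > py) != (y[j] > py) &&
        px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
      inside <- !inside
    j <- i
  }
  inside
}

#' Write detection objects to GeoJSON (and optionally CSV)
#'
#' Each detection is written as a MultiPolygon feature whose geometry is the
#' union outline of its member segments, with object id, member segment ids,
#' area, centroid and the rule-set id as properties.
#'
#' @param objects list of [detection_object()].
#' @param path output GeoJSON path.
#' @param ruleset_id rule-set identifier recorded on every feature.
#' @param csv_path optional path for a flat CSV (object id, x, y, area_m2,
#'   matched flag).
#' @param matched optional logical vector, one per object (for the CSV).
#' @return `path`, invisibly.
#' @export
write_detections <- function(objects, path, ruleset_id = NA_character_,
                             csv_path = NULL, matched = NULL) {
  feats <- lapply(objects, function(o) {
    polys <- footprint_polygons(o)
    coords <- lapply(polys, function(pl) lapply(pl, function(rg) {
      lapply(seq_len(nrow(rg)), function(i) as.numeric(rg[i, ]))
    }))
    list(type = "Feature",
         geometry = list(type = "MultiPolygon", coordinates = coords),
         properties = list(object_id = o$object_id,
                           member_segments = as.list(o$member_segments),
                           area_m2 = o$area_m2,
                           centroid_x = o$centroid_xy[1],
                           centroid_y = o$centroid_xy[2],
                           ruleset_id = ruleset_id))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  if (!is.null(csv_path)) {
    df <- detections_table(objects, matched)
    write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(path)
}

detections_table <- function(objects, matched = NULL) {
  data.frame(
    object_id = vapply(objects, function(o) o$object_id, 0L),
    x = vapply(objects, function(o) o$centroid_xy[1], 0),
    y = vapply(objects, function(o) o$centroid_xy[2], 0),
    area_m2 = vapply(objects, function(o) o$area_m2, 0),
    matched = if (is.null(matched)) rep(NA, length(objects)) else matched)
}

#' Read detection objects back from GeoJSON
#'
#' Reconstructs detection objects written by [write_detections()]. The pixel
#' footprint is recovered by rasterising the polygons onto the grid implied
#' by `pixel_size` and `origin` stored per feature centroid; since the
#' package writes pixel-aligned outlines this is exact.
#'
#' @param path GeoJSON path written by [write_detections()].
#' @return data.frame with object_id, centroid_x, centroid_y, area_m2.
#' @export
read_detections <- function(path) {
  gj <- read_geojson(path)
  feats <- gj$features %||% list()
  data.frame(
    object_id = vapply(feats, function(f) as.integer(f$properties$object_id), 0L),
    centroid_x = vapply(feats, function(f) as.numeric(f$properties$centroid_x), 0),
    centroid_y = vapply(feats, function(f) as.numeric(f$properties$centroid_y), 0),
    area_m2 = vapply(feats, function(f) as.numeric(f$properties$area_m2), 0))
}
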
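#' Threshold rule on one segment attribute
#'
#' A rule passes when the attribute lies between `lower` and `upper`.
#' Printed rules like "Spectral mean (>35)" are strict (open) bounds;
#' printed closed ranges like "-0.80 to -0.44" are inclusive, which the
#' `lower_closed`/`upper_closed` flags express.
#'
#' @param attribute column name from the segment attribute table.
#' @param lower,upper bounds (default unbounded).
#' @param lower_closed,upper_closed whether each finite bound is inclusive.
#' @return object of class `rule`.
#' @export
rule <- function(attribute, lower = -Inf, upper = Inf,
                 lower_closed = FALSE, upper_closed = FALSE) {
  if (lower > upper) stop("rule bounds must satisfy lower <= upper")
  structure(list(attribute = as.character(attribute),
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 lower_closed = isTRUE(lower_closed),
                 upper_closed = isTRUE(upper_closed)),
            class = "rule")
}

#' Rule set: a candidate detection algorithm
#'
#' A conjunction of attribute rules together with the segmentation
#' configuration they were designed for.
#'
#' @param id text identifier (e.g. `"CA#10"`).
#' @param rules non-empty list of [rule()]s (combined with AND).
#' @param config a [pipeline_config()].
#' @return object of class `rule_set`.
#' @export
rule_set <- function(id, rules, config) {
  if (length(rules) < 1) stop("a rule set needs at least one rule")
  stopifnot(all(vapply(rules, inherits, TRUE, "rule")),
            inherits(config, "pipeline_config"))
  structure(list(id = as.character(id), rules = rules, config = config),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set %s> scale %g, merge %g, kernel %d\n", x$id,
              x$config$scale_level, x$config$merge_level,
              x$config$kernel_size))
  for (r in x$rules) {
    cat(sprintf("  %s in %s%g, %g%s\n", r$attribute,
                if (r$lower_closed) "[" else "(", r$lower, r$upper,
                if (r$upper_closed) "]" else ")"))
  }
  invisible(x)
}

# the eleven published candidate algorithms (EDGE segmentation, FAST LAMBDA
# merging, kernel size 3 throughout)
CA_PRESETS <- list(
  "CA#1"  = list(80, 40, list(c("spectral_mean", 40))),
  "CA#2"  = list(80, 70, list(c("spectral_mean", 40))),
  "CA#3"  = list(80, 20, list(c("spectral_mean", 40))),
  "CA#4"  = list(30, 10, list(c("spectral_mean", 60),
                              c("tx_entropy", -0.80, -0.44))),
  "CA#5"  = list(90, 40, list(c("spectral_mean", 50),
                              c("tx_entropy", -0.80, -0.44))),
  "CA#6"  = list(90, 40, list(c("spectral_mean", 45),
                              c("tx_entropy", -0.76, -0.40))),
  "CA#7"  = list(90, 40, list(c("spectral_mean", 45),
                              c("tx_entropy", -0.80, -0.44))),
  "CA#8"  = list(90, 10, list(c("spectral_mean", 45),
                              c("tx_entropy", -0.76, -0.40))),
  "CA#9"  = list(90, 40, list(c("spectral_mean", 35),
                              c("tx_variance", 2000))),
  "CA#10" = list(90, 40, list(c("spectral_mean", 35),
                              c("tx_variance", 1500))),
  "CA#11" = list(90, 40, list(c("spectral_mean", 35),
                              c("tx_variance", 1740))))

#' The eleven published candidate algorithms
#'
#' Returns one of the eleven candidate OBIA algorithms exactly as
#' published: its scale level, merge level (kernel size 3, EDGE
#' segmentation, FAST LAMBDA merging for all eleven) and its attribute
#' rules. Spectral-mean and texture-variance rules are strict lower bounds;
#' texture-entropy rules are inclusive ranges.
#'
#' @param id one of `"CA#1"` .. `"CA#11"` (see [candidate_ids()]).
#' @return a [rule_set()].
#' @export
candidate_algorithm <- function(id) {
  p <- CA_PRESETS[[id]]
  if (is.null(p)) stop("unknown candidate algorithm id: ", id)
  rules <- lapply(p[[3]], function(spec) {
    if (length(spec) == 2) {
      rule(spec[1], lower = as.numeric(spec[2]))
    } else {
      rule(spec[1], lower = as.numeric(spec[2]), upper = as.numeric(spec[3]),
           lower_closed = TRUE, upper_closed = TRUE)
    }
  })
  rule_set(id, rules, pipeline_config(as.numeric(p[[1]]), as.numeric(p[[2]])))
}

#' @rdname candidate_algorithm
#' @export
candidate_ids <- function() names(CA_PRESETS)

#' Default rule set for synthetic scenes
#'
#' The published rule thresholds are calibrated to the radiometry of one
#' licensed WorldView-3 scene; synthetic scenes are rendered in arbitrary
#' intensity units, so the same rule *form* (spectral mean AND texture
#' variance, scale 90, merge 40 - the best-performing published
#' combination) is kept but the thresholds are recalibrated to the
#' synthetic radiometry (see the package vignette for the calibration).
#'
#' @param spectral_mean_min strict lower bound on the segment spectral mean
#'   in the high-pass image.
#' @param tx_variance_min strict lower bound on the segment mean kernel
#'   texture variance.
#' @return a [rule_set()] with id `"SYN-DEFAULT"`.
#' @export
default_ruleset <- function(spectral_mean_min = 25, tx_variance_min = 1500) {
  rule_set("SYN-DEFAULT",
           list(rule("spectral_mean", lower = spectral_mean_min),
                rule("tx_variance", lower = tx_variance_min)),
           pipeline_config(90, 40))
}

#' Classify segments with a rule set
#'
#' Returns the ids of segments satisfying every rule of the set
#' (conjunction), honouring the open/closed bound semantics of each rule.
#'
#' @param records segment attribute table from [compute_attributes()].
#' @param ruleset a [rule_set()].
#' @return integer vector of classified segment ids (possibly empty).
#' @export
classify_segments <- function(records, ruleset) {
  stopifnot(inherits(ruleset, "rule_set"))
  keep <- rep(TRUE, nrow(records))
  for (r in ruleset$rules) {
    if (!r$attribute %in% names(records))
      stop("rule references unknown attribute: ", r$attribute)
    v <- records[[r$attribute]]
    lo <- if (r$lower_closed) v >= r$lower else v > r$lower
    hi <- if (r$upper_closed) v <= r$upper else v < r$upper
    keep <- keep & lo & hi
  }
  as.integer(records$segment_id[keep])
}

# minimum distance in pixels between two pixel sets, measuring between
# pixel squares: adjacent or diagonally touching pixels are at distance 0
pixel_set_distance <- function(a, b) {
  dr <- abs(outer(a[, 1], b[, 1], "-")) - 1
  dc <- abs(outer(a[, 2], b[, 2], "-")) - 1
  dr[dr < 0] <- 0
  dc[dc < 0] <- 0
  sqrt(min(dr^2 + dc^2))
}

#' Group classified segments into detection objects
#'
#' Single-linkage clustering of classified segments: two segments belong to
#' the same detection object when the minimum distance between their pixel
#' footprints is at most `gap_px` pixels (squares sharing an edge or corner
#' are at distance 0). The default gap of 2 px lets a body-and-fluke split
#' of one whale merge into a single object while whales separated by
#' visible water stay distinct. The result does not depend on segment
#' enumeration order.
#'
#' @param footprints list of n x 2 (row, col) pixel index matrices, one per
#'   classified segment.
#' @param gap_px grouping distance in pixels (>= 0, default 2).
#' @param origin,pixel_size,crs_id georeferencing of the parent raster.
#' @param segment_ids optional integer ids of the segments (defaults to
#'   positional indices).
#' @return list of [detection_object()], ordered by smallest member id.
#' @export
group_segments <- function(footprints, gap_px = 2, origin = c(0, 0),
                           pixel_size = 0.31, crs_id = "none",
                           segment_ids = NULL) {
  if (gap_px < 0) stop("gap_px must be >= 0")
  n <- length(footprints)
  if (is.null(segment_ids)) segment_ids <- seq_len(n)
  if (n == 0) return(list())
  # union-find over segments whose footprint distance is <= gap_px
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  bbox <- t(vapply(footprints, function(p) {
    c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2]))
  }, numeric(4)))
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(i - 1)) {
      # bounding-box prefilter
      gr <- max(bbox[i, 1], bbox[j, 1]) - min(bbox[i, 2], bbox[j, 2]) - 1
      gc <- max(bbox[i, 3], bbox[j, 3]) - min(bbox[i, 4], bbox[j, 4]) - 1
      if (sqrt(max(gr, 0)^2 + max(gc, 0)^2) > gap_px) next
      if (pixel_set_distance(footprints[[i]], footprints[[j]]) <= gap_px) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), roots)
  # stable object ordering: by smallest member segment id
  groups <- groups[order(vapply(groups, function(g) min(segment_ids[g]), 0L))]
  lapply(seq_along(groups), function(k) {
    g <- groups[[k]]
    detection_object(k, sort(segment_ids[g]),
                     do.call(rbind, footprints[g]),
                     origin = origin, pixel_size = pixel_size,
                     crs_id = crs_id)
  })
}

#' Extract per-segment pixel footprints
#'
#' @param segmap a [segment_map()].
#' @param ids segment ids to extract (default all).
#' @return named list of (row, col) matrices.
#' @export
extract_footprints <- function(segmap, ids = seq_len(segmap$n_segments)) {
  lab <- segmap$labels
  out <- lapply(ids, function(s) {
    w <- which(lab == s)
    cbind(row = ((w - 1L) %% nrow(lab)) + 1L,
          col = ((w - 1L) %/% nrow(lab)) + 1L)
  })
  names(out) <- ids
  out
}
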
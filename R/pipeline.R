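#' Run the full detection pipeline
#'
#' Chains the stages of the semi-automated detector: land masking,
#' high-pass filtering, gradient/watershed segmentation at the rule set's
#' scale level, lambda-schedule merging at its merge level, attribute
#' computation with its kernel size, rule classification, and grouping of
#' classified segments into detection objects. Outputs are deterministic
#' for fixed inputs and configuration.
#'
#' @param input a [raster_tile()] or path to a GeoTIFF.
#' @param ruleset a [rule_set()] (e.g. [candidate_algorithm()] or
#'   [default_ruleset()]) or a candidate algorithm id string.
#' @param land_mask optional [mask_set()] or path to a polygon GeoJSON.
#' @param gap_px grouping distance for multi-segment detections.
#' @param out_dir optional directory; when given, writes `detections.geojson`,
#'   `detections.csv`, `labels.tif`, `attributes.csv` and `manifest.json`.
#' @return list with elements `objects` (detection objects), `whale_ids`
#'   (classified segment ids), `records` (attribute table), `segmap`
#'   (merged segment map), `hp` (high-pass tile) and `manifest`.
#' @export
run_detect <- function(input, ruleset, land_mask = NULL, gap_px = 2,
                       out_dir = NULL) {
  if (is.character(ruleset)) ruleset <- candidate_algorithm(ruleset)
  stopifnot(inherits(ruleset, "rule_set"))
  timings <- c()
  clock <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    list(res = res, dt = proc.time()[["elapsed"]] - t0)
  }
  input_path <- NA_character_
  if (is.character(input)) {
    input_path <- input
    if (!file.exists(input)) stop("detect stage [read]: input file not found: ", input)
    input <- read_raster(input)
  }
  stopifnot(inherits(input, "raster_tile"))
  if (is.character(land_mask)) land_mask <- read_mask_polygons(land_mask)
  st <- clock({
    tile <- if (is.null(land_mask)) input else apply_land_mask(input, land_mask)
    high_pass_filter(tile, filter_spec())
  })
  hp <- st$res; timings["preprocess"] <- st$dt
  st <- clock({
    grad <- gradient_map(hp)
    watershed_segment(grad, ruleset$config$scale_level, intensity = hp)
  })
  seg0 <- st$res; timings["segment"] <- st$dt
  st <- clock(fast_lambda_merge(seg0, hp, ruleset$config$merge_level))
  segmap <- st$res; timings["merge"] <- st$dt
  st <- clock(compute_attributes(segmap, hp,
                                 kernel_size = ruleset$config$kernel_size))
  records <- st$res; timings["attributes"] <- st$dt
  st <- clock({
    ids <- classify_segments(records, ruleset)
    group_segments(extract_footprints(segmap, ids), gap_px = gap_px,
                   origin = hp$origin, pixel_size = hp$pixel_size,
                   crs_id = hp$crs_id, segment_ids = ids)
  })
  objects <- st$res; timings["classify_group"] <- st$dt
  manifest <- list(
    tool_version = as.character(utils::packageVersion("belugadetect")),
    config_snapshot = list(
      ruleset_id = ruleset$id,
      scale_level = ruleset$config$scale_level,
      merge_level = ruleset$config$merge_level,
      kernel_size = ruleset$config$kernel_size,
      segment_algorithm = ruleset$config$segment_algorithm,
      merge_algorithm = ruleset$config$merge_algorithm,
      rules = lapply(ruleset$rules, unclass),
      gap_px = gap_px),
    input_hashes = if (!is.na(input_path))
      as.list(tools::md5sum(input_path)) else list(),
    n_segments_initial = seg0$n_segments,
    n_segments_merged = segmap$n_segments,
    n_classified = sum(vapply(objects, function(o) length(o$member_segments), 0L)),
    n_objects = length(objects),
    timings = as.list(timings),
    outputs = list())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, c("detections.geojson", "detections.csv",
                                  "labels.tif", "attributes.csv",
                                  "manifest.json"))
    write_detections(objects, paths[1], ruleset_id = ruleset$id,
                     csv_path = paths[2])
    write_raster(tile_like(hp, matrix(as.numeric(segmap$labels),
                                      nrow(segmap$labels)),
                           nodata_mask = hp$nodata_mask,
                           tile_id = paste0(hp$tile_id, "_labels")), paths[3])
    write_attributes(records, paths[4])
    manifest$outputs <- as.list(paths)
    jsonlite::write_json(manifest, paths[5], auto_unbox = TRUE, digits = 8,
                         pretty = TRUE)
  }
  list(objects = objects, whale_ids = classify_segments(records, ruleset),
       records = records, segmap = segmap, seg_initial = seg0, hp = hp,
       manifest = manifest)
}

#' Benchmark rule sets over scenes
#'
#' The accuracy-assessment matrix: one metrics row per (rule set, scene)
#' pair. Per-cell failures are recorded (NA metrics, message in the
#' `error` column) and the run continues.
#'
#' @param rulesets list of [rule_set()]s or candidate id strings.
#' @param scenes named list of scenes, each a list with `tile`, `truth`,
#'   and optionally `masks` (as returned by [generate_scene()]).
#' @param buffer_m matching tolerance in meters.
#' @param gap_px grouping distance in pixels.
#' @return data.frame with one row per combination (metrics columns as in
#'   [metrics_report()], plus an `error` column).
#' @export
run_benchmark <- function(rulesets, scenes, buffer_m = 1.0, gap_px = 2) {
  rows <- list()
  for (rs in rulesets) {
    ruleset <- if (is.character(rs)) candidate_algorithm(rs) else rs
    for (scene_name in names(scenes)) {
      sc <- scenes[[scene_name]]
      row <- tryCatch({
        res <- run_detect(sc$tile, ruleset, land_mask = sc$masks,
                          gap_px = gap_px)
        r <- if (nrow(sc$truth$points) > 0) {
          metrics_report(res$objects, sc$truth, algorithm_id = ruleset$id,
                         tile_id = scene_name, buffer_m = buffer_m)
        } else {
          data.frame(algorithm_id = ruleset$id, tile_id = scene_name,
                     total_count = length(res$objects),
                     tp = 0L, fp = length(res$objects), fn = 0L,
                     fnr_pct = NA_real_, fpr_pct = NA_real_,
                     acd_pct = NA_real_)
        }
        r$error <- NA_character_
        r
      }, error = function(e) {
        data.frame(algorithm_id = ruleset$id, tile_id = scene_name,
                   total_count = NA_integer_, tp = NA_integer_,
                   fp = NA_integer_, fn = NA_integer_, fnr_pct = NA_real_,
                   fpr_pct = NA_real_, acd_pct = NA_real_,
                   error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0)
    return(data.frame(algorithm_id = character(0), tile_id = character(0),
                      total_count = integer(0), tp = integer(0),
                      fp = integer(0), fn = integer(0),
                      fnr_pct = numeric(0), fpr_pct = numeric(0),
                      acd_pct = numeric(0), error = character(0)))
  do.call(rbind, rows)
}

#' Published accuracy-count table
#'
#' The printed accuracy-assessment counts for the eleven candidate
#' algorithms on the training tile (32 observer-identified whales) and test
#' tile (190), shipped with the package so the rate computations can be
#' replayed without the licensed imagery.
#'
#' @return data.frame with columns tile_id, algorithm_id, total_count, fp,
#'   fn, identified and the printed fnr/fpr/acd percentages.
#' @export
published_counts <- function() {
  read.csv(system.file("extdata", "table2_counts.csv",
                       package = "belugadetect"),
           stringsAsFactors = FALSE)
}
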
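#' Pipeline configuration: segmentation and merge controls
#'
#' The two 0-100 levels mirror the controls of rule-based feature
#' extraction in commercial OBIA software: the scale level suppresses weak
#' edges before the watershed (higher = fewer, larger segments) and the
#' merge level drives lambda-schedule region merging (higher = more
#' merging). The kernel size is the moving window used for texture
#' attributes.
#'
#' @param scale_level real in \[0, 100\].
#' @param merge_level real in \[0, 100\].
#' @param kernel_size odd integer in \[3, 19\] (default 3).
#' @param segment_algorithm only `"EDGE"` (gradient watershed) is provided.
#' @param merge_algorithm only `"FAST_LAMBDA"` is provided.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(scale_level, merge_level, kernel_size = 3L,
                            segment_algorithm = "EDGE",
                            merge_algorithm = "FAST_LAMBDA") {
  if (scale_level < 0 || scale_level > 100) stop("scale_level must be in [0, 100]")
  if (merge_level < 0 || merge_level > 100) stop("merge_level must be in [0, 100]")
  kernel_size <- as.integer(kernel_size)
  if (kernel_size %% 2L == 0L || kernel_size < 3L || kernel_size > 19L)
    stop("kernel_size must be an odd integer between 3 and 19")
  segment_algorithm <- match.arg(segment_algorithm, "EDGE")
  merge_algorithm <- match.arg(merge_algorithm, "FAST_LAMBDA")
  structure(list(scale_level = as.numeric(scale_level),
                 merge_level = as.numeric(merge_level),
                 kernel_size = kernel_size,
                 segment_algorithm = segment_algorithm,
                 merge_algorithm = merge_algorithm),
            class = "pipeline_config")
}

#' Labeled segment map
#'
#' @param labels integer matrix; 0 marks nodata/unlabeled pixels, labels
#'   1..n_segments are consecutive and each label's pixel set is
#'   4-connected.
#' @return object of class `segment_map` with `labels` and `n_segments`.
#' @export
segment_map <- function(labels) {
  storage.mode(labels) <- "integer"
  n <- max(labels, 0L)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) && !identical(ids, seq_len(n)))
    stop("segment labels must be consecutive 1..n")
  structure(list(labels = labels, n_segments = as.integer(n)),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map> %d x %d px, %d segments\n",
              nrow(x$labels), ncol(x$labels), x$n_segments))
  invisible(x)
}

#' Contrast gradient map (smoothed Sobel magnitude)
#'
#' Transforms the image into a gradient map in which high values mark the
#' boundaries between whales and open water, the input to the EDGE
#' watershed. As in classic edge detection, the Sobel operator is applied
#' to a lightly regularised image (3x3 binomial smoothing): without the
#' smoothing, targets only one or two pixels wide are pure gradient ridges
#' with no interior minimum and can never seed a watershed basin of their
#' own, while smoothing restores a crest-line gradient dip for them and
#' lowers the noise-gradient floor. Replicate-edge padding; nodata is
#' propagated.
#'
#' @param tile a [raster_tile()] (normally the high-pass filtered image).
#' @param smooth apply the 3x3 binomial pre-smoothing (default TRUE; FALSE
#'   gives the raw Sobel magnitude).
#' @return `raster_tile` of nonnegative gradient magnitudes.
#' @export
gradient_map <- function(tile, smooth = TRUE) {
  stopifnot(inherits(tile, "raster_tile"))
  px <- tile$pixels
  px[is.na(px)] <- 0
  if (smooth) {
    px <- cpp_binomial3(px, tile$nodata_mask)
    px[is.na(px)] <- 0
  }
  out <- cpp_sobel(px, tile$nodata_mask)
  tile_like(tile, out, tile$nodata_mask)
}

#' Watershed segmentation with a scale level
#'
#' Gradient values strictly below the `scale_level`-th percentile of the
#' positive gradient values are suppressed to zero (weak-edge removal), then
#' a flooding watershed grown from the regional minima of the suppressed
#' gradient labels every valid pixel. Higher scale levels suppress more
#' edges and yield fewer, larger segments. Fully deterministic: minima are
#' discovered in row-major order and flooding ties resolve first-in
#' first-out.
#'
#' Strong-edge rescue: a bright target only one or two pixels wide is a
#' pure gradient ridge with no interior minimum, so it cannot seed a basin
#' and would dissolve into the surrounding water segment. Above-threshold
#' edge components whose peak gradient reaches twice the suppression
#' threshold (the classic strong:weak edge ratio) and whose support spans
#' at least 8 pixels are therefore labelled as regions of their own before
#' flooding. When `intensity` is supplied (the high-pass image in the
#' standard pipeline), only the bright (positive-intensity) side of such an
#' edge band is labelled, since the band otherwise mixes the ridge with its
#' dark reaction halo.
#'
#' @param gradient a nonnegative `raster_tile` from [gradient_map()].
#' @param scale_level real in \[0, 100\].
#' @param intensity optional `raster_tile` congruent with `gradient` (the
#'   high-pass image) used to restrict strong-edge rescue to bright
#'   (positive-intensity) pixels.
#' @return a [segment_map()].
#' @export
watershed_segment <- function(gradient, scale_level, intensity = NULL) {
  stopifnot(inherits(gradient, "raster_tile"))
  if (scale_level < 0 || scale_level > 100)
    stop("scale_level must be in [0, 100]")
  g <- gradient$pixels
  if (all(is.na(g))) stop("all-nodata gradient input")
  # percentile over all valid gradient values: under sensor noise nearly
  # every pixel has a positive gradient so this matches a positive-only
  # percentile, while on noise-free scenes the zero background dominates
  # and weak-edge suppression correctly leaves the sparse signal alone
  thresh <- unname(quantile(g[!is.na(g)], scale_level / 100, type = 7))
  int_m <- NULL
  bright_floor <- 0
  if (!is.null(intensity)) {
    stopifnot(inherits(intensity, "raster_tile"),
              identical(dim(intensity$pixels), dim(g)))
    int_m <- intensity$pixels
    int_m[is.na(int_m)] <- 0
    # rescue pieces must be genuinely bright: floor at the same percentile
    # of positive intensities that the scale level applies to the gradient
    ipos <- int_m[int_m > 0]
    if (length(ipos))
      bright_floor <- unname(quantile(ipos, scale_level / 100, type = 7))
  }
  segment_map(cpp_watershed(g, thresh, int_m, bright_floor = bright_floor))
}

#' Lambda-schedule merge cost of an adjacent segment pair
#'
#' The merge cost `t = (n_i n_j / (n_i + n_j)) (mu_i - mu_j)^2 / border`
#' trades spectral contrast against shared border length: it is zero iff
#' the means are equal, symmetric in the two segments, and halves when the
#' shared border doubles. Vectorised over its arguments.
#'
#' @param mean_i,mean_j segment mean intensities.
#' @param size_i,size_j segment pixel counts (>= 1).
#' @param border_len shared border length in pixel edges (>= 1; a zero
#'   border means the segments are not adjacent and is an error).
#' @return merge cost(s), nonnegative.
#' @export
merge_cost <- function(mean_i, mean_j, size_i, size_j, border_len) {
  if (any(size_i < 1) || any(size_j < 1)) stop("segment sizes must be >= 1")
  if (any(border_len < 1)) stop("border_len must be >= 1 (segments must be adjacent)")
  (size_i * size_j / (size_i + size_j)) * (mean_i - mean_j)^2 / border_len
}

#' Fast lambda-schedule region merging with a merge level
#'
#' Builds the region-adjacency graph of the segment map, computes the merge
#' cost ([merge_cost()]) of every adjacent pair, and sets the threshold
#' lambda at the `merge_level`-th percentile of that initial cost
#' distribution (lambda is unbounded at merge level 100, so every finite
#' cost qualifies). Adjacent pairs are then merged cheapest-first, with
#' means, sizes and borders updated locally, until no pair's current cost is
#' below lambda. Ties break on (smaller id, smaller neighbour id), making
#' the procedure deterministic; since lambda only sets the stopping point of
#' a fixed cheapest-first schedule, the number of segments is nonincreasing
#' in the merge level.
#'
#' Segment statistics are computed on the supplied tile, which in the
#' standard pipeline is the high-pass filtered image.
#'
#' @param segmap a [segment_map()] over `tile`.
#' @param tile the `raster_tile` providing pixel values.
#' @param merge_level real in \[0, 100\].
#' @return a merged [segment_map()], relabelled consecutively.
#' @export
fast_lambda_merge <- function(segmap, tile, merge_level) {
  stopifnot(inherits(segmap, "segment_map"), inherits(tile, "raster_tile"))
  if (merge_level < 0 || merge_level > 100)
    stop("merge_level must be in [0, 100]")
  if (segmap$n_segments <= 1) return(segmap)
  px <- tile$pixels
  px[is.na(px)] <- 0
  rag <- cpp_rag(segmap$labels, px, segmap$n_segments)
  if (length(rag$i) == 0) return(segmap)
  means <- rag$sum / rag$count
  costs <- merge_cost(means[rag$i], means[rag$j],
                      rag$count[rag$i], rag$count[rag$j], rag$border)
  lambda <- if (merge_level >= 100) Inf
            else unname(quantile(costs, merge_level / 100, type = 7))
  segment_map(cpp_lambda_merge(segmap$labels, px, segmap$n_segments, lambda))
}

#' Segment sizes of a segment map
#'
#' @param segmap a [segment_map()].
#' @return integer vector of pixel counts, one per segment id.
#' @export
segment_sizes <- function(segmap) {
  tabulate(segmap$labels[segmap$labels > 0L], nbins = segmap$n_segments)
}
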
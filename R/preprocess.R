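#' High-pass filter specification
#'
#' @param window odd window width >= 3. The smallest window (3x3) retains
#'   most of the native spatial resolution and is the default.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(window = 3L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("filter window must be an odd integer >= 3")
  structure(list(window = window), class = "filter_spec")
}

#' Mask land polygons out of a raster
#'
#' Pixels whose centers fall inside any land polygon are flagged nodata;
#' all other pixels are unchanged. Polygons entirely outside the tile are a
#' no-op.
#'
#' @param tile a [raster_tile()].
#' @param masks a [mask_set()] in the same coordinate frame.
#' @return the masked `raster_tile`.
#' @export
apply_land_mask <- function(tile, masks) {
  stopifnot(inherits(tile, "raster_tile"), inherits(masks, "mask_set"))
  if (length(masks$polygons) == 0) return(tile)
  h <- nrow(tile$pixels); w <- ncol(tile$pixels)
  ps <- tile$pixel_size
  mask <- tile$nodata_mask
  for (poly in masks$polygons) {
    # restrict the point-in-polygon test to the polygon's bounding box
    cmin <- max(1L, floor((min(poly[, 1]) - tile$origin[1]) / ps - 0.5) + 1L)
    cmax <- min(w, ceiling((max(poly[, 1]) - tile$origin[1]) / ps + 0.5))
    rmin <- max(1L, floor((tile$origin[2] - max(poly[, 2])) / ps - 0.5) + 1L)
    rmax <- min(h, ceiling((tile$origin[2] - min(poly[, 2])) / ps + 0.5))
    if (cmin > cmax || rmin > rmax) next
    rows <- rmin:rmax; cols <- cmin:cmax
    grid <- expand.grid(r = rows, c = cols)
    xy <- pixel_center_xy(tile, grid$r, grid$c)
    inside <- pracma::inpolygon(xy[, 1], xy[, 2], poly[, 1], poly[, 2],
                                boundary = TRUE)
    idx <- cbind(grid$r[inside], grid$c[inside])
    if (nrow(idx)) mask[idx] <- TRUE
  }
  tile_like(tile, tile$pixels, mask)
}

#' High-pass spatial filter
#'
#' Convolution with the classic sharpen-residual high-pass kernel of width
#' `w`: center weight `w^2 - 1`, all other weights -1 (for w = 3: center 8,
#' neighbours -1). The filter emphasises small bright targets (whales)
#' against open water: any constant region maps to zero, and output values
#' can be negative (they are never clipped). Border pixels use replicate
#' padding; windows intersecting nodata renormalize the weights over the
#' valid pixels, so land edges do not produce spurious bright rims. Nodata
#' pixels stay nodata.
#'
#' @param tile a [raster_tile()].
#' @param spec a [filter_spec()].
#' @return filtered `raster_tile`.
#' @export
high_pass_filter <- function(tile, spec = filter_spec()) {
  stopifnot(inherits(tile, "raster_tile"), inherits(spec, "filter_spec"))
  if (spec$window > nrow(tile$pixels) || spec$window > ncol(tile$pixels))
    stop("filter window larger than tile")
  px <- tile$pixels
  px[is.na(px)] <- 0  # ignored: masked positions are skipped in the kernel
  out <- cpp_highpass(px, tile$nodata_mask, spec$window)
  tile_like(tile, out, tile$nodata_mask)
}
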
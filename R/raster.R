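#' Single-band georeferenced raster tile
#'
#' The container used at every pipeline stage: a matrix of pixel intensities
#' with a congruent nodata mask and minimal georeferencing. Pixel (1,1) is
#' the top-left pixel; `origin` is the world coordinate of its top-left
#' *corner*, the world x axis increases with column and the world y axis
#' decreases with row. The world coordinate of a pixel is its center. Masked
#' (nodata) pixels are stored as `NA`.
#'
#' @param pixels numeric matrix of intensities. Non-finite entries are
#'   treated as nodata.
#' @param nodata_mask logical matrix of the same dimension, `TRUE` where the
#'   pixel is excluded. Defaults to no nodata.
#' @param pixel_size ground meters per pixel (default 0.31, the nominal
#'   ground sample distance of WorldView-3 panchromatic imagery).
#' @param origin numeric length-2, world (x, y) of the top-left corner of
#'   pixel (1,1).
#' @param crs_id coordinate reference identifier, or `"none"` when the frame
#'   is a local metric grid (e.g. synthetic scenes).
#' @param tile_id text label carried through tiling and output files.
#' @return an object of class `raster_tile`.
#' @export
raster_tile <- function(pixels, nodata_mask = NULL, pixel_size = 0.31,
                        origin = c(0, 0), crs_id = "none", tile_id = "tile") {
  if (!is.matrix(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1)
    stop("pixels must be a non-empty matrix")
  storage.mode(pixels) <- "double"
  if (is.null(nodata_mask)) {
    nodata_mask <- matrix(FALSE, nrow(pixels), ncol(pixels))
  }
  if (!identical(dim(pixels), dim(nodata_mask)))
    stop("pixels and nodata_mask must have identical dimensions")
  nodata_mask <- nodata_mask | !is.finite(pixels)
  pixels[nodata_mask] <- NA_real_
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  structure(
    list(pixels = pixels, nodata_mask = nodata_mask,
         pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin[1:2]),
         crs_id = as.character(crs_id), tile_id = as.character(tile_id)),
    class = "raster_tile")
}

#' @export
print.raster_tile <- function(x, ...) {
  cat(sprintf("<raster_tile '%s'> %d x %d px @ %.3g m/px, origin (%.6g, %.6g), crs %s, %d nodata px\n",
              x$tile_id, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              x$origin[1], x$origin[2], x$crs_id, sum(x$nodata_mask)))
  invisible(x)
}

#' @export
dim.raster_tile <- function(x) dim(x$pixels)

# world coordinates of pixel centers for 1-based (row, col) indices
pixel_center_xy <- function(tile, rows, cols) {
  cbind(x = tile$origin[1] + (cols - 0.5) * tile$pixel_size,
        y = tile$origin[2] - (rows - 0.5) * tile$pixel_size)
}

# replace pixel data, keeping georeferencing
tile_like <- function(tile, pixels, nodata_mask = NULL, tile_id = tile$tile_id) {
  raster_tile(pixels, nodata_mask %||% (is.na(pixels)),
              pixel_size = tile$pixel_size, origin = tile$origin,
              crs_id = tile$crs_id, tile_id = tile_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition a raster into a grid of tiles
#'
#' Splits the raster into `n_rows` x `n_cols` tiles with no overlap and no
#' gap. When the dimensions do not divide evenly, the tiles on the right and
#' bottom edges absorb the remainder, so pixel values are never padded or
#' modified. Tile ids are `"R<r>C<c>"` appended to the parent id.
#'
#' @param tile a [raster_tile()].
#' @param n_rows,n_cols number of tile rows/columns (each >= 1 and at most
#'   the corresponding pixel dimension).
#' @return list of `raster_tile` in row-major order.
#' @export
tile_raster <- function(tile, n_rows, n_cols) {
  h <- nrow(tile$pixels); w <- ncol(tile$pixels)
  if (n_rows < 1 || n_cols < 1) stop("n_rows and n_cols must be >= 1")
  if (n_rows > h || n_cols > w)
    stop("tiling exceeds pixel dimensions (", h, " x ", w, ")")
  rh <- h %/% n_rows; cw <- w %/% n_cols
  row_starts <- (seq_len(n_rows) - 1L) * rh
  col_starts <- (seq_len(n_cols) - 1L) * cw
  row_ends <- c(row_starts[-1L], h)
  col_ends <- c(col_starts[-1L], w)
  out <- vector("list", n_rows * n_cols)
  k <- 0L
  for (r in seq_len(n_rows)) {
    for (cc in seq_len(n_cols)) {
      ri <- (row_starts[r] + 1L):row_ends[r]
      ci <- (col_starts[cc] + 1L):col_ends[cc]
      k <- k + 1L
      out[[k]] <- raster_tile(
        tile$pixels[ri, ci, drop = FALSE],
        tile$nodata_mask[ri, ci, drop = FALSE],
        pixel_size = tile$pixel_size,
        origin = c(tile$origin[1] + col_starts[cc] * tile$pixel_size,
                   tile$origin[2] - row_starts[r] * tile$pixel_size),
        crs_id = tile$crs_id,
        tile_id = sprintf("%s_R%dC%d", tile$tile_id, r, cc))
    }
  }
  out
}

#' Mosaic tiles back into a single raster
#'
#' Reassembles tiles produced by [tile_raster()] (or any set of
#' non-overlapping tiles on a common grid) by their origins. Inverse of
#' tiling: `mosaic_tiles(tile_raster(x, r, c))` is pixel-identical to `x`.
#'
#' @param tiles list of `raster_tile` sharing `pixel_size` and grid alignment.
#' @return a single `raster_tile`.
#' @export
mosaic_tiles <- function(tiles) {
  stopifnot(length(tiles) >= 1)
  ps <- tiles[[1]]$pixel_size
  ox <- min(vapply(tiles, function(t) t$origin[1], 0))
  oy <- max(vapply(tiles, function(t) t$origin[2], 0))
  col_off <- vapply(tiles, function(t) round((t$origin[1] - ox) / ps), 0)
  row_off <- vapply(tiles, function(t) round((oy - t$origin[2]) / ps), 0)
  h <- max(vapply(seq_along(tiles), function(i) row_off[i] + nrow(tiles[[i]]$pixels), 0))
  w <- max(vapply(seq_along(tiles), function(i) col_off[i] + ncol(tiles[[i]]$pixels), 0))
  px <- matrix(NA_real_, h, w)
  msk <- matrix(TRUE, h, w)
  for (i in seq_along(tiles)) {
    t <- tiles[[i]]
    ri <- (row_off[i] + 1):(row_off[i] + nrow(t$pixels))
    ci <- (col_off[i] + 1):(col_off[i] + ncol(t$pixels))
    px[ri, ci] <- t$pixels
    msk[ri, ci] <- t$nodata_mask
  }
  raster_tile(px, msk, pixel_size = ps, origin = c(ox, oy),
              crs_id = tiles[[1]]$crs_id, tile_id = tiles[[1]]$tile_id)
}
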
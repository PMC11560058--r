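# Minimal single-band GeoTIFF codec.
#
# Scope: baseline uncompressed strip-organised TIFF, one sample per pixel,
# unsigned/signed integer or IEEE float samples of 8/16/32/64 bits, with the
# GeoTIFF ModelPixelScale/ModelTiepoint tags and the GDAL nodata tag. Written
# files use 64-bit float samples so a write/read cycle is bit-for-bit exact.
# This codec exists because no installed package can store panchromatic
# intensities outside [0,1] together with georeferencing.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                    `11` = 4L, `12` = 8L)

NODATA_FILL <- -3.402823466e+38  # float32 lowest, conventional GDAL fill

#' Read a single-band GeoTIFF raster
#'
#' Supports baseline uncompressed single-band TIFF (either byte order) with
#' integer or floating-point samples. Georeferencing is taken from the
#' ModelPixelScale and ModelTiepoint tags; the nodata mask from the GDAL
#' nodata tag (ASCII tag 42113). Files without georeferencing are accepted
#' with a warning: pixel size falls back to `default_pixel_size` and the CRS
#' is set to `"none"`.
#'
#' @param path file path to a readable GeoTIFF.
#' @param default_pixel_size pixel size assumed when the file carries no
#'   ModelPixelScale tag (default 0.31 m).
#' @return a [raster_tile()].
#' @export
read_raster <- function(path, default_pixel_size = 0.31) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(magic, charToRaw("II"))) "little"
            else if (identical(magic, charToRaw("MM"))) "big"
            else stop("not a TIFF file: ", path)
  r16 <- function() readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
  r32 <- function() {
    v <- readBin(con, "integer", 1, 4, endian = endian)
    if (v < 0) v + 2^32 else as.numeric(v)
  }
  if (r16() != 42L) stop("not a TIFF file: ", path)
  ifd_off <- r32()
  seek(con, ifd_off)
  n_entries <- r16()
  tags <- list()
  for (k in seq_len(n_entries)) {
    tag <- r16(); type <- r16(); count <- r32()
    value_bytes <- readBin(con, "raw", 4)
    tags[[as.character(tag)]] <- list(type = type, count = count,
                                      raw = value_bytes)
  }
  tag_values <- function(tag) {
    e <- tags[[as.character(tag)]]
    if (is.null(e)) return(NULL)
    size <- TIFF_TYPE_SIZE[[as.character(e$type)]]
    total <- size * e$count
    if (total <= 4) {
      raw <- e$raw[seq_len(total)]
    } else {
      off <- readBin(e$raw, "integer", 1, 4, endian = endian)
      if (off < 0) off <- off + 2^32
      cur <- seek(con)
      seek(con, off)
      raw <- readBin(con, "raw", total)
      seek(con, cur)
    }
    decode_tiff_values(raw, e$type, e$count, endian)
  }
  w <- tag_values(256); h <- tag_values(257)
  if (is.null(w) || is.null(h)) stop("TIFF lacks image dimensions")
  spp <- tag_values(277) %||% 1
  if (spp > 1) stop("multi-band raster not supported (", spp, " samples per pixel)")
  compression <- tag_values(259) %||% 1
  if (compression != 1) stop("compressed TIFF not supported (compression ", compression, ")")
  bits <- tag_values(258) %||% 1
  fmt <- tag_values(339) %||% 1  # 1 uint, 2 int, 3 float
  strip_off <- tag_values(273)
  strip_cnt <- tag_values(279)
  if (is.null(strip_off)) stop("TIFF lacks strip offsets")
  if (is.null(strip_cnt)) strip_cnt <- h * w * bits / 8
  n_total <- w * h
  size <- bits %/% 8L
  vals <- numeric(0)
  for (s in seq_along(strip_off)) {
    seek(con, strip_off[s])
    n_s <- strip_cnt[s] %/% size
    chunk <- if (fmt == 3) {
      readBin(con, "double", n_s, size, endian = endian)
    } else if (fmt == 2) {
      readBin(con, "integer", n_s, size, signed = TRUE, endian = endian)
    } else {
      if (size <= 2) {
        readBin(con, "integer", n_s, size, signed = FALSE, endian = endian)
      } else {
        v <- readBin(con, "integer", n_s, size, endian = endian)
        v <- as.numeric(v); v[v < 0] <- v[v < 0] + 2^32; v
      }
    }
    vals <- c(vals, as.numeric(chunk))
  }
  if (length(vals) < n_total) stop("TIFF pixel data truncated")
  px <- matrix(vals[seq_len(n_total)], nrow = h, ncol = w, byrow = TRUE)
  scale <- tag_values(33550)
  tie <- tag_values(33922)
  if (is.null(scale)) {
    warning("no georeferencing tags; assuming pixel size ",
            default_pixel_size, " m and local coordinates")
    ps <- default_pixel_size
    origin <- c(0, 0)
  } else {
    ps <- scale[1]
    origin <- if (is.null(tie)) c(0, 0)
              else c(tie[4] - tie[1] * ps, tie[5] + tie[2] * ps)
  }
  desc <- tag_values(270)
  crs_id <- "none"; tile_id <- sub("\\.[^.]*$", "", basename(path))
  if (!is.null(desc)) {
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
    if (is.null(meta)) {
      warning("unreadable image metadata; setting crs_id = 'none'")
    } else {
      crs_id <- meta$crs_id %||% "none"
      tile_id <- meta$tile_id %||% tile_id
    }
  }
  mask <- matrix(FALSE, h, w)
  nd_txt <- tag_values(42113)
  if (!is.null(nd_txt)) {
    nd <- suppressWarnings(as.numeric(nd_txt))
    if (is.finite(nd)) mask <- px == nd
    else if (is.nan(nd)) mask <- is.nan(px)
  }
  raster_tile(px, mask, pixel_size = ps, origin = origin,
              crs_id = crs_id, tile_id = tile_id)
}

decode_tiff_values <- function(raw, type, count, endian) {
  switch(as.character(type),
    `2` = {
      txt <- rawToChar(raw[raw != as.raw(0)])
      txt
    },
    `3` = readBin(raw, "integer", count, 2, signed = FALSE, endian = endian),
    `4` = {
      v <- readBin(raw, "integer", count, 4, endian = endian)
      v <- as.numeric(v); v[v < 0] <- v[v < 0] + 2^32; v
    },
    `11` = readBin(raw, "double", count, 4, endian = endian),
    `12` = readBin(raw, "double", count, 8, endian = endian),
    stop("unsupported TIFF tag type ", type))
}

#' Write a raster tile as a single-band GeoTIFF
#'
#' Writes an uncompressed little-endian GeoTIFF with 64-bit float samples,
#' ModelPixelScale/ModelTiepoint georeferencing, the GDAL nodata tag, and
#' the CRS/tile identifiers in the image description. Nodata pixels are
#' stored as the nodata fill value. `read_raster(write_raster(x))` returns
#' the pixels bit-for-bit.
#'
#' @param tile a [raster_tile()].
#' @param path output file path (conventionally `.tif`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(tile, path) {
  stopifnot(inherits(tile, "raster_tile"))
  px <- tile$pixels
  px[tile$nodata_mask] <- NODATA_FILL
  h <- nrow(px); w <- ncol(px)
  data_bytes <- h * w * 8
  desc <- sprintf('{"crs_id":"%s","tile_id":"%s"}', tile$crs_id, tile$tile_id)
  desc_raw <- c(charToRaw(desc), as.raw(0))
  nd_raw <- c(charToRaw(sprintf("%.17g", NODATA_FILL)), as.raw(0))
  pad_even <- function(r) if (length(r) %% 2L) c(r, as.raw(0)) else r
  desc_pad <- pad_even(desc_raw)
  nd_pad <- pad_even(nd_raw)
  ps <- tile$pixel_size
  # layout: header(8) | pixel data | overflow tag data | IFD
  data_off <- 8
  extra_off <- data_off + data_bytes
  # overflow blocks: description, pixel scale (24), tiepoint (48), nodata
  desc_off <- extra_off
  scale_off <- desc_off + length(desc_pad)
  tie_off <- scale_off + 24
  nd_off <- tie_off + 48
  ifd_off <- nd_off + length(nd_pad)
  entries <- list(
    list(256, 4L, 1L, w),
    list(257, 4L, 1L, h),
    list(258, 3L, 1L, 64L),
    list(259, 3L, 1L, 1L),
    list(262, 3L, 1L, 1L),
    list(270, 2L, length(desc_raw), desc_off),
    list(273, 4L, 1L, data_off),
    list(277, 3L, 1L, 1L),
    list(278, 4L, 1L, h),
    list(279, 4L, 1L, data_bytes),
    list(339, 3L, 1L, 3L),
    list(33550, 12L, 3L, scale_off),
    list(33922, 12L, 6L, tie_off),
    list(42113, 2L, length(nd_raw), nd_off))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, 2, endian = "little")
  writeBin(as.integer(ifd_off), con, 4, endian = "little")
  writeBin(as.numeric(t(px)), con, 8, endian = "little")
  writeBin(desc_pad, con)
  writeBin(c(ps, ps, 0), con, 8, endian = "little")
  writeBin(c(0, 0, 0, tile$origin[1], tile$origin[2], 0), con, 8,
           endian = "little")
  writeBin(nd_pad, con)
  writeBin(length(entries), con, 2, endian = "little")
  for (e in entries) {
    writeBin(as.integer(e[[1]]), con, 2, endian = "little")
    writeBin(as.integer(e[[2]]), con, 2, endian = "little")
    writeBin(as.integer(e[[3]]), con, 4, endian = "little")
    size <- TIFF_TYPE_SIZE[[as.character(e[[2]])]] * e[[3]]
    if (size <= 4 && e[[2]] == 3L) {
      writeBin(as.integer(e[[4]]), con, 2, endian = "little")
      writeBin(0L, con, 2, endian = "little")
    } else {
      writeBin(as.integer(e[[4]]), con, 4, endian = "little")
    }
  }
  writeBin(0L, con, 4, endian = "little")  # no next IFD
  invisible(path)
}
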
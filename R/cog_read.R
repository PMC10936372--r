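# Lazy tiled-TIFF reading over a ByteSource. The parsed header (IFD chain +
# tile indexes) is cached on the source, so after the first open each tile
# read costs exactly one range request of that tile's stored size.

HEADER_PREFIX_BYTES <- 16384

# grow the cached front buffer until it holds at least `need` bytes
fetch_front <- function(src, need) {
  buf <- src$cache$front %||% raw(0)
  if (length(buf) < need) {
    want <- max(need, HEADER_PREFIX_BYTES)
    more <- read_bytes(src, length(buf), want - length(buf))
    buf <- c(buf, more)
    if (length(buf) < need)
      stop("corrupt-source: file truncated inside header")
    src$cache$front <- buf
  }
  buf
}

as_byte_source <- function(x) {
  if (inherits(x, "ByteSource")) x else open_byte_source(x)
}

parse_ifd_value <- function(buf, type, count, slot_pos) {
  nb <- count * switch(as.character(type), "2" = 1L, "3" = 2L, "4" = 4L)
  pos <- if (nb <= 4) slot_pos else rd_u32le(buf, slot_pos) + 1
  switch(as.character(type),
    "2" = rawToChar(buf[pos + seq_len(count - 1L) - 1L]),  # drop trailing NUL
    "3" = rd_u16le(buf, pos, count),
    "4" = rd_u32le(buf, pos, count)
  )
}

#' Open a COG and parse its header
#'
#' Parses the TIFF header, IFD chain and tile indexes of a file written by
#' [write_cog()] (or any little-endian tiled TIFF with the same tags). Only
#' the front of the file is fetched: a fixed-size prefix, extended if the
#' tile index runs past it. The parsed structure is cached on the
#' `ByteSource`, so subsequent [read_tile()] calls fetch nothing but tile
#' payloads.
#'
#' @param x a `ByteSource`, file path, or URL.
#' @return an object of class `cog` describing every level (API level 0 =
#'   coarsest), with `$source` holding the byte source.
#' @export
cog_open <- function(x) {
  src <- as_byte_source(x)
  if (!is.null(src$cache$cog)) return(src$cache$cog)

  buf <- fetch_front(src, 8)
  if (rawToChar(buf[1:2]) != "II" || rd_u16le(buf, 3) != 42)
    stop("corrupt-source: not a little-endian TIFF")
  ifd_off <- rd_u32le(buf, 5)

  levels <- list()
  while (ifd_off != 0) {
    buf <- fetch_front(src, ifd_off + 2)
    nent <- rd_u16le(buf, ifd_off + 1)
    buf <- fetch_front(src, ifd_off + 2 + nent * 12 + 4)
    tags <- new.env(parent = emptyenv())
    for (j in seq_len(nent)) {
      epos <- ifd_off + 2 + (j - 1) * 12 + 1
      tag <- rd_u16le(buf, epos)
      type <- rd_u16le(buf, epos + 2)
      count <- rd_u32le(buf, epos + 4)
      nb <- count * switch(as.character(type), "2" = 1, "3" = 2, "4" = 4,
                           "5" = 8, 0)
      if (nb > 4) buf <- fetch_front(src, rd_u32le(buf, epos + 8) + nb)
      if (type %in% c(2, 3, 4))
        assign(as.character(tag),
               parse_ifd_value(buf, type, count, epos + 8), envir = tags)
    }
    g <- function(tag, default = NULL) {
      if (exists(as.character(tag), tags)) get(as.character(tag), tags)
      else default
    }
    if (is.null(g(322)))
      stop("corrupt-source: not a tiled TIFF (no TileWidth)")
    bits <- g(258)[1]
    fmt <- (g(339) %||% 1)[1]
    dtype <- if (fmt == 3) "float32" else if (bits == 16) "uint16" else "uint8"
    levels[[length(levels) + 1L]] <- list(
      width = g(256), height = g(257), bits = bits, dtype = dtype,
      spp = g(277, 1), compression = g(259, 1),
      tile_w = g(322), tile_h = g(323),
      offsets = g(324), bytecounts = g(325),
      description = g(270)
    )
    ifd_off <- rd_u32le(buf, ifd_off + 2 + nent * 12 + 1)
  }
  if (length(levels) == 0L) stop("corrupt-source: no IFDs")

  desc <- tryCatch(jsonlite::fromJSON(levels[[1]]$description %||% "{}"),
                   error = function(e) list())
  cog <- structure(list(
    source = src,
    disk_levels = levels,            # finest first, as stored
    n_levels = length(levels),
    width = levels[[1]]$width, height = levels[[1]]$height,
    tile_size = levels[[1]]$tile_w,
    downsample_factor = as.integer(desc$downsample_factor %||% 2L),
    dtype = levels[[1]]$dtype,
    channel_names = as.character(desc$channel_names %||%
                                   paste0("ch", seq_len(levels[[1]]$spp)))
  ), class = "cog")
  src$cache$cog <- cog
  cog
}

#' @export
print.cog <- function(x, ...) {
  cat(sprintf("COG %s: %.0f x %.0f, %d channel(s), %d level(s), tile %d\n",
              x$source$uri, x$width, x$height,
              length(x$channel_names), x$n_levels, x$tile_size))
  invisible(x)
}

#' Pyramid geometry of an opened COG
#' @param x a `cog`, `ByteSource`, path, or URL.
#' @return a [pyramid_meta()] list.
#' @export
cog_meta <- function(x) {
  cog <- if (inherits(x, "cog")) x else cog_open(x)
  pyramid_meta(cog$width, cog$height, cog$tile_size,
               cog$downsample_factor, n_levels = cog$n_levels)
}

unpack_tile_pixels <- function(raw, dtype, tw, th, spp) {
  v <- switch(dtype,
    uint8 = as.integer(raw),
    uint16 = as.integer(raw[c(TRUE, FALSE)]) +
             256L * as.integer(raw[c(FALSE, TRUE)]),
    float32 = readBin(raw, "double", n = length(raw) / 4L, size = 4L,
                      endian = "little")
  )
  if (length(v) != tw * th * spp) stop("corrupt-source: tile size mismatch")
  aperm(array(v, dim = c(spp, tw, th)), c(3L, 2L, 1L))
}

#' Read one tile of a COG lazily
#'
#' Fetches and decodes a single tile. After the header has been cached (first
#' [cog_open()] on the source), each call transfers exactly the stored byte
#' count of the requested tile — the property that makes viewport-driven
#' loading cheap.
#'
#' @param x a `cog` (or source/path, opened on the fly).
#' @param level API level, 0 = coarsest.
#' @param tile_x,tile_y 0-based tile column/row at that level.
#' @param clip drop the padding of edge tiles so the returned array covers
#'   only real image pixels (default `TRUE`).
#' @return an [image_plane()] holding the decoded tile.
#' @export
read_tile <- function(x, level, tile_x, tile_y, clip = TRUE) {
  cog <- if (inherits(x, "cog")) x else cog_open(x)
  if (level < 0 || level >= cog$n_levels)
    stop("tile-address: level out of range")
  lv <- cog$disk_levels[[cog$n_levels - level]]
  ntx <- ceiling(lv$width / lv$tile_w)
  nty <- ceiling(lv$height / lv$tile_h)
  if (tile_x < 0 || tile_x >= ntx || tile_y < 0 || tile_y >= nty)
    stop("tile-address: tile (", tile_x, ",", tile_y, ") out of range")
  idx <- tile_y * ntx + tile_x + 1
  payload <- read_bytes(cog$source, lv$offsets[idx], lv$bytecounts[idx])
  if (length(payload) < lv$bytecounts[idx])
    stop("corrupt-source: truncated tile data")

  px <- switch(as.character(lv$compression),
    "1" = unpack_tile_pixels(payload, lv$dtype, lv$tile_w, lv$tile_h, lv$spp),
    "8" = {
      dec <- tryCatch(memDecompress(payload, type = "gzip"),
                      error = function(e) stop("corrupt-source: ",
                                               "deflate tile failed to decode"))
      unpack_tile_pixels(dec, lv$dtype, lv$tile_w, lv$tile_h, lv$spp)
    },
    "7" = {
      img <- jpeg::readJPEG(payload)
      if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
      round(img * 255)
    },
    stop("corrupt-source: unsupported compression code ", lv$compression)
  )
  if (clip) {
    rows <- seq_len(min(lv$tile_h, lv$height - tile_y * lv$tile_h))
    cols <- seq_len(min(lv$tile_w, lv$width - tile_x * lv$tile_w))
    px <- px[rows, cols, , drop = FALSE]
  }
  image_plane(px, dtype = cog$dtype, channel_names = cog$channel_names)
}

#' Read and mosaic one whole level of a COG
#'
#' Convenience full-scan: reads every tile of `level` and reassembles the
#' complete plane. Used for verification and by converters; a viewer would
#' use [tiles_for_viewport()] + [read_tile()] instead.
#'
#' @inheritParams read_tile
#' @return an [image_plane()].
#' @export
read_level <- function(x, level = NULL) {
  cog <- if (inherits(x, "cog")) x else cog_open(x)
  if (is.null(level)) level <- cog$n_levels - 1L
  lv <- cog$disk_levels[[cog$n_levels - level]]
  ntx <- ceiling(lv$width / lv$tile_w)
  nty <- ceiling(lv$height / lv$tile_h)
  out <- array(if (lv$dtype == "float32") 0 else 0L,
               dim = c(lv$height, lv$width, lv$spp))
  for (ty in seq_len(nty) - 1L) for (tx in seq_len(ntx) - 1L) {
    tl <- read_tile(cog, level, tx, ty)
    d <- dim(tl$pixels)
    out[ty * lv$tile_h + seq_len(d[1]), tx * lv$tile_w + seq_len(d[2]), ] <-
      tl$pixels
  }
  image_plane(out, dtype = cog$dtype, channel_names = cog$channel_names)
}
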
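# Tiled multi-resolution TIFF writer in the cloud-optimized (COG) layout:
# all IFDs and their tile indexes live in a compact block at the front of the
# file (so one small prefix fetch gives a reader the full tile index), the
# full-resolution image is IFD0, and overviews follow as reduced-resolution
# subfiles. Little-endian classic TIFF.

TIFF_TYPE_ASCII <- 2L
TIFF_TYPE_SHORT <- 3L
TIFF_TYPE_LONG <- 4L

COMPRESSION_CODE <- c(none = 1, jpeg = 7, deflate = 8)

# one IFD entry; value_raw already little-endian, offset_slot is either the
# packed value (<= 4 bytes) or NA meaning "external, fill in later"
tiff_entry <- function(tag, type, count, value_raw) {
  list(tag = tag, type = type, count = count, value = value_raw)
}

pack_tile_pixels <- function(tile, dtype) {
  v <- as.vector(aperm(tile, c(3L, 2L, 1L)))  # chunky, row-major
  switch(dtype,
    uint8 = as.raw(v),
    uint16 = u16le(v),
    float32 = writeBin(as.double(v), raw(), size = 4L, endian = "little")
  )
}

# extract tile (ty, tx) from plane; pad to full tile size, replicating edges
# (pleasant for JPEG; harmless padding for lossless codecs)
extract_tile <- function(px, ts, tx, ty) {
  d <- dim(px)
  r <- ty * ts + seq_len(ts); c <- tx * ts + seq_len(ts)
  px[pmin(r, d[1]), pmin(c, d[2]), , drop = FALSE]
}

encode_tile <- function(tile, dtype, compression, quality) {
  switch(compression,
    none = pack_tile_pixels(tile, dtype),
    deflate = memCompress(pack_tile_pixels(tile, dtype), type = "gzip"),
    jpeg = {
      img <- tile / 255
      if (dim(img)[3] == 1L) dim(img) <- dim(img)[1:2]
      jpeg::writeJPEG(img, raw(), quality = quality / 100)
    }
  )
}

#' Write a tile pyramid as a cloud-optimized tiled TIFF
#'
#' Serializes a [build_pyramid()] result to a tiled multi-resolution TIFF in
#' the COG layout: header and all tile indexes at the front of the file,
#' full-resolution image first, overviews after it as reduced-resolution
#' subfiles. Files written with `compression = "deflate"` or `"none"`
#' round-trip bit-exactly; `"jpeg"` (default quality 90) is lossy and only
#' valid for 8-bit images with 1 or 3 channels.
#'
#' @param pyramid a `TilePyramid`.
#' @param path output file path.
#' @param compression `"deflate"`, `"jpeg"`, or `"none"`.
#' @param quality JPEG quality, 1-100.
#' @return `path`, invisibly.
#' @export
write_cog <- function(pyramid, path, compression = c("deflate", "jpeg", "none"),
                      quality = 90) {
  stopifnot(inherits(pyramid, "TilePyramid"))
  compression <- match.arg(compression)
  finest <- pyramid$levels[[length(pyramid$levels)]]
  dtype <- finest$dtype
  nch <- plane_channels(finest)
  if (compression == "jpeg") {
    if (dtype != "uint8" || !nch %in% c(1L, 3L))
      stop("unsupported-compression: jpeg requires uint8 with 1 or 3 channels")
    if (quality < 1 || quality > 100)
      stop("invalid-argument: quality must be in 1..100")
  }
  ts <- pyramid$tile_size

  # disk order: finest level first
  disk_levels <- rev(pyramid$levels)
  n <- length(disk_levels)

  # encode all tiles up front so the index can be laid out before the data
  enc <- vector("list", n)
  for (i in seq_len(n)) {
    px <- disk_levels[[i]]$pixels
    d <- dim(px)
    ntx <- ceiling(d[2] / ts); nty <- ceiling(d[1] / ts)
    tiles <- vector("list", ntx * nty)
    k <- 1L
    for (ty in seq_len(nty) - 1L) for (tx in seq_len(ntx) - 1L) {
      tiles[[k]] <- encode_tile(extract_tile(px, ts, tx, ty), dtype,
                                compression, quality)
      k <- k + 1L
    }
    enc[[i]] <- list(tiles = tiles, width = d[2], height = d[1],
                     ntx = ntx, nty = nty)
  }

  desc <- jsonlite::toJSON(list(
    channel_names = finest$channel_names, dtype = dtype,
    tile_size = ts, downsample_factor = pyramid$downsample_factor,
    n_levels = n
  ), auto_unbox = TRUE)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))

  bits <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
  fmt <- if (dtype == "float32") 3L else 1L
  photometric <- if (compression == "jpeg" && nch == 3L) 6L
                 else if (nch == 3L && dtype == "uint8") 2L else 1L
  n_extra <- if (photometric == 1L && nch > 1L) nch - 1L else 0L

  build_entries <- function(i) {
    lv <- enc[[i]]
    nt <- length(lv$tiles)
    e <- list(
      tiff_entry(254L, TIFF_TYPE_LONG, 1L, if (i == 1L) 0 else 1),
      tiff_entry(256L, TIFF_TYPE_LONG, 1L, lv$width),
      tiff_entry(257L, TIFF_TYPE_LONG, 1L, lv$height),
      tiff_entry(258L, TIFF_TYPE_SHORT, nch, rep(bits, nch)),
      tiff_entry(259L, TIFF_TYPE_LONG, 1L, COMPRESSION_CODE[[compression]]),
      tiff_entry(262L, TIFF_TYPE_SHORT, 1L, photometric)
    )
    if (i == 1L)
      e <- c(e, list(tiff_entry(270L, TIFF_TYPE_ASCII, length(desc_raw),
                                desc_raw)))
    e <- c(e, list(
      tiff_entry(277L, TIFF_TYPE_SHORT, 1L, nch),
      tiff_entry(284L, TIFF_TYPE_SHORT, 1L, 1),
      tiff_entry(322L, TIFF_TYPE_LONG, 1L, ts),
      tiff_entry(323L, TIFF_TYPE_LONG, 1L, ts),
      tiff_entry(324L, TIFF_TYPE_LONG, nt, rep(0, nt)),      # patched below
      tiff_entry(325L, TIFF_TYPE_LONG, nt,
                 vapply(lv$tiles, length, numeric(1)))
    ))
    if (n_extra > 0L)
      e <- c(e, list(tiff_entry(338L, TIFF_TYPE_SHORT, n_extra,
                                rep(0, n_extra))))
    c(e, list(tiff_entry(339L, TIFF_TYPE_SHORT, nch, rep(fmt, nch))))
  }

  entry_value_raw <- function(ent) {
    switch(as.character(ent$type),
      "2" = as.raw(ent$value),
      "3" = u16le(ent$value),
      "4" = u32le(ent$value)
    )
  }
  value_nbytes <- function(ent)
    ent$count * switch(as.character(ent$type), "2" = 1L, "3" = 2L, "4" = 4L)

  all_entries <- lapply(seq_len(n), build_entries)

  # layout pass: header | per level [IFD block | external values] | tile data
  pos <- 8
  ifd_offset <- numeric(n)
  ext_offset <- vector("list", n)
  for (i in seq_len(n)) {
    ents <- all_entries[[i]]
    ifd_offset[i] <- pos
    pos <- pos + 2 + 12 * length(ents) + 4
    offs <- numeric(length(ents))
    for (j in seq_along(ents)) {
      nb <- value_nbytes(ents[[j]])
      if (nb > 4) { offs[j] <- pos; pos <- pos + nb + (nb %% 2) }
    }
    ext_offset[[i]] <- offs
  }
  data_start <- pos

  # assign tile offsets in disk order and patch tag 324
  for (i in seq_len(n)) {
    sizes <- vapply(enc[[i]]$tiles, length, numeric(1))
    offs <- pos + cumsum(c(0, sizes[-length(sizes)]))
    pos <- pos + sum(sizes)
    ents <- all_entries[[i]]
    k <- which(vapply(ents, function(e) e$tag, 0L) == 324L)
    ents[[k]]$value <- offs
    all_entries[[i]] <- ents
  }

  # serialize the front block
  front <- c(charToRaw("II"), u16le(42), u32le(ifd_offset[1]))
  for (i in seq_len(n)) {
    ents <- all_entries[[i]]
    blk <- u16le(length(ents))
    ext <- raw(0)
    for (j in seq_along(ents)) {
      ent <- ents[[j]]
      vr <- entry_value_raw(ent)
      slot <- if (length(vr) <= 4L) c(vr, raw(4L - length(vr)))
              else u32le(ext_offset[[i]][j])
      blk <- c(blk, u16le(ent$tag), u16le(ent$type), u32le(ent$count), slot)
      if (length(vr) > 4L) ext <- c(ext, vr, raw(length(vr) %% 2))
    }
    blk <- c(blk, u32le(if (i < n) ifd_offset[i + 1] else 0))
    front <- c(front, blk, ext)
  }
  stopifnot(length(front) == data_start)

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(front, con)
  for (i in seq_len(n)) for (tl in enc[[i]]$tiles) writeBin(tl, con)
  invisible(path)
}
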
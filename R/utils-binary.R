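# Low-level byte packing helpers shared by the TIFF writer/reader and the
# chunked feature store. All multi-byte integers are little-endian; values are
# carried as doubles so offsets above .Machine$integer.max survive.

u16le <- function(x) {
  x <- as.numeric(x)
  as.raw(as.vector(rbind(x %% 256, (x %/% 256) %% 256)))
}

u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(as.vector(rbind(
    x %% 256,
    (x %/% 256) %% 256,
    (x %/% 65536) %% 256,
    (x %/% 16777216) %% 256
  )))
}

# Read n unsigned 16/32-bit LE integers starting at 1-based byte position pos.
rd_u16le <- function(raw, pos, n = 1L) {
  idx <- pos + rep(seq_len(n) - 1L, each = 2L) * 2L + c(0L, 1L)
  b <- matrix(as.numeric(raw[idx]), nrow = 2L)
  b[1L, ] + 256 * b[2L, ]
}

rd_u32le <- function(raw, pos, n = 1L) {
  idx <- pos + rep(seq_len(n) - 1L, each = 4L) * 4L + 0:3
  b <- matrix(as.numeric(raw[idx]), nrow = 4L)
  b[1L, ] + 256 * b[2L, ] + 65536 * b[3L, ] + 16777216 * b[4L, ]
}

# Round to the nearest float32-representable value (via a 4-byte round trip),
# so that float32 planes round-trip bit-exactly through files.
as_float32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.double(x), raw(), size = 4L, endian = "little"),
               what = "double", n = length(x), size = 4L, endian = "little")
  dim(y) <- d
  y
}

# gzip (RFC 1952) compression of a character scalar. R's memCompress() emits a
# raw zlib stream, so compression goes through a gzfile() scratch file; the
# in-memory decompressor handles gzip headers directly.
gzip_text <- function(txt) {
  tmp <- tempfile(fileext = ".gz")
  on.exit(unlink(tmp), add = TRUE)
  con <- gzfile(tmp, "wb")
  writeBin(charToRaw(txt), con)
  close(con)
  readBin(tmp, raw(), file.size(tmp))
}

gunzip_text <- function(raw) {
  if (length(raw) == 0L) return("")
  rawToChar(memDecompress(raw, type = "gzip"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
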
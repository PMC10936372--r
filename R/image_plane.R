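#' Construct an image plane
#'
#' An `ImagePlane` is the in-memory representation of one resolution level of
#' a (possibly multi-channel) raster: an `H x W x C` array together with a
#' pixel data type and channel names. Integer types are held as R integers;
#' `float32` planes are held as doubles snapped to float32 precision so that
#' file round trips are bit-exact.
#'
#' @param pixels numeric/integer array. Accepted shapes: `H x W` (one
#'   channel) or `H x W x C`.
#' @param dtype one of `"uint8"`, `"uint16"`, `"float32"`. If missing it is
#'   inferred from the value range (integral data within 0..255 becomes
#'   `uint8`, within 0..65535 `uint16`, everything else `float32`).
#' @param channel_names character vector of length `C`. Defaults to
#'   `"ch1" ... "chC"`.
#' @return an object of class `ImagePlane`.
#' @export
image_plane <- function(pixels, dtype = NULL, channel_names = NULL) {
  if (is.null(dim(pixels))) stop("pixels must be a matrix or 3-d array")
  if (length(dim(pixels)) == 2L) dim(pixels) <- c(dim(pixels), 1L)
  if (length(dim(pixels)) != 3L) stop("pixels must be H x W x C")
  d <- dim(pixels)
  if (any(d < 1L)) stop("invalid-input: zero-sized image")

  if (is.null(dtype)) {
    if (is.integer(pixels) || all(pixels == round(pixels))) {
      rng <- range(pixels)
      dtype <- if (rng[1] >= 0 && rng[2] <= 255) "uint8"
               else if (rng[1] >= 0 && rng[2] <= 65535) "uint16"
               else "float32"
    } else dtype <- "float32"
  }
  dtype <- match.arg(dtype, c("uint8", "uint16", "float32"))
  if (dtype %in% c("uint8", "uint16")) {
    lim <- if (dtype == "uint8") 255 else 65535
    if (min(pixels) < 0 || max(pixels) > lim)
      stop("unsupported-dtype: values out of range for ", dtype)
    storage.mode(pixels) <- "integer"
  } else {
    pixels <- as_float32(pixels)
  }

  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[3]))
  if (length(channel_names) != d[3])
    stop("channel_names length must equal channel count")

  structure(
    list(pixels = pixels, dtype = dtype,
         channel_names = as.character(channel_names)),
    class = "ImagePlane"
  )
}

#' @export
dim.ImagePlane <- function(x) dim(x$pixels)

plane_width <- function(p) dim(p$pixels)[2]
plane_height <- function(p) dim(p$pixels)[1]
plane_channels <- function(p) dim(p$pixels)[3]

#' @export
print.ImagePlane <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImagePlane %d x %d, %d channel(s) [%s], dtype %s\n",
              d[2], d[1], d[3], paste(x$channel_names, collapse = ","),
              x$dtype))
  invisible(x)
}

#' Block-mean downsampling of an image plane
#'
#' Reduces an image by an integer factor: each output pixel is the arithmetic
#' mean of its `factor x factor` source block. When a dimension is not a
#' multiple of the factor, edge rows/columns are replicated to fill the last
#' block, so the output has `ceiling(input / factor)` pixels per dimension.
#' For integer dtypes the mean is rounded half-up.
#'
#' @param plane an [image_plane()].
#' @param factor integer >= 2.
#' @return an `ImagePlane` with the same dtype and channel names.
#' @export
downsample <- function(plane, factor = 2L) {
  stopifnot(inherits(plane, "ImagePlane"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 2L) stop("invalid-argument: factor must be >= 2")
  d <- dim(plane$pixels)
  integer_out <- plane$dtype %in% c("uint8", "uint16")
  ho <- ceiling(d[1] / factor); wo <- ceiling(d[2] / factor)
  # round half-up per band and keep integer dtypes integer throughout, so a
  # full-size double copy of the plane is never materialized
  out <- array(if (integer_out) 0L else 0, dim = c(ho, wo, d[3]))
  cidx <- pmin(seq_len(wo * factor), d[2])   # edge replication
  cgrp <- rep(seq_len(wo), each = factor)
  # process in output-row bands to bound transient allocations on big planes
  band <- max(1L, min(ho, 2048L %/% factor * factor))
  for (ch in seq_len(d[3])) {
    r0 <- 1L
    while (r0 <= ho) {
      r1 <- min(r0 + band - 1L, ho)
      nb <- r1 - r0 + 1L
      ridx <- pmin((r0 - 1L) * factor + seq_len(nb * factor), d[1])
      m <- plane$pixels[ridx, cidx, ch, drop = FALSE]
      dim(m) <- c(length(ridx), length(cidx))
      s <- rowsum(m, rep(seq_len(nb), each = factor), reorder = FALSE)
      s <- t(rowsum(t(s), cgrp, reorder = FALSE)) / (factor * factor)
      out[r0:r1, , ch] <- if (integer_out) as.integer(floor(s + 0.5)) else s
      r0 <- r1 + 1L
    }
  }
  image_plane(out, dtype = plane$dtype, channel_names = plane$channel_names)
}
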
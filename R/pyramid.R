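#' Number of pyramid levels for an image
#'
#' A pyramid has enough levels that the coarsest one fits within a single
#' tile along its longest side: `max(1, ceiling(log_f(max(W, H) / tile_size))
#' + 1)` levels for downsample factor `f`.
#'
#' @param width,height full-resolution image dimensions in pixels.
#' @param tile_size tile edge in pixels.
#' @param downsample_factor integer ratio between consecutive levels.
#' @return integer level count.
#' @export
n_pyramid_levels <- function(width, height, tile_size = 512L,
                             downsample_factor = 2L) {
  m <- max(width, height) / tile_size
  if (m <= 1) return(1L)
  # guard against log() landing a hair above an integer
  k <- log(m) / log(downsample_factor)
  as.integer(max(1, ceiling(k - 1e-9)) + 1L)
}

#' Build a multiscale tile pyramid
#'
#' Constructs the full resolution-level stack for an image: level 0 is the
#' coarsest, the last level is the input itself (bit-identical), and each
#' level is the block-mean [downsample()] of the next finer one. Levels are
#' added until the coarsest fits in one tile along its longest side.
#'
#' @param image an [image_plane()].
#' @param tile_size tile edge in pixels; one of 256, 512, 1024.
#' @param downsample_factor integer >= 2; ratio between consecutive levels.
#' @return an object of class `TilePyramid`: list with `levels` (coarsest
#'   first), `tile_size`, `downsample_factor`.
#' @export
build_pyramid <- function(image, tile_size = 512L, downsample_factor = 2L) {
  stopifnot(inherits(image, "ImagePlane"))
  tile_size <- as.integer(tile_size)
  if (!tile_size %in% c(256L, 512L, 1024L))
    stop("invalid-argument: tile_size must be one of 256, 512, 1024")
  downsample_factor <- as.integer(downsample_factor)
  if (downsample_factor < 2L)
    stop("invalid-argument: downsample_factor must be >= 2")

  n <- n_pyramid_levels(plane_width(image), plane_height(image),
                        tile_size, downsample_factor)
  levels <- vector("list", n)
  levels[[n]] <- image
  if (n > 1L) for (k in (n - 1L):1L)
    levels[[k]] <- downsample(levels[[k + 1L]], downsample_factor)

  structure(
    list(levels = levels, tile_size = tile_size,
         downsample_factor = downsample_factor),
    class = "TilePyramid"
  )
}

#' @export
print.TilePyramid <- function(x, ...) {
  cat(sprintf("TilePyramid: %d level(s), tile %d px, factor %d\n",
              length(x$levels), x$tile_size, x$downsample_factor))
  for (k in seq_along(x$levels)) {
    d <- dim(x$levels[[k]]$pixels)
    cat(sprintf("  level %d (%s): %d x %d\n", k - 1L,
                if (k == length(x$levels)) "finest" else "overview",
                d[2], d[1]))
  }
  invisible(x)
}

#' Pyramid geometry without pixel data
#'
#' Small descriptor used by [tiles_for_viewport()] and by readers that only
#' know a file header: full-resolution dims plus tiling parameters.
#'
#' @param width,height full-resolution dims in px.
#' @param tile_size,downsample_factor as in [build_pyramid()].
#' @param n_levels level count; computed when `NULL`.
#' @export
pyramid_meta <- function(width, height, tile_size = 512L,
                         downsample_factor = 2L, n_levels = NULL) {
  n <- n_levels %||%
    n_pyramid_levels(width, height, tile_size, downsample_factor)
  list(width = as.numeric(width), height = as.numeric(height),
       tile_size = as.integer(tile_size),
       downsample_factor = as.integer(downsample_factor),
       n_levels = as.integer(n))
}

# dims of API level k (0 = coarsest); nested ceiling division composes,
# so level k has ceiling(full / f^(n-1-k)) pixels per dimension.
level_dims <- function(meta, level) {
  s <- meta$downsample_factor^(meta$n_levels - 1L - level)
  c(width = ceiling(meta$width / s), height = ceiling(meta$height / s))
}

level_scale <- function(meta, level) {
  meta$downsample_factor^(meta$n_levels - 1L - level)
}

#' Tiles intersecting a viewport
#'
#' Returns the addresses of every tile at `zoom_level` whose footprint,
#' scaled to full-resolution pixel coordinates, intersects the viewport
#' rectangle. This is the selection a lazy viewer performs when panning or
#' zooming: only these tiles need to be fetched.
#'
#' Coordinates are 0-based with the origin at the top-left, x growing right
#' and y growing down; the viewport is half-open (`[xmin, xmax)`), so a
#' one-pixel viewport at (0,0) is `c(0, 0, 1, 1)`.
#'
#' @param meta a [pyramid_meta()] (or a `TilePyramid`).
#' @param viewport numeric `c(xmin, ymin, xmax, ymax)` in full-resolution px.
#' @param zoom_level level index, 0 = coarsest.
#' @return data.frame with columns `level`, `tile_x`, `tile_y` in row-major
#'   order (by `tile_y`, then `tile_x`); zero rows when nothing intersects.
#' @export
tiles_for_viewport <- function(meta, viewport, zoom_level) {
  if (inherits(meta, "TilePyramid")) {
    finest <- meta$levels[[length(meta$levels)]]
    meta <- pyramid_meta(plane_width(finest), plane_height(finest),
                         meta$tile_size, meta$downsample_factor,
                         n_levels = length(meta$levels))
  }
  zoom_level <- as.integer(zoom_level)
  if (zoom_level < 0L || zoom_level >= meta$n_levels)
    stop("invalid-argument: zoom_level out of range")
  stopifnot(length(viewport) == 4L)
  v <- as.numeric(viewport)
  if (v[3] <= v[1] || v[4] <= v[2])
    stop("invalid-argument: viewport must have positive extent")

  sc <- level_scale(meta, zoom_level)
  ld <- level_dims(meta, zoom_level)
  ts <- meta$tile_size
  ntx <- ceiling(ld[["width"]] / ts)
  nty <- ceiling(ld[["height"]] / ts)

  # clip viewport to image bounds, then map to tile index ranges
  x0 <- max(v[1], 0); y0 <- max(v[2], 0)
  x1 <- min(v[3], meta$width); y1 <- min(v[4], meta$height)
  empty <- data.frame(level = integer(), tile_x = integer(),
                      tile_y = integer())
  if (x1 <= x0 || y1 <= y0) return(empty)

  tx0 <- max(0L, floor(x0 / (ts * sc)))
  tx1 <- min(ntx - 1L, ceiling(x1 / (ts * sc)) - 1L)
  ty0 <- max(0L, floor(y0 / (ts * sc)))
  ty1 <- min(nty - 1L, ceiling(y1 / (ts * sc)) - 1L)
  if (tx1 < tx0 || ty1 < ty0) return(empty)

  g <- expand.grid(tile_x = tx0:tx1, tile_y = ty0:ty1)  # row-major
  data.frame(level = zoom_level, tile_x = as.integer(g$tile_x),
             tile_y = as.integer(g$tile_y))
}
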
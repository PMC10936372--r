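# Vizgen MERFISH release files -> Sample folder. Cell centroids are given in
# microns; the instrument ships a 3x3 micron-to-mosaic-pixel affine, and the
# first z-stack of the mosaic serves as the viewing background.

#' Apply a 3x3 affine transform to 2-D points
#'
#' Homogeneous multiply: `out_i = (M %*% c(x_i, y_i, 1))[1:2]`. The third
#' row is expected to be (0, 0, 1); the matrix must be invertible.
#'
#' @param points n x 2 matrix (or data.frame) of (x, y).
#' @param matrix 3 x 3 affine.
#' @return n x 2 matrix of transformed points.
#' @export
apply_affine <- function(points, matrix) {
  m <- as.matrix(matrix)
  stopifnot(all(dim(m) == c(3L, 3L)))
  if (abs(det(m)) < .Machine$double.eps * 100)
    stop("invalid-transform: singular affine matrix")
  p <- as.matrix(points)
  stopifnot(ncol(p) == 2L)
  if (any(!is.finite(p))) stop("invalid-input: non-finite point coordinates")
  out <- cbind(p, 1) %*% t(m)
  out[, 1:2, drop = FALSE] / out[, 3]
}

#' Read Vizgen MERFISH release files
#'
#' @param cells path to `cell_by_gene.csv` (first column: cell id, then one
#'   column per gene).
#' @param meta path to `cell_metadata.csv` with cell ids and `center_x`,
#'   `center_y` centroid columns in microns.
#' @param transform path to the 3x3 micron-to-mosaic-pixel transform CSV.
#' @param image path to the mosaic TIFF (multi-page: one page per z-plane),
#'   or an [image_plane()] already holding the background.
#' @param z_index which z-plane is the background; default 0 (the first).
#' @return an object of class `MerfishRun`.
#' @export
read_merfish_run <- function(cells, meta, transform, image, z_index = 0L) {
  cbg <- utils::read.csv(cells, check.names = FALSE)
  cell_ids <- as.character(cbg[[1]])
  counts <- as.matrix(cbg[, -1, drop = FALSE])
  rownames(counts) <- cell_ids

  md <- utils::read.csv(meta, check.names = FALSE)
  id_col <- if ("cell" %in% names(md)) "cell" else names(md)[1]
  if (!all(c("center_x", "center_y") %in% names(md)))
    stop("invalid-input: cell metadata needs center_x, center_y columns")
  md_ids <- as.character(md[[id_col]])

  aff <- as.matrix(utils::read.csv(transform, header = FALSE))
  if (!all(dim(aff) == c(3L, 3L)))
    stop("invalid-input: transform must be a 3x3 matrix")
  if (abs(det(aff)) < .Machine$double.eps * 100)
    stop("invalid-spec: singular affine transform")

  if (!inherits(image, "ImagePlane")) {
    # mosaic pages are z-planes; the background is one chosen plane
    image <- read_tiff_plane(image, page = z_index + 1L,
                             channel_names = "mosaic")
  }

  structure(list(counts = counts, cell_ids = cell_ids,
                 gene_names = colnames(counts),
                 metadata = md, metadata_ids = md_ids,
                 affine = unname(aff), mosaic = image,
                 z_index = as.integer(z_index)),
            class = "MerfishRun")
}

#' @export
print.MerfishRun <- function(x, ...) {
  cat(sprintf("MerfishRun: %d cell(s) x %d gene(s), mosaic %d x %d (z %d)\n",
              nrow(x$counts), ncol(x$counts), plane_width(x$mosaic),
              plane_height(x$mosaic), x$z_index))
  invisible(x)
}

#' Convert a MERFISH run into a Sample folder
#'
#' Builds a sample from Vizgen release files: the first-z mosaic as the COG
#' background, a `cells` point overlay at the affine-transformed centroid of
#' every cell, and per-cell transcript counts as a chunked feature store
#' (left untransformed by default; `log1p = TRUE` applies the natural-log
#' transform).
#'
#' @param run a [read_merfish_run()] result.
#' @param out_dir output sample folder.
#' @param log1p log-transform the counts (default `FALSE`).
#' @param compression COG compression (mosaics are 16-bit: deflate).
#' @param tile_size COG tile edge.
#' @param sample_name manifest name.
#' @return `out_dir`, invisibly.
#' @export
convert_merfish <- function(run, out_dir, log1p = FALSE,
                            compression = "deflate", tile_size = 512L,
                            sample_name = basename(out_dir)) {
  stopifnot(inherits(run, "MerfishRun"))
  missing <- setdiff(run$cell_ids, run$metadata_ids)
  if (length(missing) > 0L)
    stop("consistency error: ", length(missing),
         " cell(s) in cell_by_gene have no metadata (e.g. ", missing[1], ")")
  md <- run$metadata[match(run$cell_ids, run$metadata_ids), ]

  centroids_um <- cbind(md$center_x, md$center_y)
  centroids_px <- apply_affine(centroids_um, run$affine)

  # physical scale of a mosaic pixel, from the affine's micron->px scale
  px_per_um <- sqrt(abs(det(run$affine[1:2, 1:2])))
  m_per_px <- 1e-6 / px_per_um

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pyr <- build_pyramid(run$mosaic, tile_size = tile_size)
  write_cog(pyr, file.path(out_dir, "image.tif"), compression = compression)

  cells <- data.frame(id = run$cell_ids,
                      x = centroids_px[, 1] * m_per_px,
                      y = centroids_px[, 2] * m_per_px)
  write_overlay_csv(cells, file.path(out_dir, "cells.csv"))

  fm <- feature_matrix(run$counts)
  if (log1p) fm <- log_transform(fm)
  write_store(fm, file.path(out_dir, "genes.scf"))

  md_out <- sample_metadata(
    sample_name,
    images = list(sample_image("image.tif", run$mosaic$channel_names,
                               m_per_px)),
    overlays = list(sample_overlay("cells", "cells.csv", "point")),
    feature_groups = list(sample_feature_group("genes", "genes.scf", "cells",
                                               "chunked", "quantitative"))
  )
  write_sample(md_out, out_dir)
  invisible(out_dir)
}
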
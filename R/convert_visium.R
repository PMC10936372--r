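# 10x Visium (Space Ranger filtered output) -> Sample folder. The physical
# scale comes from the one constant the platform fixes: a capture spot is
# 55 um across, and Space Ranger reports its full-resolution pixel diameter
# as spot_diameter_fullres, so m_per_px = 55e-6 / spot_diameter_fullres.

VISIUM_SPOT_DIAMETER_M <- 55e-6

#' Gaussian pre-filter for full-resolution images
#'
#' Per-channel convolution with a normalized Gaussian kernel (sigma =
#' `radius`, truncated at 3 sigma, edge-replicated borders), applied before
#' pyramid building to suppress scanner artifacts. `radius = 0` is the
#' identity. Separable implementation (two 1-D passes).
#'
#' @param image an [image_plane()].
#' @param radius Gaussian sigma in pixels; default 4.
#' @return a filtered `ImagePlane` of the same dtype.
#' @export
gaussian_prefilter <- function(image, radius = 4) {
  stopifnot(inherits(image, "ImagePlane"))
  if (radius < 0) stop("invalid-argument: radius must be >= 0")
  if (radius == 0) return(image)
  h <- ceiling(3 * radius)
  w <- stats::dnorm(-h:h, sd = radius)
  w <- w / sum(w)
  d <- dim(image$pixels)
  out <- array(0, dim = d)
  conv1d_rows <- function(m) {
    # edge-replicated 1-D convolution down the rows of m
    H <- nrow(m)
    mp <- m[pmin(pmax(seq(1 - h, H + h), 1L), H), , drop = FALSE]
    acc <- matrix(0, H, ncol(m))
    for (k in 0:(2 * h)) acc <- acc + w[k + 1] * mp[k + seq_len(H), ,
                                                    drop = FALSE]
    acc
  }
  for (ch in seq_len(d[3])) {
    m <- image$pixels[, , ch]
    dim(m) <- d[1:2]
    m <- conv1d_rows(m)
    m <- t(conv1d_rows(t(m)))
    out[, , ch] <- m
  }
  if (image$dtype %in% c("uint8", "uint16")) out <- floor(out + 0.5)
  image_plane(out, dtype = image$dtype, channel_names = image$channel_names)
}

find_first <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

read_tsv_maybe_gz <- function(path, ...) {
  utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE, ...)
}

#' Read a Space Ranger filtered output folder
#'
#' Expects the standard filtered layout: Matrix Market counts plus
#' `barcodes.tsv` / `features.tsv` (optionally gzipped, at the folder root
#' or under `filtered_feature_bc_matrix/`), a tissue positions CSV (both
#' dialects: headerless `tissue_positions_list.csv` and headered
#' `tissue_positions.csv`, at the root or under `spatial/`), and
#' `scalefactors_json.json`. The full-resolution image is a separate TIFF.
#'
#' @param dir Space Ranger output folder.
#' @param image path to the full-resolution TIFF (H&E RGB or multichannel
#'   IF), or an [image_plane()].
#' @param channel_names optional channel names for the image.
#' @return an object of class `VisiumRun`.
#' @export
read_visium_run <- function(dir, image, channel_names = NULL) {
  mdirs <- c(".", "filtered_feature_bc_matrix", "spatial")
  mtx <- find_first(dir, as.vector(outer(
    mdirs, c("matrix.mtx", "matrix.mtx.gz"), file.path)))
  bc <- find_first(dir, as.vector(outer(
    mdirs, c("barcodes.tsv", "barcodes.tsv.gz"), file.path)))
  ft <- find_first(dir, as.vector(outer(
    mdirs, c("features.tsv", "features.tsv.gz", "genes.tsv"), file.path)))
  pos <- find_first(dir, as.vector(outer(
    mdirs, c("tissue_positions_list.csv", "tissue_positions.csv"),
    file.path)))
  sf <- find_first(dir, as.vector(outer(
    mdirs, "scalefactors_json.json", file.path)))
  if (is.null(mtx) || is.null(bc) || is.null(ft))
    stop("invalid-input: no filtered matrix (matrix.mtx + barcodes + ",
         "features) found under ", dir)
  if (is.null(pos)) stop("invalid-input: no tissue positions CSV under ", dir)
  if (is.null(sf)) stop("invalid-input: no scalefactors_json.json under ", dir)

  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  barcodes <- read_tsv_maybe_gz(bc)[[1]]
  feats <- read_tsv_maybe_gz(ft)
  gene_names <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  gene_names <- make.unique(as.character(gene_names))
  if (nrow(counts) != length(gene_names) || ncol(counts) != length(barcodes))
    stop("invalid-input: matrix dims do not match barcodes/features tables")
  dimnames(counts) <- list(gene_names, barcodes)

  # positions: 6 columns, with or without a header line
  first <- readLines(pos, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  posdf <- utils::read.csv(pos, header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(posdf) < 6) stop("invalid-input: tissue positions CSV needs 6 ",
                            "columns")
  names(posdf)[1:6] <- c("barcode", "in_tissue", "array_row", "array_col",
                         "pxl_row_in_fullres", "pxl_col_in_fullres")

  scale_factors <- jsonlite::fromJSON(sf)
  if (is.null(scale_factors$spot_diameter_fullres) ||
      scale_factors$spot_diameter_fullres <= 0)
    stop("invalid-input: spot_diameter_fullres missing or non-positive")

  if (!inherits(image, "ImagePlane")) {
    image <- read_tiff_plane(image, channel_names = channel_names)
  } else if (!is.null(channel_names)) {
    image$channel_names <- channel_names
  }

  structure(list(counts = counts, barcodes = barcodes,
                 gene_names = gene_names, positions = posdf,
                 scale_factors = scale_factors, image = image),
            class = "VisiumRun")
}

#' @export
print.VisiumRun <- function(x, ...) {
  cat(sprintf("VisiumRun: %d gene(s) x %d barcode(s), image %d x %d\n",
              nrow(x$counts), ncol(x$counts),
              plane_width(x$image), plane_height(x$image)))
  invisible(x)
}

#' Convert a Visium run into a Sample folder
#'
#' Builds the three components of a sample from Space Ranger filtered
#' output: (a) a COG pyramid of the (optionally Gaussian-filtered)
#' full-resolution image; (b) a `spots` overlay of 55 um circles at each
#' in-tissue barcode's full-resolution position, in physical coordinates
#' with `m_per_px = 55e-6 / spot_diameter_fullres`; (c) a chunked feature
#' store of `log(1 + count)` per gene per spot. Visium-SPG runs (multiplex
#' IF instead of H&E) go through the same path with a multichannel image.
#'
#' @param run a [read_visium_run()] result.
#' @param out_dir output sample folder.
#' @param gaussian_radius pre-filter sigma in px (0 disables); default 4.
#' @param compression COG compression; `"auto"` picks JPEG for 8-bit 1/3
#'   channel images and deflate otherwise.
#' @param quality JPEG quality.
#' @param log1p apply the natural-log transform to counts (default `TRUE`).
#' @param tile_size COG tile edge.
#' @param sample_name manifest name; defaults to the folder's basename.
#' @return `out_dir`, invisibly.
#' @export
convert_visium <- function(run, out_dir, gaussian_radius = 4,
                           compression = c("auto", "jpeg", "deflate", "none"),
                           quality = 90, log1p = TRUE, tile_size = 512L,
                           sample_name = basename(out_dir)) {
  stopifnot(inherits(run, "VisiumRun"))
  compression <- match.arg(compression)
  if (compression == "auto") {
    ok_jpeg <- run$image$dtype == "uint8" &&
      plane_channels(run$image) %in% c(1L, 3L)
    compression <- if (ok_jpeg) "jpeg" else "deflate"
  }

  pos <- run$positions[run$positions$in_tissue == 1, ]
  missing <- setdiff(run$barcodes, pos$barcode)
  if (length(missing) > 0L)
    stop("consistency error: ", length(missing),
         " barcode(s) in the matrix have no tissue position (e.g. ",
         missing[1], ")")
  pos <- pos[match(run$barcodes, pos$barcode), ]

  m_per_px <- VISIUM_SPOT_DIAMETER_M / run$scale_factors$spot_diameter_fullres

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  img <- if (gaussian_radius > 0)
    gaussian_prefilter(run$image, gaussian_radius) else run$image
  pyr <- build_pyramid(img, tile_size = tile_size)
  write_cog(pyr, file.path(out_dir, "image.tif"), compression = compression,
            quality = quality)

  spots <- data.frame(id = run$barcodes,
                      x = pos$pxl_col_in_fullres * m_per_px,
                      y = pos$pxl_row_in_fullres * m_per_px)
  write_overlay_csv(spots, file.path(out_dir, "spots.csv"))

  fm <- feature_matrix(as.matrix(Matrix::t(run$counts)))
  if (log1p) fm <- log_transform(fm)
  write_store(fm, file.path(out_dir, "genes.scf"))

  md <- sample_metadata(
    sample_name,
    images = list(sample_image("image.tif", run$image$channel_names,
                               m_per_px)),
    overlays = list(sample_overlay("spots", "spots.csv", "circle",
                                   diameter = VISIUM_SPOT_DIAMETER_M)),
    feature_groups = list(sample_feature_group("genes", "genes.scf", "spots",
                                               "chunked", "quantitative"))
  )
  write_sample(md, out_dir)
  invisible(out_dir)
}

#' Read a TIFF file as an image plane
#'
#' Thin wrapper over `tiff::readTIFF` that restores integer intensities and
#' stacks multi-page grayscale TIFFs as channels.
#'
#' @param path TIFF file.
#' @param channel_names optional channel names.
#' @param page for multi-page files, which page(s) to use (default: all
#'   pages as channels when grayscale, first page otherwise).
#' @export
read_tiff_plane <- function(path, channel_names = NULL, page = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.null(page)) pages <- pages[page]
  to3d <- function(p) { if (length(dim(p)) == 2L) dim(p) <- c(dim(p), 1L); p }
  arr <- if (length(pages) > 1L &&
             all(vapply(pages, function(p) length(dim(p)) == 2L, TRUE))) {
    ar <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
    for (i in seq_along(pages)) ar[, , i] <- pages[[i]]
    ar
  } else to3d(pages[[1]])
  image_plane(arr, channel_names = channel_names)
}
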
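# Deterministic synthetic inputs for every supported format, so conversions
# are testable end to end with no downloads. Each generator records its
# planted ground truth (pixel content, counts, positions) alongside the
# files, and the same seed always yields byte-identical output.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

rand_barcodes <- function(n) {
  paste0(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 16, replace = TRUE), collapse = ""),
    ""), "-1")
}

# seeded negative-binomial counts thinned to the requested sparsity
nb_counts <- function(n_row, n_col, sparsity, mean = 2, dispersion = 0.5) {
  n <- n_row * n_col
  mask <- stats::rbinom(n, 1L, sparsity)
  vals <- 1L + stats::rnbinom(n, size = dispersion, mu = mean)
  matrix(mask * vals, n_row, n_col)
}

#' Synthetic image fixture
#'
#' Deterministic image content: a coarse diagonal gradient, seeded uniform
#' noise, and a handful of bright impulse markers at recorded positions (for
#' filter-response tests). Generated column-block-wise so very large presets
#' (e.g. 20,480 square) stay within a bounded memory footprint.
#'
#' @param seed RNG seed; same seed, same bytes.
#' @param width,height image size in px.
#' @param channels channel count (uint8 output).
#' @param n_impulses bright markers to plant (0 to disable).
#' @param path TIFF output path, or `NULL` to skip writing the file and
#'   return only the in-memory plane.
#' @return list with `plane` ([image_plane()]), `path` (or `NULL`),
#'   `impulses` (data.frame x, y, recorded 0-based), `seed`.
#' @export
make_image_fixture <- function(seed = 1L, width = 512L, height = 512L,
                               channels = 1L, n_impulses = 3L, path = NULL) {
  stopifnot(width >= 1, height >= 1, channels >= 1)
  with_seed(seed, {
    px <- array(0L, dim = c(height, width, channels))
    block <- 2048L
    for (ch in seq_len(channels)) {
      c0 <- 1L
      while (c0 <= width) {
        c1 <- min(c0 + block - 1L, width)
        nc <- c1 - c0 + 1L
        grad <- (matrix(rep((c0:c1 - 1L) %/% 8L, each = height),
                        height, nc) +
                 matrix(rep((seq_len(height) - 1L) %/% 8L, nc),
                        height, nc) + 16L * (ch - 1L)) %% 192L
        noise <- matrix(sample.int(64L, height * nc, replace = TRUE) - 1L,
                        height, nc)
        px[, c0:c1, ch] <- grad + noise
        c0 <- c1 + 1L
      }
    }
    impulses <- data.frame(x = integer(), y = integer())
    if (n_impulses > 0L) {
      ix <- sample.int(width, n_impulses)
      iy <- sample.int(height, n_impulses)
      for (k in seq_len(n_impulses)) px[iy[k], ix[k], ] <- 255L
      impulses <- data.frame(x = ix - 1L, y = iy - 1L)
    }
    plane <- image_plane(px, dtype = "uint8",
                         channel_names = paste0("ch", seq_len(channels)))
    if (!is.null(path)) {
      img <- plane$pixels / 255
      if (channels == 1L) dim(img) <- dim(img)[1:2]
      tiff::writeTIFF(img, path, bits.per.sample = 8L)
    }
    list(plane = plane, path = path, impulses = impulses, seed = seed)
  })
}

hex_grid <- function(n, spacing, width, height, margin) {
  pts <- NULL
  row <- 0L
  y <- margin
  dy <- spacing * sqrt(3) / 2
  while (y <= height - margin) {
    x0 <- margin + if (row %% 2L == 1L) spacing / 2 else 0
    xs <- seq(x0, width - margin, by = spacing)
    if (length(xs) > 0L)
      pts <- rbind(pts, cbind(x = xs, y = y, array_row = row,
                              array_col = seq_along(xs) - 1L))
    y <- y + dy
    row <- row + 1L
  }
  if (is.null(pts) || nrow(pts) < n)
    stop("invalid-spec: grid capacity ", if (is.null(pts)) 0 else nrow(pts),
         " < n_spots ", n)
  pts[seq_len(n), , drop = FALSE]
}

#' Synthetic Space Ranger-style Visium folder
#'
#' Emits a filtered-output folder (Matrix Market counts, barcodes/features
#' tables, tissue positions CSV in either dialect, scale-factors JSON) plus
#' a full-resolution RGB TIFF, with spots on a hexagonal-like grid spaced at
#' twice the spot diameter. Counts are seeded negative-binomial draws
#' (mean 2, dispersion 0.5) thinned to the requested sparsity. A few
#' out-of-tissue position rows are planted to exercise the in-tissue filter.
#'
#' @param seed RNG seed.
#' @param dir output folder (created).
#' @param n_spots,n_genes matrix size.
#' @param sparsity fraction of nonzero entries.
#' @param spot_diameter_fullres spot diameter in full-res px.
#' @param image_size `c(width, height)` of the TIFF.
#' @param channels 3 for H&E-like RGB; more for an IF-like stack.
#' @param positions_header write the headered `tissue_positions.csv`
#'   dialect instead of the headerless `tissue_positions_list.csv`.
#' @return list with `dir`, `image_path`, and `truth` (planted counts
#'   matrix spots x genes, barcodes, gene names, positions in px).
#' @export
make_visium_fixture <- function(seed = 1L, dir = tempfile("visium"),
                                n_spots = 24L, n_genes = 40L,
                                sparsity = 0.2, spot_diameter_fullres = 80,
                                image_size = c(1024L, 1024L), channels = 3L,
                                positions_header = FALSE) {
  with_seed(seed, {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    spacing <- 2 * spot_diameter_fullres
    grid <- hex_grid(n_spots, spacing, image_size[1], image_size[2],
                     margin = spot_diameter_fullres)
    barcodes <- rand_barcodes(n_spots)
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    ens <- sprintf("ENSG%011d", seq_len(n_genes))

    counts <- nb_counts(n_genes, n_spots, sparsity)  # genes x spots
    dimnames(counts) <- list(genes, barcodes)
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(barcodes, file.path(dir, "barcodes.tsv"))
    utils::write.table(data.frame(ens, genes, "Gene Expression"),
                       file.path(dir, "features.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)

    pos <- data.frame(
      barcode = barcodes, in_tissue = 1L,
      array_row = as.integer(grid[, "array_row"]),
      array_col = as.integer(grid[, "array_col"]),
      pxl_row_in_fullres = round(grid[, "y"]),
      pxl_col_in_fullres = round(grid[, "x"])
    )
    # planted out-of-tissue rows, absent from the filtered matrix
    extra <- data.frame(barcode = rand_barcodes(2L), in_tissue = 0L,
                        array_row = 99L, array_col = 0:1,
                        pxl_row_in_fullres = c(1, 2),
                        pxl_col_in_fullres = c(1, 2))
    posall <- rbind(pos, extra)
    pos_path <- file.path(dir, if (positions_header) "tissue_positions.csv"
                          else "tissue_positions_list.csv")
    utils::write.table(posall, pos_path, sep = ",", row.names = FALSE,
                       col.names = positions_header, quote = FALSE)

    jsonlite::write_json(list(
      spot_diameter_fullres = spot_diameter_fullres,
      tissue_hires_scalef = 0.1, tissue_lowres_scalef = 0.03,
      fiducial_diameter_fullres = spot_diameter_fullres * 1.6
    ), file.path(dir, "scalefactors_json.json"), auto_unbox = TRUE,
    digits = NA)

    img <- make_image_fixture(seed + 1000L, image_size[1], image_size[2],
                              channels, n_impulses = 0L,
                              path = file.path(dir, "image.tif"))

    list(dir = dir, image_path = img$path,
         truth = list(counts = t(counts),          # spots x genes
                      barcodes = barcodes, gene_names = genes,
                      positions_px = data.frame(
                        barcode = barcodes,
                        x = pos$pxl_col_in_fullres,
                        y = pos$pxl_row_in_fullres),
                      spot_diameter_fullres = spot_diameter_fullres,
                      image = img$plane))
  })
}

#' Synthetic Vizgen MERFISH-style release files
#'
#' Emits `cell_by_gene.csv`, `cell_metadata.csv` (micron centroids), the 3x3
#' micron-to-mosaic-pixel transform CSV, and a multi-z uint16 mosaic TIFF
#' whose first plane is the intended background (planes are tagged with
#' distinct intensity offsets so the chosen z is verifiable).
#'
#' @param seed RNG seed.
#' @param dir output folder.
#' @param n_cells,n_genes matrix size.
#' @param sparsity fraction of nonzero counts.
#' @param image_size mosaic `c(width, height)` px.
#' @param n_z number of z-planes in the mosaic.
#' @param affine 3x3 micron-to-mosaic-pixel matrix; the default scales by
#'   9.2593 px/um (a 0.108 um mosaic pixel) with a small translation.
#' @return list with `paths` and `truth` (counts cells x genes, micron
#'   centroids, affine, expected pixel centroids, z0 plane).
#' @export
make_merfish_fixture <- function(seed = 1L, dir = tempfile("merfish"),
                                 n_cells = 200L, n_genes = 30L,
                                 sparsity = 0.15,
                                 image_size = c(512L, 512L), n_z = 3L,
                                 affine = NULL) {
  if (is.null(affine))
    affine <- matrix(c(9.2593, 0, 12.5,
                       0, 9.2593, 7.25,
                       0, 0, 1), 3L, 3L, byrow = TRUE)
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("invalid-spec: singular affine")
  with_seed(seed, {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    # place cells in micron space so their pixel images land inside bounds
    inv <- solve(affine)
    corner_px <- cbind(c(10, 10), c(image_size[1] - 10, image_size[2] - 10))
    corner_um <- apply_affine(t(corner_px), inv)
    cx <- stats::runif(n_cells, min(corner_um[, 1]), max(corner_um[, 1]))
    cy <- stats::runif(n_cells, min(corner_um[, 2]), max(corner_um[, 2]))
    cell_ids <- sprintf("cell_%04d", seq_len(n_cells))
    genes <- sprintf("Blank-%02d", seq_len(n_genes))
    genes[seq_len(ceiling(n_genes / 2))] <-
      sprintf("Gene%02d", seq_len(ceiling(n_genes / 2)))

    counts <- t(nb_counts(n_genes, n_cells, sparsity))  # cells x genes
    dimnames(counts) <- list(cell_ids, genes)
    cbg <- data.frame(cell = cell_ids, counts, check.names = FALSE)
    utils::write.csv(cbg, file.path(dir, "cell_by_gene.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(cell = cell_ids, fov = 0L,
                                center_x = cx, center_y = cy),
                     file.path(dir, "cell_metadata.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.table(affine, file.path(dir, "transform.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)

    planes <- vector("list", n_z)
    for (z in seq_len(n_z)) {
      base <- make_image_fixture(seed + z, image_size[1], image_size[2],
                                 1L, n_impulses = 0L)$plane$pixels
      m <- (base[, , 1] + 1000L * (z - 1L)) * 16L   # distinct per z
      planes[[z]] <- m / 65535
    }
    tiff::writeTIFF(planes, file.path(dir, "mosaic.tif"),
                    bits.per.sample = 16L)

    z0 <- image_plane(round(planes[[1]] * 65535), dtype = "uint16",
                      channel_names = "mosaic")
    list(paths = list(dir = dir,
                      cells = file.path(dir, "cell_by_gene.csv"),
                      meta = file.path(dir, "cell_metadata.csv"),
                      transform = file.path(dir, "transform.csv"),
                      image = file.path(dir, "mosaic.tif")),
         truth = list(counts = counts, cell_ids = cell_ids,
                      gene_names = genes,
                      centroids_um = cbind(x = cx, y = cy),
                      centroids_px = apply_affine(cbind(cx, cy), affine),
                      affine = affine, z0 = z0))
  })
}
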
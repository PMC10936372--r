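test_that("gaussian prefilter: identity at radius 0, flat on constants", {
  expect_equal(eval(formals(gaussian_prefilter)$radius), 4)
  pl <- rand_plane(71, 40, 40, 2L)
  expect_identical(gaussian_prefilter(pl, 0)$pixels, pl$pixels)
  const <- image_plane(array(123L, c(30, 30, 1)), "uint8")
  expect_identical(gaussian_prefilter(const, 4)$pixels, const$pixels)
  expect_error(gaussian_prefilter(pl, -1), "invalid-argument")
})

test_that("impulse response equals the truncated normalized gaussian kernel", {
  z <- matrix(0, 33, 33); z[17, 17] <- 1
  pl <- image_plane(z, dtype = "float32")
  got <- gaussian_prefilter(pl, 4)$pixels[, , 1]
  h <- ceiling(3 * 4)
  w1 <- dnorm(-h:h, sd = 4); w1 <- w1 / sum(w1)
  kern <- outer(w1, w1)
  want <- matrix(0, 33, 33)
  want[17 + (-h:h), 17 + (-h:h)] <- kern
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("affine transforms match the per-point homogeneous multiply", {
  id <- diag(3)
  pts <- cbind(runif(5), runif(5))
  expect_equal(apply_affine(pts, id), pts)
  tr <- matrix(c(1, 0, 10, 0, 1, -5, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(apply_affine(cbind(0, 0), tr), cbind(10, -5))
  set.seed(72)
  m <- matrix(c(runif(6, -2, 2), 0, 0, 1), 3, 3, byrow = TRUE)
  pts <- cbind(runif(100, -50, 50), runif(100, -50, 50))
  got <- apply_affine(pts, m)
  for (i in 1:100) {
    v <- m %*% c(pts[i, ], 1)
    expect_equal(unname(got[i, ]), unname(v[1:2]), tolerance = 1e-12)
  }
  expect_error(apply_affine(pts, matrix(0, 3, 3)), "invalid-transform")
})

test_that("visium conversion plants 55 um circles at the right scale", {
  vf <- make_visium_fixture(seed = 73, dir = tempfile(), n_spots = 18L,
                            spot_diameter_fullres = 100)
  run <- read_visium_run(vf$dir, vf$image_path)
  out <- withr::local_tempdir()
  convert_visium(run, out, compression = "deflate")
  md <- read_sample(out)
  ov <- md$overlays[[1]]
  expect_equal(ov$name, "spots")
  expect_equal(ov$shape, "circle")
  expect_equal(ov$diameter, 55e-6)
  expect_equal(md$images[[1]]$m_per_px, 55e-6 / 100)  # 5.5e-7 m per px
  expect_length(validate_sample(out)$errors, 0L)
})

test_that("visium features and positions survive conversion exactly", {
  vf <- make_visium_fixture(seed = 74, dir = tempfile(), n_spots = 20,
                            n_genes = 30)
  run <- read_visium_run(vf$dir, vf$image_path)
  out <- withr::local_tempdir()
  convert_visium(run, out, compression = "deflate")
  store <- file.path(out, "genes.scf")
  hdr <- read_store_header(store)
  for (g in vf$truth$gene_names) {
    expect_identical(read_feature(store, g, header = hdr),
                     unname(f32(log1p(vf$truth$counts[, g]))),
                     info = g)
  }
  md <- read_sample(out)
  mpp <- md$images[[1]]$m_per_px
  ov <- read_overlay_csv(file.path(out, "spots.csv"))
  expect_equal(ov$id, vf$truth$barcodes)
  expect_lt(max(abs(ov$x / mpp - vf$truth$positions_px$x)), 1e-6)
  expect_lt(max(abs(ov$y / mpp - vf$truth$positions_px$y)), 1e-6)
  # an all-zero gene reads back as a zero vector
  zero_gene <- names(which(colSums(vf$truth$counts) == 0))
  if (length(zero_gene) > 0)
    expect_identical(read_feature(store, zero_gene[1], header = hdr),
                     numeric(20))
})

test_that("converted image levels obey the pyramid oracle", {
  vf <- make_visium_fixture(seed = 75, dir = tempfile(), channels = 1L,
                            image_size = c(700L, 700L), n_spots = 8L)
  run <- read_visium_run(vf$dir, vf$image_path)
  out <- withr::local_tempdir()
  convert_visium(run, out, compression = "deflate", tile_size = 256L)
  cog <- cog_open(file.path(out, "image.tif"))
  filtered <- gaussian_prefilter(vf$truth$image, 4)
  finest <- read_level(cog, cog$n_levels - 1L)
  expect_identical(finest$pixels, filtered$pixels)
  lv <- read_level(cog, cog$n_levels - 2L)
  want <- oracle_pyramid_level(filtered, 1L)
  expect_lte(max(abs(lv$pixels - want)), 1)
})

test_that("both tissue-positions dialects parse to the same run", {
  a <- make_visium_fixture(seed = 76, dir = tempfile(),
                           positions_header = FALSE)
  b <- make_visium_fixture(seed = 76, dir = tempfile(),
                           positions_header = TRUE)
  ra <- read_visium_run(a$dir, a$image_path)
  rb <- read_visium_run(b$dir, b$image_path)
  expect_equal(ra$positions, rb$positions)
  expect_equal(as.matrix(ra$counts), as.matrix(rb$counts))
})

test_that("matrix barcodes without positions are a consistency error", {
  vf <- make_visium_fixture(seed = 77, dir = tempfile())
  pos_file <- file.path(vf$dir, "tissue_positions_list.csv")
  pos <- utils::read.csv(pos_file, header = FALSE)
  utils::write.table(pos[-3, ], pos_file, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  run <- read_visium_run(vf$dir, vf$image_path)
  expect_error(convert_visium(run, tempfile(), compression = "deflate"),
               "consistency error")
})

test_that("merfish conversion uses the first z-stack and the given affine", {
  mf <- make_merfish_fixture(seed = 78, dir = tempfile(), n_cells = 50,
                             n_genes = 12)
  run <- read_merfish_run(mf$paths$cells, mf$paths$meta,
                          mf$paths$transform, mf$paths$image)
  # background is z-plane 0 of the mosaic
  expect_identical(run$mosaic$pixels, mf$truth$z0$pixels)
  out <- withr::local_tempdir()
  convert_merfish(run, out)
  expect_length(validate_sample(out)$errors, 0L)
  md <- read_sample(out)
  expect_equal(md$overlays[[1]]$shape, "point")
  store <- file.path(out, "genes.scf")
  hdr <- read_store_header(store)
  for (g in mf$truth$gene_names)
    expect_identical(read_feature(store, g, header = hdr),
                     unname(f32(mf$truth$counts[, g])), info = g)
  ov <- read_overlay_csv(file.path(out, "cells.csv"))
  mpp <- md$images[[1]]$m_per_px
  expect_lt(max(abs(ov$x / mpp - mf$truth$centroids_px[, 1])), 1e-6)
  expect_lt(max(abs(ov$y / mpp - mf$truth$centroids_px[, 2])), 1e-6)
})

test_that("merfish counts can be log-transformed on request", {
  mf <- make_merfish_fixture(seed = 79, dir = tempfile(), n_cells = 30,
                             n_genes = 6)
  run <- read_merfish_run(mf$paths$cells, mf$paths$meta,
                          mf$paths$transform, mf$paths$image)
  out <- withr::local_tempdir()
  convert_merfish(run, out, log1p = TRUE)
  g <- mf$truth$gene_names[2]
  expect_identical(read_feature(file.path(out, "genes.scf"), g),
                   unname(f32(log1p(f32(mf$truth$counts[, g])))))
})

test_that("cells missing from metadata are a consistency error", {
  mf <- make_merfish_fixture(seed = 80, dir = tempfile(), n_cells = 20,
                             n_genes = 5)
  md <- utils::read.csv(mf$paths$meta)
  utils::write.csv(md[-5, ], mf$paths$meta, row.names = FALSE, quote = FALSE)
  run <- read_merfish_run(mf$paths$cells, mf$paths$meta,
                          mf$paths$transform, mf$paths$image)
  expect_error(convert_merfish(run, tempfile()), "consistency error")
})
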
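test_that("level count matches iterated halving for sampled image sizes", {
  # independent count: divide the long side by the factor until it fits a tile
  count_by_division <- function(longest, ts, f) {
    n <- 1L
    while (longest > ts) { longest <- ceiling(longest / f); n <- n + 1L }
    n
  }
  sizes <- c(1, 2, 255, 256, 511, 512, 513, 1024, 4096, 20480, 65536)
  for (w in sizes) for (ts in c(256L, 512L, 1024L)) {
    expect_identical(n_pyramid_levels(w, 1, ts),
                     count_by_division(w, ts, 2L),
                     info = sprintf("w=%d ts=%d", w, ts))
  }
  # a 20480-square image at tile 512 / factor 2 needs 7 levels
  expect_identical(n_pyramid_levels(20480, 20480, 512L), 7L)
  expect_identical(n_pyramid_levels(20480, 20480, 512L, 4L), 4L)
})

test_that("downsample averages blocks with half-up rounding", {
  p <- function(m) image_plane(m, dtype = "uint8")
  expect_equal(downsample(p(matrix(0, 2, 2)))$pixels[1, 1, 1], 0L)
  expect_equal(downsample(p(matrix(c(0, 2, 2, 4), 2, 2)))$pixels[1, 1, 1], 2L)
  # 3x3 with edge replication: enumerate the four blocks by hand
  m <- matrix(c(10, 20, 30,
                40, 50, 60,
                70, 80, 90), 3, 3, byrow = TRUE)
  got <- downsample(p(m))$pixels[, , 1]
  hand <- matrix(c(
    floor(mean(c(10, 20, 40, 50)) + 0.5),   # top-left block
    floor(mean(c(30, 30, 60, 60)) + 0.5),   # right col replicated
    floor(mean(c(70, 80, 70, 80)) + 0.5),   # bottom row replicated
    floor(mean(c(90, 90, 90, 90)) + 0.5)    # corner replicated
  ), 2, 2, byrow = TRUE)
  expect_equal(got, hand)
  expect_error(downsample(p(m), 1L), "invalid-argument")
})

test_that("downsample agrees with the phase-sum oracle across dtypes/factors", {
  for (dtype in c("uint8", "uint16", "float32")) {
    for (factor in c(2L, 3L)) {
      pl <- rand_plane(100 + factor, 37, 53, 2L, dtype)
      got <- downsample(pl, factor)
      for (ch in 1:2) {
        m <- pl$pixels[, , ch]; dim(m) <- dim(pl$pixels)[1:2]
        want <- oracle_block_mean(m, factor, dtype != "float32")
        if (dtype == "float32") {
          expect_equal(got$pixels[, , ch], f32(want), tolerance = 1e-6)
        } else {
          expect_equal(got$pixels[, , ch], want)
        }
      }
    }
  }
})

test_that("build_pyramid keeps the finest level bit-identical and obeys dims", {
  pl <- rand_plane(1, 280, 300, 3L)
  pyr <- build_pyramid(pl, 256L)
  n <- length(pyr$levels)
  expect_identical(pyr$levels[[n]]$pixels, pl$pixels)
  for (k in seq_len(n - 1)) {
    expect_equal(dim(pyr$levels[[k]]$pixels)[1:2],
                 ceiling(dim(pyr$levels[[k + 1]]$pixels)[1:2] / 2))
  }
  # single-tile image -> one level, identical
  small <- rand_plane(2, 512, 512)
  p1 <- build_pyramid(small, 512L)
  expect_length(p1$levels, 1L)
  expect_identical(p1$levels[[1]]$pixels, small$pixels)
  # constant image stays constant under the mean at every level
  const <- image_plane(array(7L, c(1024, 1024, 1)), "uint8")
  p2 <- build_pyramid(const, 512L)
  expect_length(p2$levels, 2L)
  expect_true(all(p2$levels[[1]]$pixels == 7L))
  expect_equal(dim(p2$levels[[1]]$pixels)[1:2], c(512, 512))
})

test_that("build_pyramid rejects bad input", {
  expect_error(image_plane(array(0L, c(0, 5, 1))), "invalid-input")
  pl <- rand_plane(3, 64, 64)
  expect_error(build_pyramid(pl, 128L), "tile_size")
  expect_error(build_pyramid(pl, 512L, 1L), "downsample_factor")
  expect_error(image_plane(matrix(-5, 4, 4), dtype = "uint8"),
               "unsupported-dtype")
})

test_that("every pyramid level matches iterated block-mean of the finest", {
  pl <- rand_plane(4, 700, 900, 1L)
  pyr <- build_pyramid(pl, 256L)
  n <- length(pyr$levels)
  for (k in seq_len(n - 1)) {
    want <- oracle_pyramid_level(pl, n - k)
    got <- pyr$levels[[k]]$pixels
    # interior is exact; replicated edges may differ by 1 intensity unit
    interior <- got[seq_len(nrow(want) - 1), seq_len(ncol(want) - 1), 1,
                    drop = FALSE]
    want_int <- want[seq_len(nrow(want) - 1), seq_len(ncol(want) - 1), 1,
                     drop = FALSE]
    expect_equal(interior, want_int)
    expect_lte(max(abs(got - want)), 1)
  }
})

test_that("tiles_for_viewport matches brute-force rectangle intersection", {
  meta <- pyramid_meta(4096, 4096, 512L)
  expect_equal(meta$n_levels, 4L)
  # whole image at the coarsest level of a single-tile-per-level pyramid
  whole <- tiles_for_viewport(meta, c(0, 0, 4096, 4096), 0L)
  expect_equal(nrow(whole), 1L)
  expect_equal(unlist(whole), c(level = 0L, tile_x = 0L, tile_y = 0L))
  # one-pixel viewport always selects exactly one tile
  for (lv in 0:3)
    expect_equal(nrow(tiles_for_viewport(meta, c(0, 0, 1, 1), lv)), 1L)

  brute <- function(meta, v, lv) {
    sc <- 2^(meta$n_levels - 1 - lv)
    ld <- ceiling(c(meta$width, meta$height) / sc)
    nt <- ceiling(ld / meta$tile_size)
    hits <- NULL
    for (ty in seq_len(nt[2]) - 1) for (tx in seq_len(nt[1]) - 1) {
      x0 <- tx * meta$tile_size * sc
      x1 <- min((tx + 1) * meta$tile_size, ld[1]) * sc
      y0 <- ty * meta$tile_size * sc
      y1 <- min((ty + 1) * meta$tile_size, ld[2]) * sc
      if (x0 < min(v[3], meta$width) && x1 > max(v[1], 0) &&
          y0 < min(v[4], meta$height) && y1 > max(v[2], 0))
        hits <- rbind(hits, c(lv, tx, ty))
    }
    hits
  }
  set.seed(11)
  for (i in 1:25) {
    lv <- sample(0:3, 1)
    x <- sort(runif(2, -200, 4300)); y <- sort(runif(2, -200, 4300))
    if (diff(x) < 1) x[2] <- x[1] + 1
    if (diff(y) < 1) y[2] <- y[1] + 1
    v <- c(x[1], y[1], x[2], y[2])
    got <- tiles_for_viewport(meta, v, lv)
    want <- brute(meta, v, lv)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(unname(as.matrix(got)), unname(want))
      expect_false(any(duplicated(got)))
    }
  }
})
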
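# Shared helpers: small random planes and independent oracles. Oracles are
# deliberately implemented by a different route than the package code
# (phase-sum block means instead of rowsum aggregation; winding numbers
# instead of ray casting) so they are genuine cross-checks.

rand_plane <- function(seed, h, w, c = 1L, dtype = "uint8") {
  set.seed(seed)
  maxv <- switch(dtype, uint8 = 255L, uint16 = 65535L, float32 = NA)
  px <- if (dtype == "float32") {
    array(stats::rnorm(h * w * c), c(h, w, c))
  } else {
    array(sample.int(maxv + 1L, h * w * c, replace = TRUE) - 1L, c(h, w, c))
  }
  image_plane(px, dtype = dtype)
}

# independent block-mean oracle: pad by edge replication, then average the
# factor^2 phase-shifted subgrids; round half up for integer data
oracle_block_mean <- function(mat, factor, integer_dtype = TRUE) {
  h <- nrow(mat); w <- ncol(mat)
  ho <- ceiling(h / factor); wo <- ceiling(w / factor)
  pad <- mat[pmin(seq_len(ho * factor), h), pmin(seq_len(wo * factor), w),
             drop = FALSE]
  acc <- matrix(0, ho, wo)
  for (i in seq_len(factor)) for (j in seq_len(factor))
    acc <- acc + pad[seq(i, by = factor, length.out = ho),
                     seq(j, by = factor, length.out = wo)]
  acc <- acc / factor^2
  if (integer_dtype) floor(acc + 0.5) else acc
}

oracle_pyramid_level <- function(plane, n_down, integer_dtype = TRUE) {
  d <- dim(plane$pixels)
  out <- NULL
  for (ch in seq_len(d[3])) {
    m <- plane$pixels[, , ch]
    dim(m) <- d[1:2]
    for (k in seq_len(n_down)) m <- oracle_block_mean(m, 2L, integer_dtype)
    if (is.null(out)) out <- array(0, c(dim(m), d[3]))
    out[, , ch] <- m
  }
  out
}

# winding-number point-in-polygon (nonzero rule), boundary treated as inside
oracle_point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  wn <- 0
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    len2 <- sum((b - a)^2)
    if (abs(cross) <= eps * sqrt(max(len2, 1)) &&
        px >= min(a[1], b[1]) - eps && px <= max(a[1], b[1]) + eps &&
        py >= min(a[2], b[2]) - eps && py <= max(a[2], b[2]) + eps)
      return(TRUE)
    if (a[2] <= py) {
      if (b[2] > py && cross > 0) wn <- wn + 1
    } else {
      if (b[2] <= py && cross < 0) wn <- wn - 1
    }
  }
  wn != 0
}

random_convex_polygon <- function(n_vertices, center, radius) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang))
}

f32 <- function(x) spattile:::as_float32(x)

expect_plane_identical <- function(a, b) {
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$dtype, b$dtype)
}

local_range_server <- function(root, honor_range = TRUE,
                               env = parent.frame()) {
  srv <- start_range_server(root, honor_range)
  withr::defer(stop_range_server(srv), envir = env)
  srv
}
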
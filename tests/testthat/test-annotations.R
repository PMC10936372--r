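triangle_set <- function() {
  annotation_set(
    point_labels = c("0" = "WM", "3" = "GM"),
    regions = list(list(label = "WM",
                        polygon = rbind(c(0, 0), c(100, 0), c(50, 80)))))
}

test_that("a labeled triangle exports to a closed GeoJSON polygon", {
  stem <- file.path(withr::local_tempdir(), "ann")
  paths <- export_annotations(triangle_set(), stem)
  gj <- jsonlite::fromJSON(paths[["geojson"]], simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 1L)
  ft <- gj$features[[1]]
  expect_equal(ft$geometry$type, "Polygon")
  expect_equal(ft$properties$label, "WM")
  ring <- ft$geometry$coordinates[[1]]
  expect_length(ring, 4L)                      # 3 vertices + closing point
  expect_equal(ring[[1]], ring[[4]])
  # CSV row count equals the number of labeled points
  expect_equal(nrow(utils::read.csv(paths[["csv"]])), 2L)
})

test_that("export then import is the identity on randomized sets", {
  set.seed(91)
  labels <- c("WM", "GM", "L1", "vasc")
  for (i in 1:5) {
    regions <- lapply(seq_len(sample(1:4, 1)), function(j) {
      list(label = sample(labels, 1),
           polygon = random_convex_polygon(sample(3:8, 1),
                                           runif(2, 0, 500), runif(1, 10, 80)))
    })
    n_lab <- sample(0:6, 1)
    pl <- stats::setNames(sample(labels, n_lab, replace = TRUE),
                          as.character(sample(0:999, n_lab)))
    markers <- lapply(seq_len(sample(0:2, 1)), function(j)
      list(label = sample(labels, 1), xy = runif(2, 0, 500)))
    set <- annotation_set(pl, regions, markers)
    stem <- tempfile()
    paths <- export_annotations(set, stem)
    set2 <- import_annotations(paths[["geojson"]], paths[["csv"]])
    expect_equal(set2, set)
  }
})

test_that("exports are byte-deterministic", {
  s1 <- tempfile(); s2 <- tempfile()
  export_annotations(triangle_set(), s1)
  export_annotations(triangle_set(), s2)
  expect_identical(readBin(paste0(s1, ".geojson"), raw(), 1e6),
                   readBin(paste0(s2, ".geojson"), raw(), 1e6))
  expect_identical(readLines(paste0(s1, ".csv")),
                   readLines(paste0(s2, ".csv")))
})

test_that("unsupported geometries are skipped with a warning", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(label = "ok"),
         geometry = list(type = "Polygon", coordinates = list(list(
           list(0, 0), list(10, 0), list(5, 5), list(0, 0))))),
    list(type = "Feature", properties = NULL,
         geometry = list(type = "LineString",
                         coordinates = list(list(0, 0), list(1, 1))))
  ))
  f <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA)
  expect_warning(set <- import_annotations(f), "unsupported-geometry")
  expect_length(set$regions, 1L)
  expect_equal(set$regions[[1]]$label, "ok")
})

test_that("features without labels import as 'unlabeled'", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = NULL,
         geometry = list(type = "Polygon", coordinates = list(list(
           list(0, 0), list(4, 0), list(4, 4), list(0, 4), list(0, 0)))))))
  f <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA)
  set <- import_annotations(f)
  expect_equal(set$regions[[1]]$label, "unlabeled")
})

test_that("an external drawing-tool rectangle imports with its label", {
  # hand-written file mimicking a generic GeoJSON export (closed 4-gon)
  f <- tempfile(fileext = ".geojson")
  writeLines(paste0(
    '{"type":"FeatureCollection","features":[{"type":"Feature",',
    '"properties":{"label":"cortex","source":"drawing-tool"},',
    '"geometry":{"type":"Polygon","coordinates":',
    '[[[10.5,20],[300,20],[300,180.25],[10.5,180.25],[10.5,20]]]}}]}'), f)
  set <- import_annotations(f)
  expect_length(set$regions, 1L)
  expect_equal(set$regions[[1]]$label, "cortex")
  expect_equal(nrow(set$regions[[1]]$polygon), 4L)  # reopened ring
  expect_equal(set$regions[[1]]$polygon[1, ], c(10.5, 20))
})

test_that("points go to the containing region, boundary inclusive, last wins", {
  sq <- function(x0, y0, x1, y1)
    rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  set <- annotation_set(regions = list(
    list(label = "A", polygon = sq(0, 0, 1, 1)),
    list(label = "B", polygon = sq(0.5, 0.5, 2, 2))))
  pts <- rbind(c(0.25, 0.25),   # strictly inside A only
               c(0.75, 0.75),   # inside both -> B (listed later)
               c(1, 0.25),      # on A's right edge -> inside
               c(5, 5))         # nowhere
  lab <- assign_points_to_regions(pts, set)
  expect_equal(unname(lab[c("0", "1", "2")]), c("A", "B", "A"))
  expect_false("3" %in% names(lab))
})

test_that("assignment agrees with the winding-number oracle on random points", {
  set.seed(92)
  regions <- lapply(1:5, function(j)
    list(label = paste0("R", j),
         polygon = random_convex_polygon(sample(3:7, 1),
                                         runif(2, 100, 400),
                                         runif(1, 30, 120))))
  set <- annotation_set(regions = regions)
  pts <- cbind(runif(500, 0, 512), runif(500, 0, 512))
  got <- assign_points_to_regions(pts, set)
  for (i in 1:500) {
    want <- NA_character_
    for (rg in regions)
      if (oracle_point_in_polygon(pts[i, 1], pts[i, 2], rg$polygon))
        want <- rg$label
    if (is.na(want)) {
      expect_false(as.character(i - 1) %in% names(got))
    } else {
      expect_equal(unname(got[[as.character(i - 1)]]), want)
    }
  }
  # label conservation: everything emitted is in the vocabulary
  expect_true(all(got %in% set$label_vocabulary))
})
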
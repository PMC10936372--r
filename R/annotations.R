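# Annotation import/export at three granularities: per-point labels (cells
# or spots; CSV id,label), labeled region polygons (spatial domains; GeoJSON
# Polygon features), and labeled point markers (GeoJSON Point features).
# GeoJSON coordinates are full-resolution pixel coordinates with y growing
# downward (raster frame, not geographic); the files record this in a
# top-level "crs_note" so other tools are not misled.

#' Construct an annotation set
#'
#' @param point_labels named character vector: overlay point id -> label
#'   (sparse; unlabeled points simply absent). Names are point ids.
#' @param regions list of `list(label =, polygon =)` where `polygon` is an
#'   n x 2 matrix of (x, y) full-resolution pixel vertices, at least 3
#'   distinct vertices, without the closing duplicate (added on export).
#' @param markers optional list of `list(label =, xy =)` labeled points.
#' @param label_vocabulary ordered label set; defaults to the labels in use.
#' @return object of class `AnnotationSet`.
#' @export
annotation_set <- function(point_labels = character(), regions = list(),
                           markers = list(), label_vocabulary = NULL) {
  if (length(point_labels) > 0L && is.null(names(point_labels)))
    stop("point_labels must be named by point id")
  point_labels <- stats::setNames(as.character(point_labels),
                                  as.character(names(point_labels) %||%
                                                 character()))
  for (rg in regions) {
    poly <- rg$polygon
    if (!is.matrix(poly) || ncol(poly) != 2L)
      stop("region polygon must be an n x 2 matrix")
    if (nrow(poly) >= 2L &&
        all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), ]
    if (nrow(unique(poly)) < 3L)
      stop("region polygon needs at least 3 distinct vertices")
  }
  used <- c(unname(point_labels),
            vapply(regions, `[[`, "", "label"),
            vapply(markers, `[[`, "", "label"))
  vocab <- label_vocabulary %||% unique(used)
  if (!all(used %in% vocab))
    stop("label outside vocabulary: ",
         paste(setdiff(used, vocab), collapse = ", "))
  structure(list(label_vocabulary = as.character(vocab),
                 point_labels = point_labels,
                 regions = lapply(regions, function(rg) {
                   poly <- rg$polygon
                   if (nrow(poly) >= 2L &&
                       all(poly[1, ] == poly[nrow(poly), ]))
                     poly <- poly[-nrow(poly), , drop = FALSE]
                   dimnames(poly) <- NULL
                   list(label = rg$label, polygon = poly)
                 }),
                 markers = lapply(markers, function(mk)
                   list(label = mk$label, xy = as.numeric(mk$xy)))),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf(
    "AnnotationSet: %d labeled point(s), %d region(s), %d marker(s); %s\n",
    length(x$point_labels), length(x$regions), length(x$markers),
    paste(x$label_vocabulary, collapse = ", ")))
  invisible(x)
}

#' Export annotations as CSV + GeoJSON
#'
#' Point labels go to `<stem>.csv` (`id,label` rows); regions and markers go
#' to `<stem>.geojson` as an RFC 7946-shaped FeatureCollection of Polygon /
#' Point features carrying a `label` property. Polygons are written as
#' explicitly closed rings. Output is deterministic: fixed key order and
#' number formatting, so identical sets yield byte-identical files.
#'
#' @param set an [annotation_set()].
#' @param stem output path without extension.
#' @return named character vector with `csv` and `geojson` paths.
#' @export
export_annotations <- function(set, stem) {
  stopifnot(inherits(set, "AnnotationSet"))
  csv_path <- paste0(stem, ".csv")
  geo_path <- paste0(stem, ".geojson")

  df <- data.frame(id = names(set$point_labels),
                   label = unname(set$point_labels))
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)

  feat <- list()
  for (rg in set$regions) {
    ring <- rbind(rg$polygon, rg$polygon[1, ])   # close explicitly
    coords <- lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ]))
    feat[[length(feat) + 1L]] <- list(
      type = "Feature",
      properties = list(label = rg$label),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  }
  for (mk in set$markers) {
    feat[[length(feat) + 1L]] <- list(
      type = "Feature",
      properties = list(label = mk$label),
      geometry = list(type = "Point", coordinates = as.numeric(mk$xy))
    )
  }
  fc <- list(
    type = "FeatureCollection",
    crs_note = paste("coordinates are full-resolution image pixels;",
                     "x right, y down"),
    label_vocabulary = as.list(set$label_vocabulary),
    features = feat
  )
  jsonlite::write_json(fc, geo_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(csv = csv_path, geojson = geo_path)
}

#' Import annotations from CSV and/or GeoJSON
#'
#' Accepts a GeoJSON FeatureCollection (Polygon and Point features; anything
#' else is skipped with an `unsupported-geometry` warning), an `id,label`
#' CSV, or both (pass the two paths). Features without a `label` property
#' get the label `"unlabeled"`. Polygon holes (inner rings) are not
#' supported and are dropped with a warning.
#'
#' @param geojson path to a GeoJSON file, or `NULL`.
#' @param csv path to an `id,label` CSV, or `NULL`.
#' @return an [annotation_set()].
#' @export
import_annotations <- function(geojson = NULL, csv = NULL) {
  point_labels <- character()
  regions <- list(); markers <- list(); vocab <- NULL

  if (!is.null(csv)) {
    df <- utils::read.csv(csv, colClasses = "character")
    if (!all(c("id", "label") %in% names(df)))
      stop("parse error: CSV must have id,label columns")
    point_labels <- stats::setNames(df$label, df$id)
  }

  if (!is.null(geojson)) {
    fc <- tryCatch(jsonlite::fromJSON(geojson, simplifyVector = FALSE),
                   error = function(e) stop("parse error: ",
                                            conditionMessage(e)))
    if (!identical(fc$type, "FeatureCollection"))
      stop("parse error: expected a FeatureCollection")
    if (!is.null(fc$label_vocabulary)) vocab <- unlist(fc$label_vocabulary)
    for (ft in fc$features) {
      label <- ft$properties$label %||% "unlabeled"
      geom <- ft$geometry
      if (identical(geom$type, "Polygon")) {
        rings <- geom$coordinates
        if (length(rings) > 1L)
          warning("unsupported-geometry: polygon holes dropped")
        ring <- do.call(rbind, lapply(rings[[1]], function(p)
          as.numeric(unlist(p))))
        regions[[length(regions) + 1L]] <- list(label = label, polygon = ring)
      } else if (identical(geom$type, "Point")) {
        markers[[length(markers) + 1L]] <-
          list(label = label, xy = as.numeric(unlist(geom$coordinates)))
      } else {
        warning("unsupported-geometry: skipped ", geom$type %||% "unknown",
                " feature")
      }
    }
  }
  if (!is.null(vocab))
    vocab <- unique(c(vocab, unname(point_labels),
                      vapply(regions, `[[`, "", "label"),
                      vapply(markers, `[[`, "", "label")))
  annotation_set(point_labels, regions, markers, label_vocabulary = vocab)
}

# boundary-inclusive point-in-polygon: even-odd ray casting with an on-edge
# short circuit, so points exactly on a border count as inside
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  scale <- max(abs(c(xs, ys, px, py)), 1)
  # on-edge test: collinear and within the segment's bounding box
  cross <- (xe - xs) * (py - ys) - (ye - ys) * (px - xs)
  seglen2 <- (xe - xs)^2 + (ye - ys)^2
  on_edge <- abs(cross) <= eps * scale * sqrt(pmax(seglen2, 1)) &
    px >= pmin(xs, xe) - eps * scale & px <= pmax(xs, xe) + eps * scale &
    py >= pmin(ys, ye) - eps * scale & py <= pmax(ys, ye) + eps * scale
  if (any(on_edge)) return(TRUE)
  crossings <- (ys > py) != (ye > py) &
    px < xs + (py - ys) * (xe - xs) / (ye - ys)
  sum(crossings) %% 2 == 1
}

#' Assign overlay points to annotated regions
#'
#' Labels each overlay point with the label of the region polygon containing
#' it. Boundaries count as inside; when several regions contain a point, the
#' region listed last wins; points in no region are left out of the result.
#'
#' @param points data.frame with `id`, `x`, `y` in the same pixel frame as
#'   the polygons (an overlay CSV read with [read_overlay_csv()] should be
#'   converted to pixels first), or an n x 2 matrix (ids `0:(n-1)`).
#' @param set an [annotation_set()] whose regions share that frame.
#' @return named character vector: point id -> label (sparse).
#' @export
assign_points_to_regions <- function(points, set) {
  stopifnot(inherits(set, "AnnotationSet"))
  if (is.matrix(points))
    points <- data.frame(id = seq_len(nrow(points)) - 1L,
                         x = points[, 1], y = points[, 2])
  out <- character()
  for (i in seq_len(nrow(points))) {
    hit <- NA_character_
    for (rg in set$regions)     # later regions override earlier ones
      if (point_in_polygon(points$x[i], points$y[i], rg$polygon))
        hit <- rg$label
    if (!is.na(hit)) out[as.character(points$id[i])] <- hit
  }
  out
}
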
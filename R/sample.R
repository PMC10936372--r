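# The Sample folder: one JSON manifest (sample.json) binding image pyramids,
# overlays (spatial coordinates), and feature groups. Coordinates and
# features are deliberately separated: an overlay owns the positions; any
# number of feature groups reference it by name, and removing a feature
# group can never invalidate the overlay.

SAMPLE_SCHEMA_VERSION <- 1L

#' Describe an image belonging to a sample
#' @param uri path of the COG, relative to the sample folder.
#' @param channel_names channel labels.
#' @param m_per_px physical size of one full-resolution pixel, in meters.
#' @param default_channels channels a viewer should show initially.
#' @export
sample_image <- function(uri, channel_names, m_per_px,
                         default_channels = NULL) {
  stopifnot(is.character(uri), length(uri) == 1L, m_per_px > 0)
  list(uri = uri, channel_names = as.character(channel_names),
       m_per_px = as.numeric(m_per_px),
       default_channels = as.character(default_channels %||%
                                         utils::head(channel_names, 3L)))
}

#' Describe an overlay (a layer of spatial points)
#'
#' An overlay is a named set of points sharing the image's coordinate frame.
#' Point coordinates live in the referenced CSV (`id,x,y`, in meters);
#' the manifest records the name, geometry kind and, for circles, the
#' physical diameter (e.g. 55e-6 m for a Visium spot).
#'
#' @param name overlay name, referenced by feature groups.
#' @param uri CSV path relative to the sample folder.
#' @param shape `"circle"`, `"point"`, or `"polygon"`.
#' @param diameter physical diameter in meters (required for circles).
#' @export
sample_overlay <- function(name, uri, shape = c("circle", "point", "polygon"),
                           diameter = NULL) {
  shape <- match.arg(shape)
  if (shape == "circle") {
    if (is.null(diameter) || diameter <= 0)
      stop("schema error: circle overlay needs diameter > 0")
  }
  out <- list(name = name, uri = uri, shape = shape)
  if (!is.null(diameter)) out$diameter <- as.numeric(diameter)
  out
}

#' Describe a feature group bound to an overlay
#' @param name group name.
#' @param uri feature file path relative to the sample folder.
#' @param overlay_name name of the overlay the features attach to.
#' @param storage `"chunked"` (SCF1) or `"plain"` (dense CSV).
#' @param data_kind `"quantitative"` or `"categorical"`.
#' @export
sample_feature_group <- function(name, uri, overlay_name,
                                 storage = c("chunked", "plain"),
                                 data_kind = c("quantitative",
                                               "categorical")) {
  list(name = name, uri = uri, overlay_name = overlay_name,
       storage = match.arg(storage), data_kind = match.arg(data_kind))
}

#' Assemble sample metadata
#'
#' @param sample_name sample identifier.
#' @param images list of [sample_image()].
#' @param overlays list of [sample_overlay()].
#' @param feature_groups list of [sample_feature_group()].
#' @return object of class `SampleMetadata`.
#' @export
sample_metadata <- function(sample_name, images = list(), overlays = list(),
                            feature_groups = list()) {
  overlay_names <- vapply(overlays, `[[`, "", "name")
  for (fg in feature_groups)
    if (!fg$overlay_name %in% overlay_names)
      stop("schema error: feature group '", fg$name,
           "' references unknown overlay '", fg$overlay_name, "'")
  structure(list(version = SAMPLE_SCHEMA_VERSION,
                 sample_name = sample_name, images = images,
                 overlays = overlays, feature_groups = feature_groups),
            class = "SampleMetadata")
}

#' @export
print.SampleMetadata <- function(x, ...) {
  cat(sprintf("Sample '%s': %d image(s), %d overlay(s), %d feature group(s)\n",
              x$sample_name, length(x$images), length(x$overlays),
              length(x$feature_groups)))
  invisible(x)
}

metadata_to_list <- function(md) {
  list(version = md$version, sample_name = md$sample_name,
       images = lapply(md$images, function(im) {
         im$channel_names <- as.list(im$channel_names)
         im$default_channels <- as.list(im$default_channels)
         im
       }),
       overlays = md$overlays,
       feature_groups = md$feature_groups)
}

list_to_metadata <- function(x) {
  images <- lapply(x$images, function(im)
    sample_image(im$uri, unlist(im$channel_names), im$m_per_px,
                 unlist(im$default_channels)))
  overlays <- lapply(x$overlays, function(ov)
    sample_overlay(ov$name, ov$uri, ov$shape, ov$diameter))
  fgs <- lapply(x$feature_groups, function(fg)
    sample_feature_group(fg$name, fg$uri, fg$overlay_name, fg$storage,
                         fg$data_kind))
  sample_metadata(x$sample_name, images, overlays, fgs)
}

#' Write overlay point coordinates as CSV
#' @param points data.frame with columns `id`, `x`, `y` (meters) — or a
#'   two-column matrix of x,y (ids autogenerated).
#' @param path output CSV path.
#' @export
write_overlay_csv <- function(points, path) {
  if (is.matrix(points))
    points <- data.frame(id = seq_len(nrow(points)) - 1L,
                         x = points[, 1], y = points[, 2])
  stopifnot(all(c("id", "x", "y") %in% names(points)))
  utils::write.csv(points[c("id", "x", "y")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an overlay CSV
#' @param path overlay CSV (`id,x,y`).
#' @export
read_overlay_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("id", "x", "y") %in% names(df)))
  df
}

#' Write a Sample folder
#'
#' Writes `sample.json` into `out_dir` and stages any referenced component
#' files supplied in `components` (a named list mapping manifest uri to an
#' existing file path). Components already present in `out_dir` under their
#' manifest uri are left alone. Every reference is checked; a manifest uri
#' with no file behind it is a schema error.
#'
#' @param metadata a [sample_metadata()].
#' @param out_dir sample folder (created if needed).
#' @param components named list `uri = source_path` of files to copy in.
#' @return `out_dir`, invisibly.
#' @export
write_sample <- function(metadata, out_dir, components = list()) {
  stopifnot(inherits(metadata, "SampleMetadata"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  uris <- c(vapply(metadata$images, `[[`, "", "uri"),
            vapply(metadata$overlays, `[[`, "", "uri"),
            vapply(metadata$feature_groups, `[[`, "", "uri"))
  for (u in uris) {
    dest <- file.path(out_dir, u)
    if (!file.exists(dest)) {
      srcp <- components[[u]]
      if (is.null(srcp) || !file.exists(srcp))
        stop("schema error: dangling reference '", u, "'")
      dir.create(dirname(dest), showWarnings = FALSE, recursive = TRUE)
      file.copy(srcp, dest)
    }
  }
  jsonlite::write_json(metadata_to_list(metadata),
                       file.path(out_dir, "sample.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a Sample folder's manifest
#' @param dir sample folder containing `sample.json`.
#' @return a `SampleMetadata`.
#' @export
read_sample <- function(dir) {
  path <- file.path(dir, "sample.json")
  if (!file.exists(path)) stop("fatal: no sample.json in ", dir)
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop("fatal parse error: ",
                                         conditionMessage(e)))
  list_to_metadata(x)
}

#' Validate a Sample folder
#'
#' Structural and referential checks on a sample: every manifest uri
#' resolves; feature-group point counts match their overlay's point count;
#' SCF1 headers parse and every chunk decompresses cleanly; overlay points
#' convert to pixel positions inside the companion image bounds (out-of-tissue
#' points are a warning, not an error). An empty error list means the sample
#' is loadable.
#'
#' @param dir sample folder.
#' @return object of class `sample_validation` with `errors` and `warnings`
#'   character vectors.
#' @export
validate_sample <- function(dir) {
  errors <- character(); warnings <- character()
  md <- tryCatch(read_sample(dir), error = function(e) e)
  if (inherits(md, "error")) {
    return(structure(list(errors = conditionMessage(md),
                          warnings = character()),
                     class = "sample_validation"))
  }

  resolve <- function(uri) file.path(dir, uri)
  img_dims <- list()
  for (im in md$images) {
    p <- resolve(im$uri)
    if (!file.exists(p)) {
      errors <- c(errors, paste0("dangling image reference: ", im$uri))
      next
    }
    cog <- tryCatch(cog_open(p), error = function(e) e)
    if (inherits(cog, "error")) {
      errors <- c(errors, paste0("unreadable image ", im$uri, ": ",
                                 conditionMessage(cog)))
    } else {
      img_dims[[im$uri]] <- c(cog$width, cog$height)
      if (length(im$channel_names) != length(cog$channel_names))
        errors <- c(errors, paste0("channel count mismatch for ", im$uri))
    }
  }

  overlay_n <- list()
  for (ov in md$overlays) {
    p <- resolve(ov$uri)
    if (!file.exists(p)) {
      errors <- c(errors, paste0("dangling overlay reference: ", ov$uri))
      next
    }
    pts <- tryCatch(read_overlay_csv(p), error = function(e) e)
    if (inherits(pts, "error")) {
      errors <- c(errors, paste0("malformed overlay ", ov$uri))
      next
    }
    if (nrow(pts) == 0L)
      errors <- c(errors, paste0("overlay '", ov$name, "' has no points"))
    overlay_n[[ov$name]] <- nrow(pts)
    if (identical(ov$shape, "circle") &&
        (is.null(ov$diameter) || ov$diameter <= 0))
      errors <- c(errors, paste0("overlay '", ov$name,
                                 "': circle without diameter"))
    # bounds check against the first image, if any
    if (length(md$images) > 0L && length(img_dims) > 0L) {
      im <- md$images[[1]]
      dims <- img_dims[[im$uri]]
      if (!is.null(dims)) {
        px <- pts$x / im$m_per_px; py <- pts$y / im$m_per_px
        n_out <- sum(px < 0 | px > dims[1] | py < 0 | py > dims[2])
        if (n_out > 0)
          warnings <- c(warnings,
                        paste0("overlay '", ov$name, "': ", n_out,
                               " point(s) outside image bounds"))
      }
    }
  }

  for (fg in md$feature_groups) {
    p <- resolve(fg$uri)
    if (!file.exists(p)) {
      errors <- c(errors, paste0("dangling feature reference: ", fg$uri))
      next
    }
    n_overlay <- overlay_n[[fg$overlay_name]]
    if (fg$storage == "chunked") {
      hdr <- tryCatch(read_store_header(p), error = function(e) e)
      if (inherits(hdr, "error")) {
        errors <- c(errors, paste0("malformed store header ", fg$uri, ": ",
                                   conditionMessage(hdr)))
        next
      }
      if (!is.null(n_overlay) && hdr$n_points != n_overlay)
        errors <- c(errors, paste0("count mismatch: feature group '",
                                   fg$name, "' has ", hdr$n_points,
                                   " points, overlay '", fg$overlay_name,
                                   "' has ", n_overlay))
      for (nm in names(hdr$features)) {
        v <- tryCatch(read_feature(p, nm, header = hdr),
                      error = function(e) e)
        if (inherits(v, "error"))
          errors <- c(errors, paste0("corrupt-chunk in ", fg$uri, ": ",
                                     conditionMessage(v)))
      }
    } else {
      df <- tryCatch(utils::read.csv(p, check.names = FALSE),
                     error = function(e) e)
      if (inherits(df, "error")) {
        errors <- c(errors, paste0("malformed feature CSV ", fg$uri))
      } else if (!is.null(n_overlay) && nrow(df) != n_overlay) {
        errors <- c(errors, paste0("count mismatch: feature group '",
                                   fg$name, "' has ", nrow(df),
                                   " rows, overlay '", fg$overlay_name,
                                   "' has ", n_overlay))
      }
    }
  }

  structure(list(errors = errors, warnings = warnings),
            class = "sample_validation")
}

#' @export
print.sample_validation <- function(x, ...) {
  if (length(x$errors) == 0L) cat("sample valid")
  else cat(length(x$errors), "error(s):\n ",
           paste(x$errors, collapse = "\n  "))
  cat("\n")
  if (length(x$warnings) > 0L)
    cat(length(x$warnings), "warning(s):\n ",
        paste(x$warnings, collapse = "\n  "), "\n")
  invisible(x)
}
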
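# Sparse, chunked, compressed feature store ("SCF1"). Layout:
#   bytes 0-3   magic "SCF1"
#   bytes 4-7   header length (unsigned 32-bit little-endian)
#   header      UTF-8 JSON: {version, n_points, features: {name ->
#                 {offset, length, n_nonzero, kind[, labels]}}}
#   payload     concatenated gzip chunks, one per feature, each holding CSV
#               rows "index,value" (0-based point index; zeros omitted)
# Offsets are relative to the end of the header, so a reader that has the
# header can fetch any single feature with one byte-range request.

#' Construct a feature matrix
#'
#' Per-point feature values for one overlay: `N` points by `F` features.
#' Quantitative columns are float32 (snapped on construction so file round
#' trips are exact); character/factor columns are treated as categorical
#' labels, with `NA` meaning "no label".
#'
#' @param values numeric matrix or data.frame (columns may be numeric,
#'   character, or factor).
#' @param feature_names optional; defaults to column names.
#' @return an object of class `FeatureMatrix` with fields `values`
#'   (data.frame), `n`, `feature_names`, `kinds`.
#' @export
feature_matrix <- function(values, feature_names = NULL) {
  if (is.matrix(values)) values <- as.data.frame(values)
  stopifnot(is.data.frame(values))
  feature_names <- feature_names %||% colnames(values) %||%
    paste0("f", seq_len(ncol(values)))
  if (anyDuplicated(feature_names))
    stop("schema error: duplicate feature names")
  if (length(feature_names) != ncol(values))
    stop("feature_names length must equal column count")
  kinds <- character(ncol(values))
  for (j in seq_len(ncol(values))) {
    col <- values[[j]]
    if (is.factor(col)) col <- as.character(col)
    if (is.character(col)) {
      kinds[j] <- "categorical"
    } else if (is.numeric(col)) {
      if (any(!is.finite(col))) stop("data error: non-finite value in ",
                                     feature_names[j])
      col <- as_float32(col)
      kinds[j] <- "quantitative"
    } else stop("unsupported column type in ", feature_names[j])
    values[[j]] <- col
  }
  names(values) <- feature_names
  structure(list(values = values, n = nrow(values),
                 feature_names = feature_names, kinds = kinds),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d point(s) x %d feature(s) (%d categorical)\n",
              x$n, length(x$feature_names), sum(x$kinds == "categorical")))
  invisible(x)
}

#' Natural-log transform of a feature matrix
#'
#' Applies `x -> log(1 + x)` elementwise to every quantitative feature.
#' Zeros map to zeros, so the sparsity pattern (and each feature's
#' `n_nonzero`) is preserved. Categorical columns pass through unchanged.
#'
#' @param matrix a [feature_matrix()].
#' @return a transformed `FeatureMatrix`.
#' @export
log_transform <- function(matrix) {
  stopifnot(inherits(matrix, "FeatureMatrix"))
  v <- matrix$values
  for (j in seq_along(v)) {
    if (matrix$kinds[j] != "quantitative") next
    if (any(v[[j]] < 0)) stop("domain error: log_transform needs ",
                              "non-negative values (", names(v)[j], ")")
    v[[j]] <- as_float32(log1p(v[[j]]))
  }
  feature_matrix(v, matrix$feature_names)
}

format_f32 <- function(x) {
  # 9 significant digits round-trip any float32 exactly
  s <- sprintf("%.9g", x)
  i <- x == round(x) & abs(x) < 1e15
  s[i] <- sprintf("%.0f", x[i])
  s
}

feature_chunk_text <- function(col, kind, labels = NULL) {
  if (kind == "quantitative") {
    nz <- which(col != 0)
    if (length(nz) == 0L) return("")
    paste0(paste0(nz - 1L, ",", format_f32(col[nz]), collapse = "\n"), "\n")
  } else {
    nz <- which(!is.na(col) & col != "")
    if (length(nz) == 0L) return("")
    paste0(paste0(nz - 1L, ",", match(col[nz], labels) - 1L, collapse = "\n"),
           "\n")
  }
}

#' Write a feature matrix as a chunked sparse store
#'
#' Serializes each feature as its own gzip-compressed sparse-CSV chunk with a
#' JSON index header at the front of the file, so a reader can fetch exactly
#' one feature with one byte-range request.
#'
#' @param matrix a [feature_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_store <- function(matrix, path) {
  stopifnot(inherits(matrix, "FeatureMatrix"))
  chunks <- vector("list", length(matrix$feature_names))
  feats <- list()
  offset <- 0
  for (j in seq_along(matrix$feature_names)) {
    kind <- matrix$kinds[j]
    col <- matrix$values[[j]]
    labels <- if (kind == "categorical")
      unique(col[!is.na(col) & col != ""]) else NULL
    txt <- feature_chunk_text(col, kind, labels)
    gz <- gzip_text(txt)
    chunks[[j]] <- gz
    entry <- list(offset = offset, length = length(gz),
                  n_nonzero = if (nzchar(txt))
                    length(gregexpr("\n", txt, fixed = TRUE)[[1]]) else 0L,
                  kind = kind)
    if (kind == "categorical") entry$labels <- as.list(labels)
    feats[[matrix$feature_names[j]]] <- entry
    offset <- offset + length(gz)
  }
  header <- charToRaw(as.character(jsonlite::toJSON(
    list(version = 1L, n_points = matrix$n, features = feats),
    auto_unbox = TRUE)))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("SCF1"), con)
  writeBin(u32le(length(header)), con)
  writeBin(header, con)
  for (gz in chunks) writeBin(gz, con)
  invisible(path)
}

#' Read the index header of a chunked feature store
#'
#' Fetches and parses the store's JSON header (two reads: the 8-byte prefix,
#' then the header itself) and caches it on the source so later
#' [read_feature()] calls pay only for their own chunk.
#'
#' @param x a `ByteSource`, path, or URL of an SCF1 file.
#' @return list with `n_points`, `features` (the per-feature index), and
#'   `payload_start` (absolute offset of the first chunk).
#' @export
read_store_header <- function(x) {
  src <- as_byte_source(x)
  if (!is.null(src$cache$scf)) return(src$cache$scf)
  pre <- read_bytes(src, 0, 8)
  if (length(pre) < 8 || rawToChar(pre[1:4]) != "SCF1")
    stop("corrupt-source: not an SCF1 store")
  hlen <- rd_u32le(pre, 5)
  hdr <- read_bytes(src, 8, hlen)
  if (length(hdr) < hlen) stop("corrupt-source: truncated header")
  parsed <- jsonlite::fromJSON(rawToChar(hdr), simplifyVector = FALSE)
  out <- list(n_points = parsed$n_points, features = parsed$features,
              payload_start = 8 + hlen, source = src)
  src$cache$scf <- out
  out
}

#' Names of the features in a store
#' @param x a store path/source or parsed header.
#' @export
store_feature_names <- function(x) {
  hdr <- if (is.list(x) && !is.null(x$features)) x else read_store_header(x)
  names(hdr$features)
}

#' Lazily read one feature as a dense vector
#'
#' Fetches only the named feature's chunk (plus the header, once per source)
#' and densifies it: zeros are filled in for quantitative features, `NA` for
#' unlabeled points of categorical features.
#'
#' @param x a `ByteSource`, path, or URL of an SCF1 store.
#' @param name feature name.
#' @param header optional pre-fetched [read_store_header()] result.
#' @return numeric (float32-valued) or character vector of length `n_points`.
#' @export
read_feature <- function(x, name, header = NULL) {
  src <- as_byte_source(x)
  hdr <- header %||% read_store_header(src)
  ent <- hdr$features[[name]]
  if (is.null(ent)) stop("missing-feature: ", name)
  gz <- read_bytes(src, hdr$payload_start + ent$offset, ent$length)
  if (length(gz) < ent$length) stop("corrupt-chunk: truncated chunk for ", name)
  txt <- tryCatch(gunzip_text(gz),
                  error = function(e) stop("corrupt-chunk: ", name,
                                           " failed to decompress"),
                  warning = function(w) stop("corrupt-chunk: ", name,
                                             " failed to decompress"))
  n <- hdr$n_points
  quant <- identical(ent$kind, "quantitative")
  out <- if (quant) numeric(n) else rep(NA_character_, n)
  if (nzchar(txt)) {
    rows <- read.csv(text = txt, header = FALSE,
                     colClasses = c("integer", if (quant) "numeric"
                                    else "integer"))
    if (nrow(rows) != ent$n_nonzero)
      stop("corrupt-chunk: row count mismatch for ", name)
    if (any(rows[[1]] < 0 | rows[[1]] >= n))
      stop("corrupt-chunk: point index out of range for ", name)
    if (quant) {
      out[rows[[1]] + 1L] <- as_float32(rows[[2]])
    } else {
      labels <- unlist(ent$labels)
      out[rows[[1]] + 1L] <- labels[rows[[2]] + 1L]
    }
  } else if (ent$n_nonzero != 0) {
    stop("corrupt-chunk: empty chunk but n_nonzero > 0 for ", name)
  }
  out
}

#' Write features as a plain dense CSV
#'
#' The simple representation for small feature sets: one CSV with an `id`
#' column followed by one dense column per feature.
#'
#' @param matrix a [feature_matrix()].
#' @param path output path.
#' @param ids optional point ids (default `0:(N-1)`).
#' @export
write_features_csv <- function(matrix, path, ids = NULL) {
  stopifnot(inherits(matrix, "FeatureMatrix"))
  df <- cbind(data.frame(id = ids %||% (seq_len(matrix$n) - 1L)),
              matrix$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one feature from a plain dense CSV
#' @param path CSV written by [write_features_csv()].
#' @param name feature column name.
#' @export
read_feature_csv <- function(path, name) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!name %in% names(df)) stop("missing-feature: ", name)
  col <- df[[name]]
  if (is.numeric(col)) as_float32(col) else as.character(col)
}

#' Write a feature matrix, choosing the representation automatically
#'
#' Small feature sets (<= 50 features) go to a plain dense CSV; larger ones
#' to the chunked sparse store. Either can be forced.
#'
#' @param matrix a [feature_matrix()].
#' @param path output path (extension chosen by storage: `.csv` or `.scf`).
#' @param storage `"auto"`, `"chunked"`, or `"plain"`.
#' @param ids point ids for plain CSV mode.
#' @return list with `path` and `storage` actually used.
#' @export
write_features <- function(matrix, path, storage = c("auto", "chunked",
                                                     "plain"), ids = NULL) {
  storage <- match.arg(storage)
  if (storage == "auto")
    storage <- if (length(matrix$feature_names) <= 50L) "plain" else "chunked"
  if (storage == "plain") write_features_csv(matrix, path, ids)
  else write_store(matrix, path)
  list(path = path, storage = storage)
}
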
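# Readers/writers for the surface-data formats the pipeline consumes:
# FreeSurfer morph-data ("curv"-style) scalars, FreeSurfer binary surface
# geometry (for sphere vertex coordinates), and GIFTI overlays. All FreeSurfer
# formats are big-endian regardless of platform.

read3byte <- function(con) {
  b <- readBin(con, "integer", 3L, size = 1L, signed = FALSE)
  if (length(b) < 3L) stop("truncated file", call. = FALSE)
  b[1] * 65536L + b[2] * 256L + b[3]
}

write3byte <- function(con, x) {
  writeBin(as.integer(c(x %/% 65536, (x %/% 256) %% 256, x %% 256)),
           con, size = 1L)
}

#' Read / write FreeSurfer morph-data (curv/sulc) files
#'
#' The "new-style" binary morph-data format: a 3-byte magic `0xFFFFFF`,
#' big-endian int32 vertex/face/values-per-vertex counts, then big-endian
#' float32 per-vertex values.
#'
#' @param path file path.
#' @return `read_morph_data`: numeric vector of per-vertex values.
#' @export
read_morph_data <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  if (read3byte(con) != 0xFFFFFF) {
    stop("not a new-style FreeSurfer morph-data file", call. = FALSE)
  }
  vnum <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  readBin(con, "integer", 1L, size = 4L, endian = "big")  # face count
  vpv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (vpv != 1L) stop("unsupported values-per-vertex: ", vpv, call. = FALSE)
  vals <- readBin(con, "double", vnum, size = 4L, endian = "big")
  if (length(vals) != vnum) stop("truncated morph-data file", call. = FALSE)
  vals
}

#' @rdname read_morph_data
#' @param values numeric per-vertex values.
#' @param fnum face count to record (metadata only).
#' @export
write_morph_data <- function(path, values, fnum = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  write3byte(con, 0xFFFFFF)
  writeBin(as.integer(c(length(values), fnum, 1L)), con, size = 4L,
           endian = "big")
  writeBin(as.numeric(values), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read / write FreeSurfer binary surface geometry
#'
#' The triangle-file format (magic `0xFFFFFE`): a comment line terminated by
#' `"\n\n"`, big-endian int32 vertex and face counts, float32 coordinates and
#' int32 zero-based triangle indices.
#'
#' @param path file path.
#' @return `read_surface_geometry`: list with `vertices` (V x 3) and `faces`
#'   (F x 3, one-based).
#' @export
read_surface_geometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  if (read3byte(con) != 0xFFFFFE) {
    stop("not a FreeSurfer triangle surface file", call. = FALSE)
  }
  prev <- 0L
  repeat {
    b <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
    if (length(b) == 0L) stop("truncated surface file", call. = FALSE)
    if (b == 10L && prev == 10L) break
    prev <- b
  }
  nv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  coords <- readBin(con, "double", 3L * nv, size = 4L, endian = "big")
  faces <- readBin(con, "integer", 3L * nf, size = 4L, endian = "big")
  if (length(coords) != 3L * nv || length(faces) != 3L * nf) {
    stop("truncated surface file", call. = FALSE)
  }
  list(vertices = matrix(coords, ncol = 3L, byrow = TRUE),
       faces = matrix(faces, ncol = 3L, byrow = TRUE) + 1L)
}

#' @rdname read_surface_geometry
#' @param vertices V x 3 coordinate matrix.
#' @param faces F x 3 one-based triangle index matrix.
#' @param comment header comment string.
#' @export
write_surface_geometry <- function(path, vertices, faces,
                                   comment = "created by spherereg") {
  con <- file(path, "wb")
  on.exit(close(con))
  write3byte(con, 0xFFFFFE)
  writeBin(charToRaw(paste0(comment, "\n\n")), con)
  writeBin(as.integer(c(nrow(vertices), nrow(faces))), con, size = 4L,
           endian = "big")
  writeBin(as.numeric(t(vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(faces) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read unit-sphere vertex coordinates from a FreeSurfer sphere surface
#'
#' Reads the surface geometry and rescales every vertex to unit norm
#' (FreeSurfer spheres have radius ~100).
#'
#' @param path sphere surface file.
#' @return V x 3 matrix of unit vectors.
#' @export
read_sphere_geometry <- function(path) {
  surf <- read_surface_geometry(path)
  v <- surf$vertices
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm <= 0)) stop("degenerate vertex at the origin", call. = FALSE)
  v / nrm
}

#' Read / write a GIFTI functional overlay
#'
#' Minimal GIFTI (XML) support for per-vertex scalar overlays: ASCII,
#' Base64Binary and GZipBase64Binary encodings of float32/float64/int32 data,
#' little- or big-endian. Returns the first data array.
#'
#' @param path `.gii` file path.
#' @return numeric vector of per-vertex values.
#' @export
read_gifti_overlay <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  da <- xml2::xml_find_first(doc, ".//DataArray")
  if (is.na(xml2::xml_name(da))) stop("no DataArray in GIFTI file",
                                      call. = FALSE)
  enc <- xml2::xml_attr(da, "Encoding")
  dtype <- xml2::xml_attr(da, "DataType")
  endian <- xml2::xml_attr(da, "Endian")
  dims <- as.integer(xml2::xml_attr(da, "Dim0"))
  txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
  size <- switch(dtype,
                 "NIFTI_TYPE_FLOAT32" = 4L,
                 "NIFTI_TYPE_FLOAT64" = 8L,
                 "NIFTI_TYPE_INT32" = 4L,
                 stop("unsupported GIFTI data type: ", dtype, call. = FALSE))
  what <- if (dtype == "NIFTI_TYPE_INT32") "integer" else "double"
  end <- if (identical(endian, "BigEndian")) "big" else "little"
  vals <- switch(enc,
    "ASCII" = as.numeric(scan(text = txt, quiet = TRUE)),
    "Base64Binary" = readBin(jsonlite::base64_dec(gsub("\\s", "", txt)),
                             what, n = dims, size = size, endian = end),
    "GZipBase64Binary" = readBin(
      memDecompress(jsonlite::base64_dec(gsub("\\s", "", txt)),
                    type = "gzip"),
      what, n = dims, size = size, endian = end),
    stop("unsupported GIFTI encoding: ", enc, call. = FALSE))
  if (!is.na(dims) && length(vals) != dims) {
    stop("GIFTI data length does not match Dim0", call. = FALSE)
  }
  as.numeric(vals)
}

#' @rdname read_gifti_overlay
#' @param values numeric per-vertex values to write (ASCII encoding).
#' @param intent NIFTI intent string.
#' @export
write_gifti_overlay <- function(path, values,
                                intent = "NIFTI_INTENT_NONE") {
  txt <- paste(format(as.numeric(values), digits = 9, trim = TRUE),
               collapse = "\n")
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="1">\n',
    '<DataArray Intent="', intent, '" DataType="NIFTI_TYPE_FLOAT32" ',
    'ArrayIndexingOrder="RowMajorOrder" Dimensionality="1" Dim0="',
    length(values), '" Encoding="ASCII" Endian="LittleEndian" ',
    'ExternalFileName="" ExternalFileOffset="">\n',
    '<Data>', txt, '</Data>\n</DataArray>\n</GIFTI>\n')
  writeLines(xml, path)
  invisible(path)
}

check_vertex_count <- function(n_coords, n_values, what = "overlay") {
  if (n_coords != n_values) {
    stop(sprintf("vertex count mismatch: geometry has %d vertices but %s has %d values",
                 n_coords, what, n_values), call. = FALSE)
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Feature container: the package's on-disk exchange format. One file holds
# the grid (grid/theta, grid/phi), named feature sets with channel-role and
# validity attributes, optional deformation fields (with unit and axis-order
# attributes), and free-form metadata.
# ---------------------------------------------------------------------------

#' Write / read the feature container
#'
#' Serializes grids, feature maps and deformation fields to a single file.
#' Deformations record their units (`"grid_cells"`) and axis order
#' (`"lat,lon"`).
#'
#' @param path file path.
#' @param grid a [make_grid()] object.
#' @param features named list of [feature_map()] objects.
#' @param deformations optional named list of [deformation_field()] or
#'   [velocity_field()] objects.
#' @param metadata optional list of metadata entries.
#' @return `read_feature_container` returns a list with `grid`, `features`,
#'   `deformations`, `metadata`.
#' @export
write_feature_container <- function(path, grid, features = list(),
                                    deformations = list(),
                                    metadata = list()) {
  stopifnot(inherits(grid, "sphere_grid"))
  obj <- list(
    format = "spherereg-container",
    version = 1L,
    grid = list(theta = grid$theta, phi = grid$phi),
    features = lapply(features, function(fm) {
      stopifnot(inherits(fm, "feature_map"))
      list(values = fm$values, channel_roles = fm$channel_roles,
           valid_mask = fm$valid_mask)
    }),
    deformations = lapply(deformations, function(d) {
      arr <- if (inherits(d, "deformation_field")) d$u else d$v
      list(values = arr, units = "grid_cells", axes = "lat,lon",
           kind = if (inherits(d, "velocity_field")) "velocity"
                  else "displacement")
    }),
    metadata = metadata
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_feature_container
#' @export
read_feature_container <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (!identical(obj$format, "spherereg-container")) {
    stop("not a spherereg feature container", call. = FALSE)
  }
  grid <- make_grid(length(obj$grid$theta), length(obj$grid$phi))
  features <- lapply(obj$features, function(f) {
    feature_map(grid, f$values, f$channel_roles, f$valid_mask)
  })
  deformations <- lapply(obj$deformations, function(d) {
    if (identical(d$kind, "velocity")) velocity_field(grid, d$values)
    else deformation_field(grid, d$values)
  })
  list(grid = grid, features = features, deformations = deformations,
       metadata = obj$metadata)
}

#' Write / read a synthetic cohort container
#'
#' Stores a full [make_cohort()] result (subject maps, ground-truth fields,
#' true atlas, configuration) in one file.
#'
#' @param cohort a [make_cohort()] result.
#' @param path file path.
#' @return `read_cohort` returns the `synthetic_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  saveRDS(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readRDS(path)
  if (!inherits(x, "synthetic_cohort")) {
    stop("not a cohort container", call. = FALSE)
  }
  x
}
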
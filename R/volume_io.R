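#' 8-bit voxel volume
#'
#' Container for a 3D grid of 8-bit gray-level intensities with a physical
#' voxel size. The array uses the R-native layout `dim = c(ny, nx, nz)`:
#' the third index is the slice position along the specimen long axis, so
#' `vol$data[, , k]` is the k-th cross-sectional slice (1-based). Intensities
#' are dimensionless gray levels, integers in `[0, 255]`.
#'
#' @param data 3D integer array of gray levels in `[0, 255]`.
#' @param voxel_size_um positive physical voxel edge length in micrometres.
#' @return An object of class `voxel_volume`: a list with elements `data`
#'   and `voxel_size_um`.
#' @examples
#' vol <- voxel_volume(array(100L, dim = c(4, 4, 2)), voxel_size_um = 9)
#' dim(vol$data)
#' @export
voxel_volume <- function(data, voxel_size_um) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_ctx("`data` must be a 3D array", "cortexture_format_error")
  }
  if (any(dim(data) < 1L)) {
    abort_ctx("all three volume dimensions must be >= 1",
              "cortexture_format_error")
  }
  if (anyNA(data)) {
    abort_ctx("volume contains missing intensities", "cortexture_domain_error")
  }
  if (!is.integer(data)) {
    if (any(data != floor(data))) {
      abort_ctx("intensities must be integers", "cortexture_domain_error")
    }
    storage.mode(data) <- "integer"
  }
  rng <- range(data)
  if (rng[1] < 0L || rng[2] > 255L) {
    abort_ctx(sprintf("intensities must lie in [0, 255]; found range [%d, %d]",
                      rng[1], rng[2]),
              "cortexture_domain_error")
  }
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0) {
    abort_ctx("`voxel_size_um` must be a single positive number",
              "cortexture_domain_error")
  }
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d pixels, %d slices, voxel %.3g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  if (!file.exists(path)) return(NULL)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Reject any slice image that is not single-channel 8-bit.
check_depth <- function(bits, path) {
  if (!is.null(bits) && !identical(as.integer(bits), 8L)) {
    abort_ctx(sprintf("unsupported bit depth %d in '%s'; only 8-bit input is accepted",
                      as.integer(bits), path),
              "cortexture_depth_error")
  }
}

read_slice <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    check_depth(attr(img, "bits.per.sample"), path)
    m <- matrix(as.integer(img), nrow(img), ncol(img))
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    check_depth(info$bit.depth, path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]   # drop extra channels
    m <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  } else {
    abort_ctx(sprintf("unsupported slice format '%s'", ext),
              "cortexture_format_error")
  }
  m
}

#' Read an image volume
#'
#' Accepts three on-disk layouts: a multi-page 8-bit TIFF, a directory of
#' equally sized single-slice TIFF/PNG files (slices ordered
#' lexicographically by filename), or a raw 8-bit binary with a JSON
#' sidecar giving `{nx, ny, nz, voxel_size_um}`. Intensities are read
#' exactly as stored; no rescaling or normalization is ever applied.
#'
#' The voxel size is taken from `metadata` (a JSON sidecar path) when
#' given, else from `<path>.json` if present, else from `voxel_size_um`.
#'
#' @param path file or directory to read.
#' @param metadata optional path to a JSON metadata sidecar.
#' @param voxel_size_um fallback voxel size when no sidecar exists.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, metadata = NULL, voxel_size_um = NULL) {
  meta <- NULL
  if (!is.null(metadata)) {
    if (!file.exists(metadata)) {
      abort_ctx(sprintf("metadata sidecar '%s' not found", metadata),
                "cortexture_io_error")
    }
    meta <- jsonlite::read_json(metadata, simplifyVector = TRUE)
  }

  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) {
      abort_ctx(sprintf("no TIFF/PNG slices found in '%s'", path),
                "cortexture_format_error")
    }
    files <- files[order(basename(files), method = "radix")]
    slices <- lapply(files, read_slice)
    dims <- vapply(slices, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      abort_ctx("slice images differ in size (ragged stack)",
                "cortexture_format_error")
    }
    data <- array(0L, dim = c(dims[1, 1], dims[2, 1], length(slices)))
    for (k in seq_along(slices)) data[, , k] <- slices[[k]]
    if (is.null(meta)) meta <- read_sidecar(file.path(path, "volume.json"))
  } else if (file.exists(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
      pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      check_depth(attr(pages[[1]], "bits.per.sample"), path)
      dims <- vapply(pages, dim, integer(2))
      if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
        abort_ctx("TIFF pages differ in size (ragged stack)",
                  "cortexture_format_error")
      }
      data <- array(0L, dim = c(dims[1, 1], dims[2, 1], length(pages)))
      for (k in seq_along(pages)) {
        data[, , k] <- matrix(as.integer(pages[[k]]), dims[1, 1], dims[2, 1])
      }
      if (is.null(meta)) meta <- read_sidecar(sidecar_path(path))
    } else if (ext %in% c("raw", "bin")) {
      if (is.null(meta)) meta <- read_sidecar(sidecar_path(path))
      if (is.null(meta) || !all(c("nx", "ny", "nz") %in% names(meta))) {
        abort_ctx("raw input requires a JSON sidecar with nx, ny, nz and voxel_size_um",
                  "cortexture_format_error")
      }
      n <- as.integer(meta$nx) * as.integer(meta$ny) * as.integer(meta$nz)
      bytes <- readBin(path, what = "integer", n = n + 1L, size = 1L,
                       signed = FALSE)
      if (length(bytes) != n) {
        abort_ctx(sprintf("raw file length %d does not match nx*ny*nz = %d",
                          length(bytes), n),
                  "cortexture_format_error")
      }
      # layout: first array index fastest (column-major), slices last
      data <- array(as.integer(bytes),
                    dim = c(as.integer(meta$ny), as.integer(meta$nx),
                            as.integer(meta$nz)))
    } else {
      abort_ctx(sprintf("unsupported volume format '%s'", ext),
                "cortexture_format_error")
    }
  } else {
    abort_ctx(sprintf("path '%s' does not exist", path), "cortexture_io_error")
  }

  vs <- if (!is.null(meta) && !is.null(meta$voxel_size_um)) {
    as.numeric(meta$voxel_size_um)
  } else {
    voxel_size_um
  }
  if (is.null(vs)) {
    abort_ctx("voxel size unknown: supply a sidecar or `voxel_size_um`",
              "cortexture_format_error")
  }
  voxel_volume(data, vs)
}

#' Write an image volume
#'
#' Writes a multi-page 8-bit grayscale TIFF plus a JSON sidecar
#' (`<path>.json`) carrying the voxel size and dimensions, so that
#' [read_volume()] inverts the write exactly.
#'
#' @param vol a [voxel_volume()].
#' @param path output TIFF path; parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!dir.exists(dirname(path))) {
    abort_ctx(sprintf("directory '%s' does not exist", dirname(path)),
              "cortexture_io_error")
  }
  d <- dim(vol$data)
  pages <- lapply(seq_len(d[3]), function(k) vol$data[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(nx = d[2], ny = d[1], nz = d[3], voxel_size_um = vol$voxel_size_um),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write tabular results as CSV
#'
#' Accepts a data frame or a list of records sharing one schema (texture
#' profiles, comparison rows, worked-example rows) and writes an RFC 4180
#' CSV with a header row and deterministic column order. Numeric values are
#' written at full double precision (15 significant digits).
#'
#' @param rows data frame, or list of named lists / one-row data frames
#'   with identical field names.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  df <- as_record_frame(rows)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

as_record_frame <- function(rows) {
  if (is.data.frame(rows)) return(rows)
  if (!is.list(rows)) {
    abort_ctx("`rows` must be a data frame or a list of records",
              "cortexture_schema_error")
  }
  if (length(rows) == 0L) return(data.frame())
  recs <- lapply(rows, function(r) {
    if (inherits(r, "texture_profile")) r <- unclass(r)
    if (is.data.frame(r)) r <- as.list(r)
    r
  })
  nm <- names(recs[[1]])
  if (is.null(nm)) {
    abort_ctx("records must have named fields", "cortexture_schema_error")
  }
  for (r in recs) {
    if (!identical(names(r), nm)) {
      abort_ctx("records do not share a common schema",
                "cortexture_schema_error")
    }
  }
  do.call(rbind, lapply(recs, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
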
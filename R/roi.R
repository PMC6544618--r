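#' Region-of-interest specification
#'
#' Describes the mid-diaphysis slab ROI: a slab of fixed physical length
#' along the specimen long axis, centered at a relative long-axis position,
#' with an intensity threshold separating cortical bone from marrow and
#' background. The default length of 0.5 mm at the mid-plane matches
#' standard cortical-bone morphometry practice; the default threshold of 50
#' gray levels comfortably separates near-zero marrow/background from
#' cortical intensities (around 100).
#'
#' @param length_mm slab extent along the long axis in millimetres (> 0).
#' @param center_fraction relative long-axis position of the slab center in
#'   (0, 1); 0.5 = mid-plane.
#' @param mask_threshold minimum gray level counted as bone, in `[0, 255]`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(length_mm = 0.5, center_fraction = 0.5,
                     mask_threshold = 50L) {
  if (!is.numeric(length_mm) || length_mm <= 0) {
    abort_ctx("`length_mm` must be positive", "cortexture_domain_error")
  }
  if (!is.numeric(center_fraction) || center_fraction <= 0 ||
      center_fraction >= 1) {
    abort_ctx("`center_fraction` must lie in (0, 1)", "cortexture_domain_error")
  }
  if (!is.numeric(mask_threshold) || mask_threshold < 0 ||
      mask_threshold > 255) {
    abort_ctx("`mask_threshold` must lie in [0, 255]", "cortexture_domain_error")
  }
  structure(list(length_mm = as.numeric(length_mm),
                 center_fraction = as.numeric(center_fraction),
                 mask_threshold = as.integer(mask_threshold)),
            class = "roi_spec")
}

#' Select the ROI slab slice range
#'
#' Converts the physical slab length to a slice count
#' (`round-half-up(length_mm * 1000 / voxel_size_um)`, minimum 1) and
#' centers the slab on slice `floor(center_fraction * nz)` (counting slices
#' from 0). A slab that does not fit inside the volume is an error; the
#' range is never clipped silently.
#'
#' @param vol a [voxel_volume()].
#' @param spec an [roi_spec()].
#' @return Integer vector `c(first, last)`: 1-based inclusive slice range.
#' @examples
#' vol <- voxel_volume(array(0L, dim = c(2, 2, 200)), voxel_size_um = 9)
#' select_slab(vol, roi_spec(length_mm = 0.5))
#' @export
select_slab <- function(vol, spec) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(spec, "roi_spec"))
  nz <- dim(vol$data)[3]
  n_slices <- max(1L, as.integer(floor(spec$length_mm * 1000 /
                                         vol$voxel_size_um + 0.5)))
  center0 <- as.integer(floor(spec$center_fraction * nz))  # 0-based center
  start0 <- center0 - n_slices %/% 2L
  if (start0 < 0L || start0 + n_slices > nz) {
    abort_ctx(sprintf(
      "slab of %d slices centered at slice %d does not fit in %d slices",
      n_slices, center0, nz), "cortexture_bounds_error")
  }
  c(first = start0 + 1L, last = start0 + n_slices)
}

#' Extract the ROI pixel population
#'
#' All voxel intensities inside the slab selected by [select_slab()] whose
#' gray level is at least `spec$mask_threshold`, in deterministic
#' array-native order (row, then column, then slice).
#'
#' @inheritParams select_slab
#' @return Integer vector of gray levels.
#' @export
extract_roi_pixels <- function(vol, spec) {
  rng <- select_slab(vol, spec)
  slab <- vol$data[, , rng[1]:rng[2], drop = FALSE]
  px <- slab[slab >= spec$mask_threshold]
  if (length(px) == 0L) {
    abort_ctx(sprintf("empty ROI: no voxels at or above threshold %d",
                      spec$mask_threshold),
              "cortexture_empty_roi_error")
  }
  as.integer(px)
}

#' Read an ROI specification from YAML or JSON
#'
#' Recognized keys: `length_mm`, `center_fraction`, `mask_threshold`;
#' unknown keys are rejected.
#'
#' @param path config file ending in `.yaml`/`.yml` or `.json`.
#' @return An [roi_spec()].
#' @export
read_roi_spec <- function(path) {
  cfg <- read_config_file(path)
  known <- c("length_mm", "center_fraction", "mask_threshold")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    abort_ctx(sprintf("unknown ROI config key(s): %s",
                      paste(unknown, collapse = ", ")),
              "cortexture_config_error")
  }
  do.call(roi_spec, cfg)
}

read_config_file <- function(path) {
  if (!file.exists(path)) {
    abort_ctx(sprintf("config file '%s' not found", path),
              "cortexture_config_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort_ctx(sprintf("unsupported config format '%s'", ext),
              "cortexture_config_error")
  }
}
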
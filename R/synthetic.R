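# Skew-normal machinery: the generator needs a three-parameter family whose
# first three moments can be matched to published group summaries; the
# skew-normal covers |skewness| < 0.9953, which both diet groups satisfy.

b_const <- sqrt(2 / pi)
max_sn_skewness <- 0.5 * (4 - pi) * b_const^3 / (1 - b_const^2)^1.5  # ~0.99527

#' Skew-normal parameters from target moments
#'
#' Inverts the standard skew-normal moment formulas: given a target mean,
#' standard deviation and skewness, returns the (location, scale, shape)
#' parametrization whose analytic moments equal the targets. The shape is
#' obtained in closed form from the skewness; scale and location follow.
#' Only `|skewness| < 0.99527` (the supremum of the family) is attainable.
#'
#' @param mean target mean (gray levels).
#' @param sd target standard deviation (> 0).
#' @param skewness target skewness, `|skewness| < 0.99527`.
#' @return List with `location`, `scale`, `shape`.
#' @examples
#' skew_normal_from_moments(98.1, 17.8, -0.906)
#' @export
skew_normal_from_moments <- function(mean, sd, skewness) {
  if (!is.numeric(sd) || sd <= 0) {
    abort_ctx("`sd` must be positive", "cortexture_domain_error")
  }
  if (abs(skewness) >= max_sn_skewness) {
    abort_ctx(sprintf(
      "skewness %.4f unattainable: the skew-normal family is bounded by |skewness| < %.5f",
      skewness, max_sn_skewness), "cortexture_unattainable_skewness_error")
  }
  # solve m = b*delta from skewness = (4-pi)/2 * m^3 / (1-m^2)^(3/2)
  c3 <- 2 * skewness / (4 - pi)
  cc <- sign(c3) * abs(c3)^(1 / 3)
  m <- cc / sqrt(1 + cc^2)
  delta <- m / b_const
  scale <- sd / sqrt(1 - m^2)
  location <- mean - scale * m
  shape <- delta / sqrt(1 - delta^2)
  list(location = location, scale = scale, shape = shape)
}

# Analytic mean/sd/skewness of a skew-normal; used by tests as the
# round-trip oracle and kept exported for transparency.

#' Analytic moments of a skew-normal distribution
#'
#' @param location,scale,shape skew-normal parameters (`scale > 0`).
#' @return List with `mean`, `sd`, `skewness`.
#' @export
skew_normal_moments <- function(location, scale, shape) {
  stopifnot(scale > 0)
  delta <- shape / sqrt(1 + shape^2)
  m <- b_const * delta
  mu <- location + scale * m
  s <- scale * sqrt(1 - m^2)
  g1 <- 0.5 * (4 - pi) * m^3 / (1 - m^2)^1.5
  list(mean = mu, sd = s, skewness = g1)
}

# Draws via the bivariate-normal construction: delta*|Z0| + sqrt(1-d^2)*Z1.
rskewnorm <- function(n, location, scale, shape) {
  delta <- shape / sqrt(1 + shape^2)
  z0 <- rnorm(n)
  z1 <- rnorm(n)
  location + scale * (delta * abs(z0) + sqrt(1 - delta^2) * z1)
}

#' Synthetic cortical-bone group specification
#'
#' Target moments and geometry for one diet arm of the synthetic cohort.
#' The defaults returned by [default_group_specs()] match the published
#' group summaries: control (mean 98.1, sigma 17.8, skewness -0.906) and
#' low-magnesium (105, 12.6, -0.729), seven specimens each.
#'
#' Geometry: an annular cylinder (cortical shell) of `outer_radius` voxels
#' with a marrow canal of `canal_radius` voxels, extending over `n_slices`
#' slices; canal and background voxels are 0. `specimen_jitter_sd` adds an
#' optional between-specimen shift of the target mean (gray levels); the
#' default 0 keeps every specimen exactly on target.
#'
#' @param label group label.
#' @param target_mean,target_sigma,target_skewness intensity moments the
#'   shell voxels are drawn to match.
#' @param n_specimens specimens in the group.
#' @param outer_radius,canal_radius shell geometry in voxels
#'   (`outer_radius > canal_radius >= 0`).
#' @param n_slices slab length in slices.
#' @param voxel_size_um physical voxel size.
#' @param specimen_jitter_sd SD of a per-specimen mean shift (gray levels).
#' @param seed base seed; per-specimen sub-seeds are derived from it.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(label, target_mean, target_sigma, target_skewness,
                       n_specimens = 7L, outer_radius = 40, canal_radius = 20,
                       n_slices = 56L, voxel_size_um = 9,
                       specimen_jitter_sd = 0, seed = 1L) {
  if (target_sigma <= 0) {
    abort_ctx("`target_sigma` must be positive", "cortexture_domain_error")
  }
  if (abs(target_skewness) >= max_sn_skewness) {
    abort_ctx(sprintf("|target_skewness| must be < %.5f", max_sn_skewness),
              "cortexture_unattainable_skewness_error")
  }
  if (outer_radius <= canal_radius || canal_radius < 0) {
    abort_ctx("need outer_radius > canal_radius >= 0",
              "cortexture_degenerate_geometry_error")
  }
  structure(list(label = as.character(label),
                 target_mean = target_mean, target_sigma = target_sigma,
                 target_skewness = target_skewness,
                 n_specimens = as.integer(n_specimens),
                 outer_radius = outer_radius, canal_radius = canal_radius,
                 n_slices = as.integer(n_slices),
                 voxel_size_um = voxel_size_um,
                 specimen_jitter_sd = specimen_jitter_sd,
                 seed = as.integer(seed)),
            class = "group_spec")
}

#' Default two-arm cohort specifications
#'
#' Control and low-magnesium group specs with the published intensity
#' moments, seven specimens per arm.
#'
#' @param seed base seed; the two arms use `seed` and `seed + 1`.
#' @param ... overrides forwarded to both [group_spec()] calls
#'   (e.g. geometry for smaller test volumes).
#' @return List with elements `control` and `low_mg`.
#' @export
default_group_specs <- function(seed = 1L, ...) {
  list(
    control = group_spec("control", 98.1, 17.8, -0.906, seed = seed, ...),
    low_mg = group_spec("low_mg", 105, 12.6, -0.729, seed = seed + 1L, ...)
  )
}

specimen_seed <- function(g, specimen_index) {
  as.integer((as.numeric(g$seed) * 10007 + specimen_index * 7919) %% 2147483629)
}

shell_mask_2d <- function(outer_radius, canal_radius) {
  n <- 2L * as.integer(ceiling(outer_radius)) + 5L
  ctr <- (n + 1) / 2
  d2 <- outer(seq_len(n), seq_len(n),
              function(i, j) (i - ctr)^2 + (j - ctr)^2)
  d2 <= outer_radius^2 & d2 > canal_radius^2
}

#' Generate one synthetic cortical-bone volume
#'
#' An annular-cylinder cortical shell whose voxels are independent draws
#' from the skew-normal matched to the group's target moments, rounded
#' half-to-even and clipped to `[0, 255]`; canal and background are 0.
#' Deterministic given `(seed, specimen_index)`. The returned volume
#' carries a logical `shell_mask` attribute marking shell voxels.
#'
#' @param g a [group_spec()].
#' @param specimen_index 1-based specimen number within the group.
#' @return A [voxel_volume()] with attribute `shell_mask`.
#' @export
generate_cortical_volume <- function(g, specimen_index = 1L) {
  stopifnot(inherits(g, "group_spec"))
  mask <- shell_mask_2d(g$outer_radius, g$canal_radius)
  n_shell <- sum(mask)
  if (n_shell == 0L) {
    abort_ctx("geometry leaves no shell voxels",
              "cortexture_degenerate_geometry_error")
  }
  set.seed(specimen_seed(g, specimen_index))
  mu <- g$target_mean +
    if (g$specimen_jitter_sd > 0) rnorm(1, 0, g$specimen_jitter_sd) else 0
  sn <- skew_normal_from_moments(mu, g$target_sigma, g$target_skewness)
  n <- dim(mask)[1]
  data <- array(0L, dim = c(n, n, g$n_slices))
  mask3 <- array(mask, dim = dim(data))
  draws <- rskewnorm(n_shell * g$n_slices, sn$location, sn$scale, sn$shape)
  data[mask3] <- as.integer(pmin(pmax(round(draws), 0), 255))
  vol <- voxel_volume(data, g$voxel_size_um)
  attr(vol, "shell_mask") <- mask3
  vol
}

#' Generate a two-arm synthetic cohort
#'
#' @param control,treated [group_spec()]s with distinct labels.
#' @return List with `control` and `treated` (lists of volumes) and
#'   `manifest` (data frame: `specimen_id`, `group`, `seed`).
#' @export
generate_cohort <- function(control, treated) {
  stopifnot(inherits(control, "group_spec"), inherits(treated, "group_spec"))
  if (identical(control$label, treated$label)) {
    abort_ctx("the two groups must have distinct labels",
              "cortexture_config_error")
  }
  gen_arm <- function(g) {
    lapply(seq_len(g$n_specimens), function(i) generate_cortical_volume(g, i))
  }
  vols <- list(control = gen_arm(control), treated = gen_arm(treated))
  manifest <- do.call(rbind, lapply(list(control, treated), function(g) {
    data.frame(
      specimen_id = sprintf("%s_%02d", g$label, seq_len(g$n_specimens)),
      group = g$label,
      seed = vapply(seq_len(g$n_specimens), function(i) specimen_seed(g, i),
                    integer(1)),
      stringsAsFactors = FALSE)
  }))
  c(vols, list(manifest = manifest))
}

#' Bone-mineral-density phantom specification
#'
#' Five parallel cylindrical inserts of known hydroxyapatite densities in a
#' uniform base material, emulating a calibration phantom. Densities map
#' linearly to gray levels via `gray = slope * density + intercept`; the
#' default mapping sends 200 -> 60 and 1000 -> 220 mg-HA/cm^3, keeping all
#' inserts on the 8-bit scale. Additive Gaussian noise (rounded, clipped)
#' is applied everywhere.
#'
#' @param densities strictly increasing insert densities (mg-HA/cm^3).
#' @param slope,intercept density-to-gray mapping.
#' @param noise_sigma Gaussian noise SD in gray levels.
#' @param insert_radius,insert_length insert geometry in voxels.
#' @param background_level base-material gray level.
#' @param voxel_size_um physical voxel size.
#' @param seed RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(densities = c(200, 400, 600, 800, 1000),
                         slope = 0.2, intercept = 20, noise_sigma = 10,
                         insert_radius = 8L, insert_length = 20L,
                         background_level = 30L, voxel_size_um = 9,
                         seed = 1L) {
  if (any(diff(densities) <= 0)) {
    abort_ctx("insert densities must be strictly increasing",
              "cortexture_config_error")
  }
  gray <- slope * densities + intercept
  if (any(gray < 0) || any(gray > 255)) {
    abort_ctx("density-to-gray mapping leaves the 8-bit range",
              "cortexture_config_error")
  }
  if (noise_sigma < 0) {
    abort_ctx("`noise_sigma` must be >= 0", "cortexture_config_error")
  }
  structure(list(densities = densities, slope = slope, intercept = intercept,
                 noise_sigma = noise_sigma,
                 insert_radius = as.integer(insert_radius),
                 insert_length = as.integer(insert_length),
                 background_level = as.integer(background_level),
                 voxel_size_um = voxel_size_um, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic five-insert BMD phantom
#'
#' Inserts are laid out side by side along x, each a cylinder along the
#' slice axis at its mapped mean gray level; base material fills the rest.
#' Gaussian noise is added everywhere, then values are rounded and clipped
#' to `[0, 255]`.
#'
#' @param p a [phantom_spec()].
#' @return List with `volume` (a [voxel_volume()]), `labels` (integer array
#'   of the same dimensions; 0 = base material, `i` = i-th insert) and
#'   `insert_table` (data frame: `insert`, `density`, `mapped_gray`).
#' @export
generate_bmd_phantom <- function(p) {
  stopifnot(inherits(p, "phantom_spec"))
  n_ins <- length(p$densities)
  r <- p$insert_radius
  gap <- max(4L, r %/% 2L)
  pitch <- 2L * r + gap
  nx <- n_ins * pitch + gap
  ny <- 2L * r + 2L * gap
  nz <- p$insert_length + 4L
  labels <- array(0L, dim = c(ny, nx, nz))
  cy <- (ny + 1) / 2
  z_range <- 3:(2L + p$insert_length)
  for (i in seq_len(n_ins)) {
    cx <- gap + (i - 1L) * pitch + r + 0.5
    disk <- outer(seq_len(ny), seq_len(nx),
                  function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
    labels[, , z_range][array(disk, dim = c(ny, nx, length(z_range)))] <- i
  }
  gray <- p$slope * p$densities + p$intercept
  mean_map <- array(p$background_level, dim = dim(labels))
  for (i in seq_len(n_ins)) mean_map[labels == i] <- gray[i]
  set.seed(p$seed)
  noisy <- mean_map +
    if (p$noise_sigma > 0) rnorm(length(mean_map), 0, p$noise_sigma) else 0
  data <- array(as.integer(pmin(pmax(round(noisy), 0), 255)),
                dim = dim(labels))
  list(volume = voxel_volume(data, p$voxel_size_um),
       labels = labels,
       insert_table = data.frame(insert = seq_len(n_ins),
                                 density = p$densities,
                                 mapped_gray = gray))
}
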
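#' Normalized gray-level histogram
#'
#' Probability vector `p` over the 256 gray levels `k = 0..255`. Histograms
#' built from pixels always sum to one; analytic histograms produced by
#' [discretize()] with `renormalize = FALSE` carry `n_pixels = 0` and may
#' sum to less than one (probability mass truncated at the 8-bit range).
#'
#' @param p numeric vector of 256 non-negative bin values for levels 0..255.
#' @param n_pixels number of contributing pixels; 0 marks an analytic
#'   histogram.
#' @return An object of class `gray_histogram`.
#' @export
gray_histogram <- function(p, n_pixels = 0L) {
  if (length(p) != 256L || any(!is.finite(p))) {
    abort_ctx("`p` must be a finite numeric vector of length 256",
              "cortexture_domain_error")
  }
  if (any(p < 0)) {
    abort_ctx("histogram bins must be non-negative", "cortexture_domain_error")
  }
  n_pixels <- as.integer(n_pixels)
  if (n_pixels > 0L && abs(sum(p) - 1) > 1e-9) {
    abort_ctx("pixel histogram probabilities must sum to 1 within 1e-9",
              "cortexture_domain_error")
  }
  structure(list(p = as.numeric(p), n_pixels = n_pixels),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  cat(sprintf("<gray_histogram> %d pixels, %d occupied bins, mass %.6f\n",
              x$n_pixels, sum(x$p > 0), sum(x$p)))
  invisible(x)
}

check_pixels <- function(pixels) {
  if (length(pixels) == 0L) {
    abort_ctx("empty ROI: no pixels to analyse", "cortexture_empty_roi_error")
  }
  if (anyNA(pixels) || any(pixels != floor(pixels))) {
    abort_ctx("pixels must be integer gray levels", "cortexture_domain_error")
  }
  bad <- pixels < 0 | pixels > 255
  if (any(bad)) {
    abort_ctx(sprintf("gray level %d outside [0, 255]",
                      as.integer(pixels[which(bad)[1]])),
              "cortexture_domain_error")
  }
  as.integer(pixels)
}

#' Build a normalized histogram from pixel gray levels
#'
#' `p[k] = count(k) / N` over the 256 levels of the 8-bit range.
#'
#' @param pixels integer gray levels in `[0, 255]`; must be nonempty.
#' @return A [gray_histogram()] with `n_pixels = length(pixels)`.
#' @examples
#' h <- build_histogram(c(0L, 255L))
#' h$p[c(1, 256)]   # 0.5 at levels 0 and 255
#' @export
build_histogram <- function(pixels) {
  pixels <- check_pixels(pixels)
  counts <- tabulate(pixels + 1L, nbins = 256L)
  gray_histogram(counts / length(pixels), n_pixels = length(pixels))
}

levels_k <- 0:255

#' Histogram mean (first-order moment)
#'
#' The average gray level, `sum(k * p[k])`. Equals the arithmetic mean of
#' the source pixels exactly when the histogram was built from pixels.
#'
#' @param h a [gray_histogram()].
#' @return Mean gray level in `[0, 255]`.
#' @export
hist_mean <- function(h) {
  stopifnot(inherits(h, "gray_histogram"))
  sum(levels_k * h$p) / sum(h$p)
}

#' Histogram standard deviation (sigma)
#'
#' Probability-weighted population standard deviation about [hist_mean()];
#' no sample-size correction is applied.
#'
#' @inheritParams hist_mean
#' @return Standard deviation in gray levels, `>= 0`.
#' @export
hist_sigma <- function(h) {
  stopifnot(inherits(h, "gray_histogram"))
  w <- h$p / sum(h$p)
  m <- sum(levels_k * w)
  sqrt(sum((levels_k - m)^2 * w))
}

#' Histogram skewness
#'
#' Third standardized central moment of the gray-level distribution. A
#' negative value indicates a distribution whose bulk sits above the mean
#' with a longer tail toward low gray levels (low-density bone voxels).
#'
#' @inheritParams hist_mean
#' @return Dimensionless skewness.
#' @export
hist_skewness <- function(h) {
  stopifnot(inherits(h, "gray_histogram"))
  w <- h$p / sum(h$p)
  m <- sum(levels_k * w)
  s <- sqrt(sum((levels_k - m)^2 * w))
  if (s == 0) {
    abort_ctx("skewness undefined: histogram has zero sigma",
              "cortexture_degenerate_error")
  }
  sum((levels_k - m)^3 * w) / s^3
}

#' Histogram excess kurtosis
#'
#' Fourth standardized central moment minus 3, so a Gaussian-shaped
#' histogram scores 0 (leptokurtic > 0, platykurtic < 0).
#'
#' @inheritParams hist_mean
#' @return Dimensionless excess kurtosis.
#' @export
hist_kurtosis <- function(h) {
  stopifnot(inherits(h, "gray_histogram"))
  w <- h$p / sum(h$p)
  m <- sum(levels_k * w)
  s2 <- sum((levels_k - m)^2 * w)
  if (s2 == 0) {
    abort_ctx("kurtosis undefined: histogram has zero sigma",
              "cortexture_degenerate_error")
  }
  sum((levels_k - m)^4 * w) / s2^2 - 3
}

#' Histogram energy (uniformity)
#'
#' `sum(p[k]^2)`. The maximum value 1 is attained exactly when all pixels
#' share one gray level; a spread-out histogram scores close to 0.
#'
#' @inheritParams hist_mean
#' @return Energy in `(0, 1]` for a pixel histogram.
#' @export
hist_energy <- function(h) {
  stopifnot(inherits(h, "gray_histogram"))
  sum(h$p^2)
}

#' Histogram entropy
#'
#' `-sum(p[k] * log(p[k]))` with the convention `0 * log 0 = 0`. The
#' default uses the natural logarithm (nats); `base = "log2"` gives bits.
#' Zero for a single-level image; at most `log(256)` (uniform histogram).
#'
#' @inheritParams hist_mean
#' @param base `"natural"` (nats, default) or `"log2"` (bits).
#' @return Non-negative entropy.
#' @export
hist_entropy <- function(h, base = c("natural", "log2")) {
  stopifnot(inherits(h, "gray_histogram"))
  base <- match.arg(base)
  p <- h$p[h$p > 0]
  e <- -sum(p * log(p))
  if (base == "log2") e / log(2) else e
}

#' Nakagami parameter of a gray-level population
#'
#' The concentration statistic `E(X^2)^2 / Var(X^2)` of the intensity
#' population, borrowed from ultrasound backscatter analysis as a proxy for
#' tissue scatter characteristics. Population (divide-by-N) moments are
#' used throughout, so the pixel path and the histogram path agree to
#' numerical precision.
#'
#' @param x integer pixel gray levels, or a [gray_histogram()].
#' @return Dimensionless Nakagami parameter.
#' @export
nakagami_parameter <- function(x) {
  if (inherits(x, "gray_histogram")) {
    w <- x$p / sum(x$p)
    e2 <- sum(levels_k^2 * w)
    e4 <- sum(levels_k^4 * w)
  } else {
    px <- as.numeric(check_pixels(x))
    e2 <- mean(px^2)
    e4 <- mean(px^4)
  }
  v <- e4 - e2^2
  if (v <= 0) {
    abort_ctx("Nakagami parameter undefined: Var(X^2) is zero (constant input)",
              "cortexture_degenerate_error")
  }
  e2^2 / v
}

#' Fraction of histogram mass at or below a gray-level cutoff
#'
#' Sums `p[k]` for `k <= max_level`. The default cutoff 64 is the first
#' quartile of the 8-bit range, so the result proxies the fraction of
#' low-density bone voxels in the ROI.
#'
#' @inheritParams hist_mean
#' @param max_level inclusive gray-level cutoff in `[0, 255]`.
#' @return Proportion in `[0, 1]`.
#' @export
quartile_fraction <- function(h, max_level = 64L) {
  stopifnot(inherits(h, "gray_histogram"))
  if (max_level < 0 || max_level > 255) {
    abort_ctx("`max_level` must lie in [0, 255]", "cortexture_domain_error")
  }
  sum(h$p[seq_len(max_level + 1L)])
}

#' Full first-order texture profile of a pixel population
#'
#' One histogram pass producing all seven texture parameters plus the
#' below-first-quartile fraction.
#'
#' @param pixels integer gray levels; nonempty and non-constant.
#' @param entropy_base passed to [hist_entropy()].
#' @param quartile_max_level passed to [quartile_fraction()].
#' @return A `texture_profile`: named list with fields `mean`, `sigma`,
#'   `skewness`, `kurtosis`, `energy`, `entropy`, `nakagami`,
#'   `quartile_fraction`.
#' @examples
#' set.seed(1)
#' texture_profile(sample(60:140, 5000, replace = TRUE))
#' @export
texture_profile <- function(pixels, entropy_base = "natural",
                            quartile_max_level = 64L) {
  h <- build_histogram(pixels)
  prof <- list(
    mean = hist_mean(h),
    sigma = hist_sigma(h),
    skewness = hist_skewness(h),
    kurtosis = hist_kurtosis(h),
    energy = hist_energy(h),
    entropy = hist_entropy(h, base = entropy_base),
    nakagami = nakagami_parameter(h),
    quartile_fraction = quartile_fraction(h, max_level = quartile_max_level)
  )
  structure(prof, class = "texture_profile")
}

#' @export
print.texture_profile <- function(x, ...) {
  cat("<texture_profile>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.texture_profile <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Export a histogram as a two-column CSV
#'
#' @param h a [gray_histogram()].
#' @param path output CSV path (columns `level`, `probability`).
#' @return `path`, invisibly.
#' @export
write_histogram <- function(h, path) {
  stopifnot(inherits(h, "gray_histogram"))
  write_table(data.frame(level = levels_k, probability = h$p), path)
}

#' Read a histogram written by [write_histogram()]
#'
#' @param path CSV path with columns `level`, `probability`.
#' @param n_pixels pixel count to attach (0 = analytic).
#' @return A [gray_histogram()].
#' @export
read_histogram <- function(path, n_pixels = 0L) {
  df <- read.csv(path)
  if (!all(c("level", "probability") %in% names(df)) || nrow(df) != 256L) {
    abort_ctx("histogram CSV must have 256 rows with columns level, probability",
              "cortexture_format_error")
  }
  gray_histogram(df$probability[order(df$level)], n_pixels = n_pixels)
}
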
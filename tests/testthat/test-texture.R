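test_that("build_histogram matches a brute-force tally and validates input", {
  h <- build_histogram(rep(128L, 256))
  expect_equal(h$p[129], 1)
  expect_equal(sum(h$p), 1)
  expect_equal(sum(h$p > 0), 1L)

  h2 <- build_histogram(c(0L, 255L))
  expect_equal(h2$p[c(1, 256)], c(0.5, 0.5))

  set.seed(21)
  px <- sample(0:255, 16 * 16, replace = TRUE)
  expect_equal(build_histogram(px)$p, brute_tally(px))

  expect_error(build_histogram(integer(0)), class = "cortexture_empty_roi_error")
  expect_error(build_histogram(c(1L, 300L)), "300",
               class = "cortexture_domain_error")
})

test_that("two-point and single-level histograms give the analytic values", {
  h <- build_histogram(c(rep(0L, 50), rep(255L, 50)))
  expect_equal(hist_mean(h), 127.5)
  expect_equal(hist_sigma(h), 127.5)
  expect_equal(hist_skewness(h), 0)
  expect_equal(hist_kurtosis(h), -2)
  expect_equal(hist_energy(h), 0.5)
  expect_equal(nakagami_parameter(h), 1.0)

  single <- build_histogram(rep(128L, 10))
  expect_equal(hist_mean(single), 128)
  expect_equal(hist_sigma(single), 0)
  expect_equal(hist_energy(single), 1)
  expect_equal(hist_entropy(single), 0)
  expect_equal(quartile_fraction(single), 0)
  expect_error(hist_skewness(single), class = "cortexture_degenerate_error")
  expect_error(hist_kurtosis(single), class = "cortexture_degenerate_error")
  expect_error(nakagami_parameter(rep(100L, 10)),
               class = "cortexture_degenerate_error")
})

test_that("uniform histogram attains the entropy/energy extremes", {
  h <- build_histogram(rep(0:255, 4))
  expect_equal(hist_energy(h), 1 / 256)
  expect_equal(hist_entropy(h), log(256))
  expect_equal(hist_entropy(h, base = "log2"), 8)
})

test_that("discretized analytic densities match the quadrature oracle", {
  g25 <- discretize(analytic_distribution("gaussian_25"))
  oracle <- quad_moments(function(x) dnorm(x, 128, 25))
  expect_equal(hist_mean(g25), 128, tolerance = 1e-6)
  expect_equal(hist_sigma(g25), oracle$sigma, tolerance = 1e-6)
  expect_lt(abs(hist_sigma(g25) - 25), 1e-3)
  expect_equal(hist_kurtosis(g25), 0, tolerance = 0.01)
  expect_equal(hist_entropy(g25), 4.63, tolerance = 0.05)

  ray <- discretize(analytic_distribution("rayleigh_100"))
  ro <- quad_moments(rayleigh100, lo = 0)   # density vanishes below 0
  expect_gt(hist_skewness(ray), 0)
  expect_lt(abs(hist_skewness(ray) - ro$skewness), 1e-4)
  expect_lt(abs(hist_kurtosis(ray) - ro$kurtosis), 1e-4)
})

test_that("Nakagami agrees between pixel path, histogram path and closed form", {
  # discretized Gaussian vs the closed-form normal-moment expression
  h <- gray_histogram(dnorm(0:255, 100, 15) / sum(dnorm(0:255, 100, 15)))
  expect_equal(nakagami_parameter(h), closed_nakagami_normal(100, 15),
               tolerance = 0.005)

  set.seed(77)
  for (i in 1:5) {
    px <- sample(0:255, 500, replace = TRUE)
    expect_equal(nakagami_parameter(px),
                 nakagami_parameter(build_histogram(px)),
                 tolerance = 1e-9)
  }
})

test_that("quartile fraction reproduces the published low-density percentages", {
  f1 <- discretize(analytic_distribution("gaussian_25"), renormalize = FALSE)
  f2 <- discretize(analytic_distribution("gaussian_50"), renormalize = FALSE)
  expect_lt(abs(quartile_fraction(f1) - 0.0055), 0.0005)
  expect_lt(abs(quartile_fraction(f2) - 0.0969), 0.002)
  expect_error(quartile_fraction(f1, max_level = 300),
               class = "cortexture_domain_error")
})

test_that("texture_profile is consistent with the individual operations", {
  set.seed(9)
  px <- as.integer(pmin(pmax(round(rnorm(5000, 120, 20)), 0), 255))
  prof <- texture_profile(px)
  h <- build_histogram(px)
  expect_equal(prof$mean, hist_mean(h))
  expect_equal(prof$sigma, hist_sigma(h))
  expect_equal(prof$skewness, hist_skewness(h))
  expect_equal(prof$kurtosis, hist_kurtosis(h))
  expect_equal(prof$energy, hist_energy(h))
  expect_equal(prof$entropy, hist_entropy(h))
  expect_equal(prof$nakagami, nakagami_parameter(h))
  expect_equal(prof$quartile_fraction, quartile_fraction(h))
  # mean path equals the arithmetic pixel mean exactly
  expect_equal(prof$mean, mean(px))
})

test_that("large Gaussian samples recover the analytic moments", {
  set.seed(31)
  n <- 2e5
  px <- as.integer(pmin(pmax(round(rnorm(n, 120, 18)), 0), 255))
  prof <- texture_profile(px)
  expect_equal(prof$mean, 120, tolerance = 0.2)
  # rounding to integer levels adds variance 1/12
  expect_equal(prof$sigma, sqrt(18^2 + 1 / 12), tolerance = 0.15)
  expect_equal(prof$skewness, 0, tolerance = 0.03)
  expect_equal(prof$kurtosis, 0, tolerance = 0.06)
  expect_equal(prof$nakagami, closed_nakagami_normal(120, 18),
               tolerance = 0.25)
})

test_that("histogram moments obey bounds and are reorder-invariant", {
  set.seed(55)
  for (i in 1:10) {
    px <- sample(0:255, sample(50:2000, 1), replace = TRUE)
    h <- build_histogram(px)
    expect_lte(hist_energy(h), 1)
    expect_gte(hist_entropy(h), 0)
    expect_lte(hist_entropy(h), log(256) + 1e-12)
    expect_true(hist_mean(h) >= 0 && hist_mean(h) <= 255)
    expect_gte(hist_sigma(h), 0)
    expect_identical(build_histogram(sample(px))$p, h$p)
    mom <- pop_moments(px)
    expect_equal(hist_mean(h), mom$mean, tolerance = 1e-9)
    expect_equal(hist_sigma(h), mom$sigma, tolerance = 1e-9)
    expect_equal(hist_skewness(h), mom$skewness, tolerance = 1e-9)
    expect_equal(hist_kurtosis(h), mom$kurtosis, tolerance = 1e-9)
  }
})

test_that("histogram CSV export round-trips", {
  dir <- withr::local_tempdir()
  set.seed(8)
  h <- build_histogram(sample(0:255, 300, replace = TRUE))
  f <- file.path(dir, "hist.csv")
  write_histogram(h, f)
  back <- read_histogram(f, n_pixels = h$n_pixels)
  expect_equal(back$p, h$p)
})
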
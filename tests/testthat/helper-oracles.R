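# Independent oracles used across the suite.

# Moments of a continuous density restricted to the 8-bit range, by
# numerical quadrature over [-0.5, 255.5] (the interval the unit-spaced
# level grid tiles). Independent of the package's discrete-sum path.
quad_moments <- function(density_fn, lo = -0.5, hi = 255.5) {
  # split at the interval midpoint: near-antisymmetric integrands (odd
  # central moments of symmetric densities) otherwise trip integrate()'s
  # roundoff detection
  q <- function(f) {
    mid <- (lo + hi) / 2
    integrate(f, lo, mid, rel.tol = 1e-10, subdivisions = 500L)$value +
      integrate(f, mid, hi, rel.tol = 1e-10, subdivisions = 500L)$value
  }
  z <- q(density_fn)
  m <- q(function(x) x * density_fn(x)) / z
  v <- q(function(x) (x - m)^2 * density_fn(x)) / z
  g1 <- q(function(x) (x - m)^3 * density_fn(x)) / z / v^1.5
  g2 <- q(function(x) (x - m)^4 * density_fn(x)) / z / v^2 - 3
  list(mean = m, sigma = sqrt(v), skewness = g1, kurtosis = g2)
}

# Closed-form Nakagami parameter of a Normal(mu, sigma) intensity law:
# E(X^2) = mu^2 + s^2, Var(X^2) = 4 mu^2 s^2 + 2 s^4.
closed_nakagami_normal <- function(mu, sigma) {
  (mu^2 + sigma^2)^2 / (4 * mu^2 * sigma^2 + 2 * sigma^4)
}

# Brute-force histogram tally: a plain loop, no tabulate().
brute_tally <- function(pixels) {
  counts <- numeric(256)
  for (v in pixels) counts[v + 1] <- counts[v + 1] + 1
  counts / length(pixels)
}

# Population (divide-by-N) moments of a pixel vector.
pop_moments <- function(px) {
  m <- mean(px)
  s <- sqrt(mean((px - m)^2))
  list(mean = m, sigma = s,
       skewness = mean((px - m)^3) / s^3,
       kurtosis = mean((px - m)^4) / s^4 - 3)
}

rayleigh100 <- function(x) ifelse(x >= 0, x / 100^2 * exp(-0.5 * x^2 / 100^2), 0)

# Published worked-example triplets (inputs to correlation checks).
printed_entropies <- c(4.63, 5.23, 5.43)
printed_quartile_pcts <- c(0.55, 9.69, 18.89)

shell_pixels <- function(vol) as.integer(vol$data[attr(vol, "shell_mask")])
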
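# cortexture

First-order histogram texture analysis of 8-bit micro-CT volumes of
cortical bone.

Micro computed tomography depicts local bone mineral density as gray-level
intensity. Conventional morphometry reduces a region of interest (ROI) to
one average density; `cortexture` instead quantifies the whole intensity
distribution, for researchers comparing cortical bone quality between
animal cohorts (diet, treatment, disease models). From the normalized
histogram $P_k$ over gray levels $k = 0..255$ it derives seven parameters —

- mean $\bar m = \sum_k k P_k$ and sigma
  $\sigma = [\sum_k (k - \bar m)^2 P_k]^{1/2}$,
- skewness $\sigma^{-3} \sum_k (k-\bar m)^3 P_k$ and excess kurtosis
  $\sigma^{-4} \sum_k (k-\bar m)^4 P_k - 3$,
- energy $\sum_k P_k^2$ and entropy $-\sum_k P_k \log P_k$ (nats by
  default),
- the Nakagami parameter $\mathrm{E}^2(X^2)/\mathrm{Var}(X^2)$ of the
  intensity population,

plus the fraction of mass at levels $\le 64$ (the first quartile of the
8-bit range), a proxy for the low-density bone fraction. An F-test-gated
two-sample t-test compares two cohorts parameter by parameter. Because no
public scanner data accompanies the method, the package also generates
synthetic cortical-bone cohorts (annular shells with skew-normal
intensity laws moment-matched to published group summaries) and a
five-insert bone-mineral-density phantom, so the full pipeline is testable
end to end.

## Worked example

Simulate the default two-diet cohort (7 + 7 specimens, ≈ 2×10⁵ cortical
voxels each), extract each specimen's mid-diaphysis ROI, and compare the
groups:

```r
library(cortexture)

specs  <- default_group_specs(seed = 101)
cohort <- generate_cohort(specs$control, specs$low_mg)

# synthetic background/canal are exactly 0, so threshold 1 delineates the
# cortical compartment exactly
spec <- roi_spec(mask_threshold = 1)
prof <- function(vol) as.data.frame(texture_profile(extract_roi_pixels(vol, spec)))
pa <- do.call(rbind, lapply(cohort$control, prof))
pb <- do.call(rbind, lapply(cohort$treated, prof))

print(compare_groups(pa, pb), digits = 3)
#>   parameter groupA_mean groupA_sd groupB_mean groupB_sd  p_value percent_change test_variant
#> 1      mean     98.1134  4.10e-02    104.9736  2.04e-02 4.52e-26           6.99       pooled
#> 2     sigma     17.7833  4.23e-02     12.6131  7.29e-03 1.32e-14         -29.07        welch
#> 3  skewness     -0.9003  8.45e-03     -0.7254  4.20e-03 3.35e-15         -19.44       pooled
#> 4  kurtosis      0.7350  3.28e-02      0.5602  2.09e-02 5.39e-08         -23.77       pooled
#> 5    energy      0.0176  3.73e-05      0.0238  2.33e-05 1.05e-25          34.79       pooled
#> 6   entropy      4.2000  2.15e-03      3.9030  7.07e-04 1.28e-16          -7.07        welch
#> 7  nakagami      9.4476  3.60e-02     19.3258  1.62e-02 9.62e-29         104.56       pooled
```

Reading the report: the low-magnesium arm is brighter on average (mean up
~7%) but far more uniform — sigma down 29%, energy up, entropy down — and
its Nakagami parameter roughly doubles; skewness moves from −0.90 toward
zero (−0.73; the signed percent change is on the raw negative scale).
Every parameter's p-value is the F-gated pooled or Welch two-sided t-test;
no multiplicity correction is applied across the seven rows.

The analytic worked examples — two Gaussians (location 128, scales 25 and
50) and a Rayleigh (scale 100) discretized onto the 256 gray levels —
show how distributions with near-identical means differ in heterogeneity:

```r
wx <- worked_example_table()
wx$table
#>         family entropy_nats quartile_pct
#> 1  gaussian_25     4.637810    0.5539803
#> 2  gaussian_50     5.281471    9.6954248
#> 3 rayleigh_100     5.418252   18.7792806
```

Entropy and the below-first-quartile percentage rise together: a more
heterogeneous histogram carries a larger low-density fraction.

A command-line wrapper for the same workflow (subcommands `simulate`,
`analyze`, `compare`, `worked-examples`) ships at
`system.file("cli", "cortexture.R", package = "cortexture")`.

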
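#' Two-sided F-test of equal variances
#'
#' Variance-ratio test with the larger sample variance in the numerator;
#' returns the two-sided p-value. Used to decide whether the pooled
#' (equal-variance) or Welch t-test is applied to a parameter.
#'
#' @param a,b numeric samples, each of size `>= 2` with positive variance.
#' @return Two-sided p-value.
#' @export
f_test_equal_variance <- function(a, b) {
  check_sample <- function(x, nm) {
    if (length(x) < 2L || var(x) <= 0) {
      abort_ctx(sprintf("sample `%s` needs >= 2 values with positive variance",
                        nm), "cortexture_degenerate_sample_error")
    }
  }
  check_sample(a, "a")
  check_sample(b, "b")
  va <- var(a); vb <- var(b)
  if (va >= vb) {
    f <- va / vb; df1 <- length(a) - 1L; df2 <- length(b) - 1L
  } else {
    f <- vb / va; df1 <- length(b) - 1L; df2 <- length(a) - 1L
  }
  min(1, 2 * pf(f, df1, df2, lower.tail = FALSE))
}

#' Two-sample t-test
#'
#' Two-sided t-test, either pooled-variance or Welch (Satterthwaite
#' degrees of freedom).
#'
#' @param a,b numeric samples of size `>= 2`.
#' @param pooled use the equal-variance pooled test? Default `TRUE`.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, pooled = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort_ctx("each sample needs at least 2 values",
              "cortexture_degenerate_sample_error")
  }
  if (var(a) + var(b) <= 0) {
    abort_ctx("t-test undefined: both samples are constant",
              "cortexture_degenerate_sample_error")
  }
  r <- t.test(a, b, var.equal = pooled)
  list(t = unname(r$statistic), df = unname(r$parameter), p = r$p.value)
}

#' Percent change between group means
#'
#' `100 * (treated - control) / control`, signed.
#'
#' @param control_mean reference group mean (nonzero).
#' @param treated_mean comparison group mean.
#' @return Signed percentage.
#' @export
percent_change <- function(control_mean, treated_mean) {
  if (control_mean == 0) {
    abort_ctx("percent change undefined for zero control mean",
              "cortexture_degenerate_error")
  }
  100 * (treated_mean - control_mean) / control_mean
}

comparison_parameters <- c("mean", "sigma", "skewness", "kurtosis",
                           "energy", "entropy", "nakagami")

profiles_to_frame <- function(profiles) {
  if (is.data.frame(profiles)) return(profiles)
  do.call(rbind, lapply(profiles, as.data.frame))
}

#' Compare two groups of texture profiles
#'
#' One row per texture parameter (mean, sigma, skewness, kurtosis, energy,
#' entropy, Nakagami). For each parameter an F-test at `alpha` chooses
#' between the pooled and the Welch t-test; the percent change is computed
#' from the raw group means, signed. No multiple-testing correction is
#' applied across the seven parameters.
#'
#' @param profiles_a,profiles_b data frames (or lists of
#'   [texture_profile()]s), one row/profile per specimen, `>= 2` per group.
#' @param alpha significance level of the F-test gate (default 0.05).
#' @param label_a,label_b group labels used in messages only.
#' @return Data frame with columns `parameter`, `groupA_mean`, `groupA_sd`,
#'   `groupB_mean`, `groupB_sd`, `p_value`, `percent_change`,
#'   `test_variant`.
#' @export
compare_groups <- function(profiles_a, profiles_b, alpha = 0.05,
                           label_a = "groupA", label_b = "groupB") {
  pa <- profiles_to_frame(profiles_a)
  pb <- profiles_to_frame(profiles_b)
  if (nrow(pa) < 2L || nrow(pb) < 2L) {
    abort_ctx("need at least 2 profiles per group",
              "cortexture_degenerate_sample_error")
  }
  missing_cols <- setdiff(comparison_parameters, intersect(names(pa), names(pb)))
  if (length(missing_cols) > 0L) {
    abort_ctx(sprintf("profiles lack parameter column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "cortexture_schema_error")
  }
  rows <- lapply(comparison_parameters, function(param) {
    a <- pa[[param]]; b <- pb[[param]]
    pooled <- f_test_equal_variance(a, b) >= alpha
    tt <- two_sample_t(a, b, pooled = pooled)
    data.frame(parameter = param,
               groupA_mean = mean(a), groupA_sd = sd(a),
               groupB_mean = mean(b), groupB_sd = sd(b),
               p_value = tt$p,
               percent_change = percent_change(mean(a), mean(b)),
               test_variant = if (pooled) "pooled" else "welch",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Nakagami-versus-density linear regression
#'
#' Ordinary least squares of per-insert Nakagami parameters on insert
#' densities, quantifying the phantom's Nakagami-BMD linearity.
#'
#' @param nakagami_values per-insert Nakagami parameters (`>= 3`).
#' @param densities matching insert densities (mg-HA/cm^3).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value` (slope
#'   t-test) and `df` (residual degrees of freedom, `n - 2`).
#' @export
nakagami_density_regression <- function(nakagami_values, densities) {
  if (length(nakagami_values) != length(densities) ||
      length(densities) < 3L) {
    abort_ctx("need >= 3 matched (nakagami, density) points",
              "cortexture_domain_error")
  }
  if (sd(densities) == 0 || sd(nakagami_values) == 0) {
    abort_ctx("regression undefined for constant input",
              "cortexture_degenerate_error")
  }
  fit <- lm(nakagami_values ~ densities)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = unname(coef(s)[2, 4]),
       df = fit$df.residual)
}
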
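test_that("skew-normal moment matching round-trips the target moments", {
  sym <- skew_normal_from_moments(100, 10, 0)
  expect_equal(sym$shape, 0)
  expect_equal(sym$scale, 10)
  expect_equal(sym$location, 100)

  targets <- list(c(98.1, 17.8, -0.906), c(105, 12.6, -0.729),
                  c(50, 5, 0.5))
  for (tg in targets) {
    sn <- skew_normal_from_moments(tg[1], tg[2], tg[3])
    mom <- skew_normal_moments(sn$location, sn$scale, sn$shape)
    expect_equal(mom$mean, tg[1], tolerance = 1e-6)
    expect_equal(mom$sd, tg[2], tolerance = 1e-6)
    expect_equal(mom$skewness, tg[3], tolerance = 1e-6)
  }

  expect_error(skew_normal_from_moments(100, 10, 1.2),
               class = "cortexture_unattainable_skewness_error")
  expect_error(skew_normal_from_moments(100, 0, 0),
               class = "cortexture_domain_error")
})

test_that("cortical volumes are deterministic, clipped and on-target", {
  g <- group_spec("control", 98.1, 17.8, -0.906,
                  outer_radius = 30, canal_radius = 15, n_slices = 24,
                  seed = 17L)
  v1 <- generate_cortical_volume(g, 1L)
  v2 <- generate_cortical_volume(g, 1L)
  expect_identical(v1$data, v2$data)
  v_other <- generate_cortical_volume(g, 2L)
  expect_false(identical(v_other$data, v1$data))
  expect_true(all(v1$data >= 0L & v1$data <= 255L))

  px <- shell_pixels(v1)
  expect_gt(length(px), 5e4)
  mom <- pop_moments(px)
  expect_lt(abs(mom$mean - 98.1), 0.5)
  expect_lt(abs(mom$sigma - 17.8), 0.3)
  expect_lt(abs(mom$skewness - (-0.906)), 0.1)

  # canal and background stay empty
  expect_true(all(v1$data[!attr(v1, "shell_mask")] == 0L))
})

test_that("degenerate geometry raises instead of returning empty shells", {
  expect_error(group_spec("g", 100, 10, 0, outer_radius = 5, canal_radius = 5),
               class = "cortexture_degenerate_geometry_error")
  tiny <- group_spec("g", 100, 10, 0, outer_radius = 0.3, canal_radius = 0.2)
  expect_error(generate_cortical_volume(tiny, 1L),
               class = "cortexture_degenerate_geometry_error")
})

test_that("cohorts carry seven specimens per arm and a manifest", {
  specs <- default_group_specs(seed = 2L, outer_radius = 10, canal_radius = 5,
                               n_slices = 4)
  cohort <- generate_cohort(specs$control, specs$low_mg)
  expect_length(cohort$control, 7L)
  expect_length(cohort$treated, 7L)
  expect_identical(nrow(cohort$manifest), 14L)
  expect_identical(sort(unique(cohort$manifest$group)),
                   c("control", "low_mg"))
  expect_false(any(duplicated(cohort$manifest$seed)))

  same <- default_group_specs(seed = 2L)
  same$low_mg$label <- "control"
  expect_error(generate_cohort(specs$control, same$low_mg),
               class = "cortexture_config_error")
})

test_that("phantom inserts sit at their mapped gray levels", {
  quiet <- phantom_spec(noise_sigma = 0)
  ph <- generate_bmd_phantom(quiet)
  expect_identical(dim(ph$labels), dim(ph$volume$data))
  for (i in 1:5) {
    vox <- ph$volume$data[ph$labels == i]
    expect_gt(length(vox), 0L)
    expect_true(all(vox == as.integer(quiet$slope * quiet$densities[i] +
                                        quiet$intercept)))
  }
  expect_true(all(ph$volume$data[ph$labels == 0L] == quiet$background_level))
  expect_equal(ph$insert_table$mapped_gray,
               quiet$slope * quiet$densities + quiet$intercept)

  expect_error(phantom_spec(densities = c(200, 200, 400)),
               class = "cortexture_config_error")
  expect_error(phantom_spec(slope = 1, intercept = 0),
               class = "cortexture_config_error")
})

test_that("phantom Nakagami rises strictly with insert density", {
  ph <- generate_bmd_phantom(phantom_spec(seed = 9L))
  nak <- vapply(1:5, function(i) {
    nakagami_parameter(as.integer(ph$volume$data[ph$labels == i]))
  }, numeric(1))
  expect_true(all(diff(nak) > 0))
  # noisy-constant law predicts Nakagami ~ (mu^2+s^2)^2 / (4 mu^2 s^2 + 2 s^4)
  spec <- phantom_spec(seed = 9L)
  predicted <- closed_nakagami_normal(spec$slope * spec$densities +
                                        spec$intercept, spec$noise_sigma)
  expect_equal(nak, predicted, tolerance = 0.05)
})
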
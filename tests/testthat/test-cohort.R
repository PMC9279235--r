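test_that("cohort generation is reproducible and validates its config", {
  cfg <- tiny_cohort_config(seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_error(cohort_config(prevalence = 0), "prevalence")
  expect_error(cohort_config(diameter_range_mm = c(2, 30)), "diameter")
  expect_error(cohort_config(voxel_spacing_mm = c(1, -1, 1)), "positive")
})

test_that("null label model realises the target prevalence", {
  w0 <- c(log_diameter = 0, spiculation = 0, part_solid = 0,
          upper_lobe = 0, age = 0, emphysema = 0)
  cfg <- cohort_config(n_participants = 2000, prevalence = 0.5,
                       logit_weights = w0, seed = 5)
  co <- generate_cohort(cfg)
  expect_gte(mean(co$malignant), 0.45)
  expect_lte(mean(co$malignant), 0.55)
})

test_that("prevalence calibration holds within 20% relative over seeds", {
  for (s in 1:10) {
    cfg <- cohort_config(n_participants = 500, prevalence = 0.12, seed = s)
    co <- generate_cohort(cfg)
    expect_lt(abs(mean(co$malignant) - 0.12) / 0.12, 0.20)
  }
})

test_that("a positive size weight makes malignant nodules larger on average", {
  w <- c(log_diameter = 2, spiculation = 0, part_solid = 0,
         upper_lobe = 0, age = 0, emphysema = 0)
  cfg <- cohort_config(n_participants = 2000, logit_weights = w, seed = 2)
  co <- generate_cohort(cfg)
  expect_gt(mean(co$true_diameter_mm[co$malignant]),
            mean(co$true_diameter_mm[!co$malignant]))
})

test_that("inclusion filters keep 6-30 mm solid/part-solid nodules", {
  df <- tibble::tibble(
    manual_diameter_mm = c(5.9, 6.0, 30.0, 30.1),
    nodule_type = "solid")
  kept <- apply_inclusion_filters(df)
  expect_equal(kept$manual_diameter_mm, c(6.0, 30.0))

  expect_equal(nrow(apply_inclusion_filters(df[0, ])), 0)

  set.seed(42)
  rand <- tibble::tibble(
    manual_diameter_mm = runif(100, 4, 36),
    nodule_type = sample(c("solid", "part_solid", "ground_glass"), 100,
                         replace = TRUE))
  kept <- apply_inclusion_filters(rand)
  manual <- rand[rand$manual_diameter_mm >= 6 & rand$manual_diameter_mm <= 30 &
                   rand$nodule_type %in% c("solid", "part_solid"), ]
  expect_equal(kept, manual)
  # input untouched, order preserved
  expect_equal(nrow(rand), 100)
  expect_true(all(diff(match(kept$manual_diameter_mm,
                             rand$manual_diameter_mm)) > 0))
})

test_that("rendered solid spheres hit the analytic volume", {
  cfg <- cohort_config(n_participants = 1, voxel_spacing_mm = c(0.5, 0.5, 0.5),
                       patch_extent_mm = 30, axis_ratio_range = c(1, 1),
                       spiculation_rate = 0, part_solid_rate = 0,
                       emphysema_rate = 0, seed = 1)
  co <- generate_cohort(cfg)
  co$true_diameter_mm <- 10
  co$center_x_mm <- 0; co$center_y_mm <- 0; co$center_z_mm <- 0
  rv <- render_volume(co[1, ], cfg)
  expect_lt(abs(nodule_volume(rv$mask) - pi / 6 * 1000) / (pi / 6 * 1000), 0.02)
})

test_that("emphysema-free volumes have no pocket-depth voxels outside the nodule", {
  cfg <- tiny_cohort_config(seed = 9, n = 10)
  co <- generate_cohort(cfg)
  co$emphysema <- FALSE
  rv <- render_volume(co[1, ], cfg)
  outside <- rv$volume$values[rv$mask$values == 0]
  expect_true(all(outside > cfg$emphysema_pocket_hu + 20))
})

test_that("part-solid nodules render a shell darker than the core", {
  cfg <- cohort_config(n_participants = 30, part_solid_rate = 1,
                       voxel_spacing_mm = c(1, 1, 1), seed = 4)
  co <- generate_cohort(cfg)
  big <- co[which(co$true_diameter_mm > 15)[1], ]
  rv <- render_volume(big, cfg)
  core_mean <- mean(rv$volume$values[rv$mask$values == 1])
  shell_mean <- mean(rv$volume$values[rv$mask$values == 2])
  expect_lt(shell_mean, core_mean)
  # mask invariants: nonempty, single 26-connected component
  expect_true(any(rv$mask$values > 0))
  expect_true(is_connected_mask(rv$mask))
})

test_that("oversized nodules fail to render with an explicit error", {
  cfg <- cohort_config(n_participants = 1, patch_extent_mm = 30, seed = 1)
  co <- generate_cohort(cfg)
  co$true_diameter_mm <- 29
  expect_error(render_volume(co[1, ], cfg), "does not fit")
})

test_that("rendered-mask ESD is within 5% of the requested diameter", {
  cfg <- cohort_config(n_participants = 12, voxel_spacing_mm = c(0.5, 0.5, 0.5),
                       patch_extent_mm = 44, diameter_range_mm = c(8, 16),
                       spiculation_rate = 0, part_solid_rate = 0, seed = 21)
  co <- generate_cohort(cfg)
  co$center_x_mm <- 0
  for (i in seq_len(4)) {
    rv <- render_volume(co[i, ], cfg)
    esd <- equivalent_spherical_diameter(nodule_volume(rv$mask))
    expect_lt(abs(esd - co$true_diameter_mm[i]) / co$true_diameter_mm[i], 0.05)
  }
})

test_that("hilum landmark sits inside the volume, off and away from the nodule", {
  cfg <- tiny_cohort_config(seed = 13, n = 20)
  co <- generate_cohort(cfg)
  half <- cfg$patch_extent_mm / 2
  for (i in seq_len(nrow(co))) {
    hp <- hilum_point(co[i, ])
    expect_true(all(abs(hp) <= half))
    d <- sqrt(sum((hp - nodule_center(co[i, ]))^2))
    expect_gte(d, 25)
  }
})
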
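# One rendered fixture shared across the ablation tests: a spiculated
# 12 mm solid nodule at fine (0.5 mm) spacing, plus a coarse part-solid one.
local_fixture <- local({
  cache <- new.env()
  function(which = "fine") {
    if (!is.null(cache[[which]])) return(cache[[which]])
    if (which == "fine") {
      cfg <- cohort_config(n_participants = 1, voxel_spacing_mm = c(0.5, 0.5, 0.5),
                           patch_extent_mm = 76, diameter_range_mm = c(12, 12.5),
                           spiculation_rate = 1, part_solid_rate = 0,
                           emphysema_rate = 1, seed = 33)
    } else {
      cfg <- cohort_config(n_participants = 1, voxel_spacing_mm = c(1.5, 1.5, 1.5),
                           patch_extent_mm = 88, diameter_range_mm = c(16, 18),
                           spiculation_rate = 0, part_solid_rate = 1,
                           emphysema_rate = 1, seed = 34)
    }
    co <- generate_cohort(cfg)
    rv <- render_volume(co[1, ], cfg)
    cache[[which]] <- list(cfg = cfg, rec = co[1, ], vol = rv$volume,
                           mask = rv$mask)
    cache[[which]]
  }
})

test_that("mean nodule density is the arithmetic mask mean", {
  sp <- c(1, 1, 1)
  arr <- array(-800, c(4, 4, 4))
  msk <- array(0L, c(4, 4, 4))
  msk[2, 2, 2] <- 1L; arr[2, 2, 2] <- -50
  expect_equal(mean_nodule_density(ct_volume(arr, sp), nodule_mask(msk, sp)), -50)
  msk[3, 2, 2] <- 1L; arr[3, 2, 2] <- -100; arr[2, 2, 2] <- 0
  expect_equal(mean_nodule_density(ct_volume(arr, sp), nodule_mask(msk, sp)), -50)

  fx <- local_fixture("fine")
  expect_equal(mean_nodule_density(fx$vol, fx$mask),
               sum(fx$vol$values[fx$mask$values > 0]) / sum(fx$mask$values > 0))
  empty <- nodule_mask(array(0L, dim(arr)), sp)
  expect_error(mean_nodule_density(ct_volume(arr, sp), empty), "empty")
})

test_that("uniform-density ablation leaves only fill and component means", {
  fx <- local_fixture("coarse")
  spec <- ablation_spec("uniform_density")
  ab <- uniform_density_ablation(fx$vol, fx$mask, spec)
  vals <- unique(as.vector(ab$values))
  expect_lte(length(vals), 3)  # fill + core mean + shell mean
  expect_true(-825 %in% vals)
  expect_equal(ab$values[fx$mask$values == 0][1], -825)
  core_mean <- mean(fx$vol$values[fx$mask$values == 1])
  shell_mean <- mean(fx$vol$values[fx$mask$values == 2])
  expect_setequal(setdiff(vals, -825), c(core_mean, shell_mean))

  # global-mean mode collapses the nodule to a single value
  ab1 <- uniform_density_ablation(fx$vol, fx$mask, spec, per_component = FALSE)
  expect_lte(length(unique(as.vector(ab1$values))), 2)
})

test_that("uniform-density ablation preserves mask-derived measurements exactly", {
  fx <- local_fixture("coarse")
  before <- measure_nodule(fx$mask, methods = c("esd", "pairwise"))
  ab <- uniform_density_ablation(fx$vol, fx$mask)
  after <- measure_nodule(fx$mask, methods = c("esd", "pairwise"))
  expect_identical(before, after)
  # idempotence
  twice <- uniform_density_ablation(ab, fx$mask)
  expect_equal(twice$values, ab$values)
})

test_that("parenchyma-only windows follow the centroid-to-hilum geometry", {
  # synthetic straight-line case: 10 mm sphere at the centre, hilum on +x
  sp <- c(0.5, 0.5, 0.5)
  n <- 121
  xs <- (seq_len(n) - (n + 1) / 2) * 0.5
  q <- outer(outer(xs^2, xs^2, "+"), xs^2, "+")
  origin <- -((n - 1) / 2) * sp
  msk <- nodule_mask((q <= 25) + 0L, sp, origin)
  vol <- ct_volume(array(-825, c(n, n, n)), sp, origin)
  spec <- ablation_spec("parenchyma_only", patch_extent_mm = 10)
  patch <- parenchyma_only_patch(vol, msk, c(40, 0, 0), spec)
  ctr <- attr(patch, "center_mm")
  # surface point 5 mm from the centroid, window centre 15 mm beyond it
  expect_equal(attr(patch, "realized_offset_mm"), 15)
  expect_equal(ctr[1], 20, tolerance = 0.5)
  expect_equal(ctr[2:3], c(0, 0), tolerance = 0.5)
})

test_that("parenchyma-only windows never contain nodule voxels", {
  fx <- local_fixture("fine")
  spec <- ablation_spec("parenchyma_only", patch_extent_mm = 24)
  patch <- parenchyma_only_patch(fx$vol, fx$mask, hilum_point(fx$rec), spec)
  mpatch <- extract_patch(fx$mask, attr(patch, "center_mm"),
                          spec$patch_extent_mm)
  expect_false(any(mask_binary(mpatch)))
  # deterministic
  patch2 <- parenchyma_only_patch(fx$vol, fx$mask, hilum_point(fx$rec), spec)
  expect_equal(patch$values, patch2$values)
  expect_equal(attr(patch, "realized_offset_mm"),
               attr(patch2, "realized_offset_mm"))
})

test_that("windows that would leave the volume raise a deficit error", {
  fx <- local_fixture("fine")
  spec <- ablation_spec("parenchyma_only", patch_extent_mm = 70)
  expect_error(
    parenchyma_only_patch(fx$vol, fx$mask, hilum_point(fx$rec), spec),
    "leaves the volume")
})

test_that("sphere implantation conserves volume and mean density", {
  fx <- local_fixture("fine")
  spec <- ablation_spec("implant_sphere", patch_extent_mm = 24)
  patch <- implant_sphere(fx$vol, fx$mask, hilum_point(fx$rec), spec)
  dens <- mean_nodule_density(fx$vol, fx$mask)
  target <- nodule_volume(fx$mask)
  implanted <- patch$values == dens
  vol_implant <- sum(implanted) * prod(patch$spacing)
  expect_lt(abs(vol_implant - target) / target, 0.005)
  expect_equal(mean(patch$values[implanted]), dens)

  # a volume-preserving sphere has diameter equal to the nodule ESD
  impl_mask <- nodule_mask(implanted + 0L, patch$spacing, patch$origin)
  d_ell <- ellipse_fit_axial_diameter(impl_mask)
  esd <- equivalent_spherical_diameter(target)
  expect_lt(abs(d_ell - esd) / esd, 0.03)
})

test_that("apply_ablation dispatches every condition on a common window", {
  fx <- local_fixture("coarse")
  hp <- hilum_point(fx$rec)
  for (mode in c("none", "uniform_density", "implant_sphere", "parenchyma_only")) {
    patch <- apply_ablation(fx$vol, fx$mask, hp,
                            ablation_spec(mode, patch_extent_mm = 36))
    expect_s3_class(patch, "ct_volume")
    expect_equal(dim(patch$values), patch_voxels(36, fx$vol$spacing))
  }
})
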
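test_that("attenuation model is positive, decreasing, and jumps at the K-edge", {
  mats <- material_library()
  grid <- energy_grid()
  e <- as.numeric(grid)

  w <- mass_attenuation(mats$water, e, grid)
  expect_true(all(w > 0))
  expect_true(all(diff(w) < 0))
  expect_gt(mass_attenuation(mats$water, 25, grid),
            mass_attenuation(mats$water, 60, grid))

  eps <- 1e-12
  lo <- mass_attenuation(mats$iodine, 33.2 - eps, grid)
  hi <- mass_attenuation(mats$iodine, 33.2 + eps, grid)
  expect_lt(abs(hi / lo - mats$iodine$kedge_jump), 1e-9)
  below <- e[e < 33.2]; above <- e[e >= 33.2]
  expect_true(all(diff(mass_attenuation(mats$iodine, below, grid)) < 0))
  expect_true(all(diff(mass_attenuation(mats$iodine, above, grid)) < 0))

  expect_equal(mass_attenuation(mats$null, e, grid), rep(0, length(e)))
  expect_error(mass_attenuation(mats$water, 5, grid), "outside")
  expect_error(material("bad", -1, 0), "non-negative")
  expect_error(material("bad", 1, 1, kedge_energy = 33.2, kedge_jump = 0.5),
               "kedge_jump")
})

test_that("mixture attenuation is linear in concentrations", {
  mats <- material_library()[c("water", "iodine", "calcium")]
  grid <- energy_grid()
  e <- c(28, 40, 65)
  set.seed(42)
  for (i in 1:20) {
    c1 <- runif(3, 0, 10); c2 <- runif(3, 0, 10)
    a <- runif(1, 0.1, 3)
    lhs <- pcctcardiac:::mixture_attenuation(mats, c1 + a * c2, e, grid)
    rhs <- pcctcardiac:::mixture_attenuation(mats, c1, e, grid) +
      a * pcctcardiac:::mixture_attenuation(mats, c2, e, grid)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("dynamic phantom truth matches rendered masks and configured volumes", {
  ph <- make_dynamic_phantom(dlvv_ml = 0.045, slvv_ml = 0.022)
  vox_vol <- 0.25^2 * 1 / 1000
  # stored truth equals the rendered extreme-phase masks exactly
  expect_identical(ph$truth$dlvv_ml,
                   lv_volume(lv_mask(ph, 0), c(0.25, 0.25, 1)))
  expect_identical(ph$truth$slvv_ml,
                   lv_volume(lv_mask(ph, 0.5), c(0.25, 0.25, 1)))
  # rendered truth tracks the requested volumes within partial-volume
  # quantization of the 0.5-coverage mask (a few boundary voxels, < 1%)
  expect_lt(abs(ph$truth$dlvv_ml - 0.045) / 0.045, 0.01)
  expect_lt(abs(ph$truth$slvv_ml - 0.022) / 0.022, 0.01)
  # group-mean stroke volume by subtraction: 0.045 - 0.022 = 0.023 mL
  expect_lt(abs(ph$truth$sv_ml - 0.023), 2 * vox_vol)
  # waveform extrema are attained at phases 0 and 0.5
  vols <- sapply(seq(0, 0.95, by = 0.05), function(p)
    lv_volume(lv_mask(ph, p), c(0.25, 0.25, 1)))
  expect_equal(max(vols), ph$truth$dlvv_ml)
  expect_equal(min(vols), ph$truth$slvv_ml)
})

test_that("degenerate and invalid phantom configurations behave as specified", {
  ph0 <- make_dynamic_phantom(dlvv_ml = 0.03, slvv_ml = 0.03)
  expect_identical(lv_mask(ph0, 0), lv_mask(ph0, 0.37))
  expect_identical(phantom_state(ph0, 0.1)$iodine, phantom_state(ph0, 0.9)$iodine)
  expect_error(make_dynamic_phantom(dlvv_ml = 0.02, slvv_ml = 0.04), "exceeds")
  expect_error(make_dynamic_phantom(heart_rate = 200), "300")
  # determinism: identical configurations render identically
  expect_identical(make_dynamic_phantom(seed = 3)$truth,
                   make_dynamic_phantom(seed = 3)$truth)
})

test_that("detectability phantom renders the concentration/diameter grid", {
  ph <- make_detectability_phantom()
  expect_equal(nrow(ph$cylinders), 20) # 4 material rows x 5 diameters
  expect_setequal(unique(ph$cylinders$concentration[ph$cylinders$material == "calcium"]),
                  c(10, 20, 40))
  expect_equal(sort(unique(ph$cylinders$diameter_mm)), c(0.5, 1, 1.5, 2, 2.5))
  # rendered area within 10% of pi r^2 for cylinders of >= 4 voxel diameter
  for (i in which(ph$cylinders$diameter_mm >= 4 * ph$voxel_mm)) {
    area <- sum(ph$cylinder_coverage[[i]]) * ph$voxel_mm^2
    expect_rel(area, pi * (ph$cylinders$diameter_mm[i] / 2)^2, 0.1)
  }
  # rendered Ca-40 interior concentration
  i40 <- which(ph$cylinders$concentration == 40 & ph$cylinders$diameter_mm == 2.5)
  core <- ph$cylinder_coverage[[i40]] >= 1
  expect_rel(mean(ph$maps$calcium[core]), 40, 1e-6)
  # overlap detection
  expect_error(make_detectability_phantom(diameters_mm = c(3, 3, 3, 3, 3)),
               "overlap")
  w <- testthat::capture_warnings(
    make_detectability_phantom(diameters_mm = c(0, 1, 1.5, 2, 2.5)))
  expect_true(any(grepl("zero diameter", w)))
})

test_that("mask volume arithmetic is exact", {
  m <- array(0L, c(20, 10, 5)); m[1:1000] <- 1L
  expect_equal(lv_volume(m, 0.125), 1000 * 0.125^3 / 1000)
  expect_equal(lv_volume(matrix(0, 4, 4), 0.5), 0)
})
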
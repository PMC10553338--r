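test_that("source spectrum is normalized, non-negative, zero at the endpoint", {
  grid <- energy_grid(to = 80)
  s <- source_spectrum(80, grid, photons_per_ray = 12345)
  expect_true(all(s >= 0))
  expect_equal(s[length(s)], 0) # bremsstrahlung endpoint at kVp
  expect_rel(sum(s) * attr(grid, "step"), 12345, 1e-9)
  bins <- pcctcardiac:::bin_index(as.numeric(grid), c(25, 34, 50, 60), 80)
  expect_gt(sum(s[!is.na(bins) & bins == 1]), 0)
  expect_gt(sum(s[!is.na(bins) & bins == 4]), 0)
})

test_that("projector produces accurate line integrals and is linear", {
  fx <- fix_water()
  A <- proj_matrix(fx$proj, 0.3)
  # uniform disk, central ray: mu * diameter within 1%
  p <- as.vector(A %*% as.vector(0.3 * fx$disk))
  expect_rel(max(p), 0.3 * 1.6, 0.01) # radius 8 mm -> 1.6 cm chord
  expect_equal(as.vector(A %*% numeric(fx$n^2)), numeric(fx$proj$ndet))
  m1 <- as.vector(A %*% as.vector(fx$disk))
  m2 <- as.vector(A %*% as.vector(0.5 * fx$disk))
  expect_equal(as.vector(A %*% as.vector(1.5 * fx$disk)), m1 + m2,
               tolerance = 1e-12)
})

test_that("projector and backprojector are exact adjoints", {
  fx <- fix_water()
  A <- system_matrix(fx$proj, c(0.1, 1.0, 2.3))
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(ncol(A)); y <- rnorm(nrow(A))
    lhs <- sum((A %*% x) * y)
    rhs <- sum(x * as.vector(Matrix::crossprod(A, y)))
    expect_rel(lhs, rhs, 1e-6)
  }
})

test_that("acquisition timestamps, determinism, and air counts are exact", {
  ph <- static_phantom(list(water = matrix(0, 32, 32)), voxel_mm = 0.5)
  cfg <- acquisition_config(views = 50, exposure = 0.01, noise = FALSE,
                            photons_per_ray = 1e4)
  sino <- acquire(ph, cfg)
  expect_equal(sino$timestamps, seq(0, 0.49, by = 0.01))
  expect_true(all(diff(sino$timestamps) > 0))
  # zero phantom, no noise: every ray equals the air scan
  for (b in 1:4) expect_equal(unname(sino$data[, , b]),
                              matrix(sino$air[b], sino$ndet, 50),
                              tolerance = 1e-9)
  cfgN <- acquisition_config(views = 50, photons_per_ray = 1e4, seed = 21)
  expect_identical(acquire(ph, cfgN)$data, acquire(ph, cfgN)$data)
  expect_error(acquisition_config(photons_per_ray = 0), "positive")
  expect_error(acquisition_config(thresholds = c(34, 25)), "increasing")
  expect_error(acquisition_config(thresholds = c(25, 90)), "below kVp")
})

test_that("expected counts are conserved across the energy bins", {
  fx <- fix_water()
  cfg4 <- acquisition_config(views = 8, n_rotations = 1, noise = FALSE,
                             photons_per_ray = 1e4)
  cfg1 <- acquisition_config(views = 8, n_rotations = 1, noise = FALSE,
                             photons_per_ray = 1e4, thresholds = 25)
  s4 <- acquire(fx$phantom, cfg4, fx$proj)
  s1 <- acquire(fx$phantom, cfg1, fx$proj)
  expect_equal(apply(s4$data, c(1, 2), sum), s1$data[, , 1], tolerance = 1e-9)
  expect_equal(sum(s4$air), s1$air[1], tolerance = 1e-9)
})

test_that("log normalization has the exact closed forms and clamps zeros", {
  ph <- static_phantom(list(water = matrix(0, 32, 32)), voxel_mm = 0.5)
  sino <- acquire(ph, acquisition_config(views = 5, noise = FALSE,
                                         photons_per_ray = 1e4))
  lg <- log_normalize(sino)
  expect_equal(max(abs(lg$data)), 0, tolerance = 1e-12) # counts == air -> 0
  sino2 <- sino
  sino2$data <- sino$data * exp(-1)
  expect_equal(unname(log_normalize(sino2)$data[1, 1, ]), rep(1, 4),
               tolerance = 1e-9)
  sino3 <- sino
  sino3$data[1, 1, 1] <- 0
  expect_warning(lg3 <- log_normalize(sino3), "clamped")
  expect_true(is.finite(lg3$data[1, 1, 1]))
  expect_error(log_normalize(lg), "already")
  expect_error(log_normalize(sino, air = NULL), "air")
})

test_that("the view rate satisfies the cardiac Nyquist check at 100 Hz", {
  ph <- make_dynamic_phantom(heart_rate = 600, n = 32, voxel_mm = 0.75)
  fast <- acquire(ph, acquisition_config(views = 60, exposure = 0.010,
                                         noise = FALSE, photons_per_ray = 1e3))
  slow <- acquire(ph, acquisition_config(views = 60, exposure = 0.080,
                                         noise = FALSE, photons_per_ray = 1e3))
  expect_true(fast$sampling_ok)   # 100 Hz vs 20 Hz Nyquist requirement
  expect_false(slow$sampling_ok)  # 12.5 Hz view rate aliases 600 bpm
})
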
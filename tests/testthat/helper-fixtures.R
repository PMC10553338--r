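# Shared, lazily built and memoized fixtures. Everything is generated in
# code at test time; the cache keeps the suite fast by reusing expensive
# simulations across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  hit <- .fixtures[[key]]
  if (!is.null(hit)) return(hit)
  val <- builder()
  .fixtures[[key]] <- val
  val
}

# small shared projector + water-disk scan (noiseless and noisy variants)
fix_water <- function() memo("water", function() {
  n <- 96; vox <- 0.25
  g <- pcctcardiac:::pixel_grid(n, vox)
  disk <- pcctcardiac:::disk_coverage(g$x, g$y, 0, 0, 8, vox)
  proj <- projector(n, vox)
  ph <- static_phantom(list(water = disk), voxel_mm = vox)
  roi <- pcctcardiac:::disk_coverage(g$x, g$y, 0, 0, 4, vox) >= 1
  cfg0 <- acquisition_config(views = 240, n_rotations = 1, noise = FALSE,
                             photons_per_ray = 2e4)
  cfgN <- acquisition_config(views = 360, n_rotations = 1, noise = TRUE,
                             photons_per_ray = 2e4, seed = 3)
  list(n = n, vox = vox, grid = g, disk = disk, proj = proj, phantom = ph,
       roi = roi,
       sino0 = log_normalize(acquire(ph, cfg0, proj)),
       sinoN = suppressWarnings(log_normalize(acquire(ph, cfgN, proj))))
})

# shared dynamic-phantom acquisition (beating LV, counting noise)
fix_dynamic <- function() memo("dynamic", function() {
  ph <- make_dynamic_phantom()
  proj <- projector(ph$n, ph$voxel_mm)
  sino <- acquire(ph, acquisition_config(views = 1000, n_rotations = 5,
                                         seed = 7), proj)
  list(phantom = ph, proj = proj, sino = sino)
})

# a quickly trained (weak but functional) segmentation model
fix_tiny_model <- function() memo("tiny_model", function() {
  ds <- make_lv_dataset(48, seed = 5)
  train <- list(images = ds$images[, , 1:36], masks = ds$masks[, , 1:36])
  val <- list(images = ds$images[, , 37:48], masks = ds$masks[, , 37:48])
  train_unet(train, val, epochs = 6, seed = 9)
})

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps), tol)
}
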
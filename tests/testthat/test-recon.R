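test_that("FBP reconstructs a uniform disk quantitatively", {
  fx <- fix_water()
  img <- fbp(fx$sino0, bin = 1, proj = fx$proj)
  mu_w <- bin_effective_mu(material_library()$water, 1)
  expect_rel(mean(img[fx$roi]), mu_w, 0.03)
  # zero sinogram -> zero image
  z <- fx$sino0; z$data[] <- 0
  expect_equal(max(abs(fbp(z, bin = 1, proj = fx$proj))), 0)
  expect_error(fbp(fx$sino0, subset = integer(0)), "empty")
  # 1/10 angular subset: same ROI mean within 5%, higher streak variance
  img_full <- fbp(fx$sinoN, bin = 1, proj = fx$proj)
  img_sub <- fbp(fx$sinoN, bin = 1, subset = seq(1, 360, by = 10),
                 proj = fx$proj)
  expect_rel(mean(img_sub[fx$roi]), mean(img_full[fx$roi]), 0.05)
  expect_gt(sd(img_sub[fx$roi]), sd(img_full[fx$roi]))
})

test_that("temporal bilateral filter has the specified fixed points and limits", {
  set.seed(4)
  base <- matrix(rnorm(100), 100, 1)[, rep(1, 6)]
  expect_equal(temporal_bilateral_filter(base), base, tolerance = 1e-12)
  # direct evaluation of the bilateral weight formula as the oracle
  x <- matrix(rnorm(600), 100, 6)
  got <- temporal_bilateral_filter(x, sigma_domain = 1, sigma_range = 0.7,
                                   window = 2)
  oracle <- x
  for (p in 1:100) for (t in 1:6) {
    num <- x[p, t]; den <- 1
    for (o in setdiff(-2:2, 0)) {
      s <- ((t - 1 + o) %% 6) + 1
      w <- exp(-o^2 / 2) * exp(-(x[p, s] - x[p, t])^2 / (2 * 0.7^2))
      num <- num + w * x[p, s]; den <- den + w
    }
    oracle[p, t] <- num / den
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  # one-phase impulse (within the range sigma) is attenuated by at least
  # half; a strong edge exceeding the range sigma is preserved within 5%
  stack <- matrix(0.1, 50, 6)
  stack[25, 3] <- stack[25, 3] + 0.5          # impulse in one phase
  stack[10, 3:6] <- 5                         # temporal edge >> range sigma
  f <- temporal_bilateral_filter(stack, sigma_range = 1.0)
  expect_lt(f[25, 3] - 0.1, 0.5 * 0.5)
  expect_rel(f[10, 4], 5, 0.05)
  # infinite range sigma reduces to plain Gaussian smoothing in time
  g <- temporal_bilateral_filter(x, sigma_domain = 1, sigma_range = Inf, window = 2)
  w <- exp(-(-2:2)^2 / 2)
  oracle2 <- x
  for (t in 1:6) {
    idx <- ((t - 1 + -2:2) %% 6) + 1
    oracle2[, t] <- (x[, idx] %*% w) / sum(w)
  }
  expect_equal(g, oracle2, tolerance = 1e-12)
})

test_that("rank-sparse energy filter: fixed points, identity, and denoising", {
  set.seed(5)
  # spectrally proportional (rank-1) stack is an exact fixed point
  u <- abs(rnorm(16 * 16)); v <- c(1, 0.7, 0.5, 0.4)
  clean <- array(outer(u, v), c(16, 16, 4))
  expect_equal(energy_rank_sparse_filter(clean), clean, tolerance = 1e-12)
  # zero threshold and disabled kernel -> identity
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  expect_equal(energy_rank_sparse_filter(x, tau = 0, sigma_spatial = 0), x,
               tolerance = 1e-12)
  # rank-1 signal + iid noise: RMSE strictly reduced (Monte-Carlo, fixed seed)
  noisy <- clean + array(rnorm(length(clean), 0, 0.1), dim(clean))
  den <- energy_rank_sparse_filter(noisy, tau = 0.05, sigma_spatial = 1.5)
  expect_lt(sqrt(mean((den - clean)^2)), sqrt(mean((noisy - clean)^2)))
})

test_that("HU conversion closed forms", {
  expect_equal(to_hu(0.2, 0.2), 0)
  expect_equal(to_hu(0, 0.2), -1000)
  expect_equal(to_hu(0.5, 0.2), 1500)
  expect_error(to_hu(0.2, 0), "positive")
})

test_that("iterative reconstruction matches least squares when unregularized", {
  fx <- fix_water()
  rv <- iterative_recon(fx$sino0, bins = 1, proj = fx$proj,
                        reg = regularizer_config(lambda_tv = 0, outer = 3,
                                                 inner = 30, bilateral = NULL,
                                                 rskr = NULL))
  A <- system_matrix(fx$proj, fx$sino0$angles)
  y <- as.vector(fx$sino0$data[, , 1])
  xls <- pcctcardiac:::cg_solve(function(v) as.vector(Matrix::crossprod(A, A %*% v)),
                                as.vector(Matrix::crossprod(A, y)),
                                numeric(fx$n^2), 150)
  expect_rel(mean(rv$data[, , 1, 1][fx$roi]),
             mean(matrix(xls, fx$n, fx$n)[fx$roi]), 0.01)
  # and the FBP ROI mean agrees with the least-squares solution within 1%
  expect_rel(mean(fbp(fx$sino0, proj = fx$proj)[fx$roi]),
             mean(matrix(xls, fx$n, fx$n)[fx$roi]), 0.01)
})

test_that("multi-channel consistency on noiseless data and invalid inputs", {
  fx <- fix_water()
  rv <- iterative_recon(fx$sino0, bins = 1:4, proj = fx$proj,
                        reg = regularizer_config(outer = 2))
  for (b in 1:4) {
    expect_rel(mean(rv$data[, , 1, b][fx$roi]),
               mean(fbp(fx$sino0, bin = b, proj = fx$proj)[fx$roi]), 0.02)
  }
  expect_error(iterative_recon(acquire(fx$phantom,
                                       acquisition_config(views = 8, noise = FALSE,
                                                          photons_per_ray = 1e3),
                                       fx$proj)),
               "log-mode")
  expect_error(regularizer_config(outer = 0), "counts")
  expect_error(regularizer_config(lambda_tv = -1), "non-negative")
})

test_that("split-Bregman denoises the water phantom without biasing the mean", {
  fx <- fix_water()
  f1 <- fbp(fx$sinoN, bin = 1, proj = fx$proj)
  rv <- iterative_recon(fx$sinoN, bins = 1, proj = fx$proj,
                        reg = regularizer_config(outer = 5))
  it <- rv$data[, , 1, 1]
  expect_rel(mean(it[fx$roi]), mean(f1[fx$roi]), 0.03) # matched ROI mean
  expect_lte(sd(it[fx$roi]), 0.5 * sd(f1[fx$roi]))     # >= 2x noise reduction
  # objective recorded and non-increasing within 0.1% per outer iteration
  expect_gte(length(rv$objective), 2)
  expect_true(all(diff(rv$objective) <= 1e-3 * head(rv$objective, -1)))
})

test_that("gated diastole image is sharper at the LV border than the time average", {
  fx <- fix_dynamic()
  gr <- intrinsic_gating(fx$sino, proj = fx$proj)
  lg <- suppressWarnings(log_normalize(fx$sino))
  dia_bin <- which.max(vapply(0:9, function(p)
    sum(gr$per_view_phase == p & abs(fx$sino$phases_truth - 0.5) > 0.4), 0))
  gated <- fbp(lg, bin = 1, subset = gr$phase_subsets[[dia_bin]], proj = fx$proj)
  ungated <- fbp(lg, bin = 1, proj = fx$proj)
  ph <- fx$phantom
  g <- ph$grid
  d <- sqrt((g$x - ph$lv_center_mm[1])^2 + (g$y - ph$lv_center_mm[2])^2)
  rd <- pcctcardiac:::lv_radius(ph, 0)
  border <- abs(d - rd) < 0.4
  grad_mag <- function(img) {
    gx <- pcctcardiac:::grad_x(img); gy <- pcctcardiac:::grad_y(img)
    sqrt(gx^2 + gy^2)
  }
  expect_gt(mean(grad_mag(gated)[border]), mean(grad_mag(ungated)[border]))
})
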
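test_that("composite loss equals independently computed BCE + (1 - soft Dice)", {
  set.seed(13)
  for (i in 1:10) {
    p <- array(runif(200, 0.01, 0.99), c(10, 20))
    y <- array(rbinom(200, 1, 0.3), c(10, 20))
    bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
    dice <- (2 * sum(p * y) + 1) / (sum(p) + sum(y) + 1)
    expect_equal(composite_loss(p, y), bce + (1 - dice), tolerance = 1e-9)
  }
  # half-ones truth under a constant 0.5 prediction: BCE = ln 2 and the
  # smoothed soft-Dice term has the closed form (N/2 + 1)/(N + 1)
  N <- 400
  y <- c(rep(1, N / 2), rep(0, N / 2))
  p <- rep(0.5, N)
  expect_equal(composite_loss(p, y), log(2) + 1 - (N / 2 + 1) / (N + 1),
               tolerance = 1e-12)
  # near-perfect prediction: loss bounded by the clamping scale
  eps <- 1e-7
  yp <- ifelse(y == 1, 1 - eps, eps)
  expect_lt(composite_loss(yp, y), 3 * eps * N)
  # empty truth mask stays finite through the smoothing constant
  expect_true(is.finite(composite_loss(rep(eps, N), rep(0, N))))
  expect_warning(composite_loss(c(0, 0.5, 1), c(0, 1, 1)), "clamped")
})

test_that("U-Net backpropagation matches numerical gradients", {
  m <- unet_init(size = 8, base = 2, levels = 2, seed = 3)
  set.seed(4)
  x <- array(rnorm(8 * 8 * 2), c(64, 2, 1))
  R <- array(rnorm(64 * 2), c(64, 2, 1))
  fw <- pcctcardiac:::unet_forward(m, x, record = TRUE)
  g <- pcctcardiac:::unet_backward(m, fw$tape, R)
  loss_of <- function(mm) sum(pcctcardiac:::unet_forward(mm, x)$logits * R)
  eps <- 1e-6
  for (nm in names(g)) for (f in c("W", "b")) {
    P <- m$params[[nm]][[f]]
    for (k in sample(length(P), min(3, length(P)))) {
      mp <- m; mp$params[[nm]][[f]][k] <- P[k] + eps
      mn <- m; mn$params[[nm]][[f]][k] <- P[k] - eps
      num <- (loss_of(mp) - loss_of(mn)) / (2 * eps)
      expect_lt(abs(num - g[[nm]][[f]][k]) / max(abs(num), 1e-6), 1e-4)
    }
  }
})

test_that("augmentation preserves geometry contracts", {
  ds <- make_lv_dataset(2, seed = 3)
  smp <- list(image = ds$images[, , 1], mask = ds$masks[, , 1])
  # zero-magnitude augmentation is the identity (input already normalized)
  out <- augment(smp, seed = 1, max_shift = 0, max_zoom = 0, max_rotate = 0)
  expect_equal(out$image, smp$image, tolerance = 1e-9)
  expect_identical(out$mask != 0, smp$mask != 0)
  # exact 90-degree rotation conserves the mask voxel count
  n <- 64
  ci <- (n + 1) / 2
  ii <- matrix(seq_len(n), n, n) - ci
  jj <- matrix(seq_len(n), n, n, byrow = TRUE) - ci
  th <- pi / 2
  xi <- cos(th) * ii + sin(th) * jj + ci
  yi <- -sin(th) * ii + cos(th) * jj + ci
  rot <- pcctcardiac:::nearest_sample(smp$mask, xi, yi)
  expect_equal(sum(rot != 0), sum(smp$mask != 0))
  # 1.2x zoom scales the mask area by ~1.44 (area scaling, within 5%)
  zoom <- 1.2
  xi <- ii / zoom + ci; yi <- jj / zoom + ci
  zoomed <- pcctcardiac:::nearest_sample(smp$mask, xi, yi)
  expect_rel(sum(zoomed != 0), zoom^2 * sum(smp$mask != 0), 0.05)
  # seeded augmentation is reproducible and renormalized
  a1 <- augment(smp, seed = 77); a2 <- augment(smp, seed = 77)
  expect_identical(a1, a2)
  expect_lt(abs(mean(a1$image)), 1e-6)
  expect_lt(abs(sd(a1$image) - 1), 1e-6)
})

test_that("dataset generation is seeded, normalized, and binary-masked", {
  ds <- make_lv_dataset(4, seed = 9)
  ds2 <- make_lv_dataset(4, seed = 9)
  expect_identical(ds, ds2)
  for (k in 1:4) {
    expect_lt(abs(mean(ds$images[, , k])), 1e-6)
    expect_lt(abs(sd(ds$images[, , k]) - 1), 1e-6)
    expect_true(all(ds$masks[, , k] %in% c(0L, 1L)))
  }
  di <- make_lv_dataset(2, seed = 9, kind = "iodine")
  # iodine maps: the LV is the only strong structure
  expect_gt(mean(di$images[, , 1][di$masks[, , 1] == 1]),
            mean(di$images[, , 1][di$masks[, , 1] == 0]) + 1)
})

test_that("train/val/test split reproduces the reference partition sizes", {
  sp <- split_samples(246, seed = 1)
  expect_equal(lengths(sp), c(train = 186L, val = 38L, test = 22L))
  expect_identical(sort(unname(unlist(sp))), 1:246)
  # shuffle happens before separation
  expect_false(identical(sp$train, 1:186))
  sp200 <- split_samples(200, seed = 2)
  expect_equal(sum(lengths(sp200)), 200)
})

test_that("training report traces losses and the LR plateau rule exactly", {
  ds <- make_lv_dataset(12, seed = 15)
  tiny <- list(images = ds$images[, , 1:8], masks = ds$masks[, , 1:8])
  val <- list(images = ds$images[, , 9:12], masks = ds$masks[, , 9:12])
  tr1 <- train_unet(tiny, val, epochs = 1, seed = 1)
  expect_length(tr1$report$train_loss, 1)
  expect_length(tr1$report$val_loss, 1)
  expect_true(tr1$report$threshold > 0 && tr1$report$threshold < 1)
  # zero learning rate freezes the model: validation loss is constant, and
  # the plateau rule fires exactly once after epoch 6 (patience 5)
  tr0 <- train_unet(tiny, val, epochs = 6, lr = 0, seed = 1)
  expect_equal(diff(range(tr0$report$val_loss)), 0, tolerance = 1e-12)
  expect_identical(tr0$report$lr_events, 6L)
  expect_error(train_unet(list(images = array(0, c(64, 64, 0)),
                               masks = array(0, c(64, 64, 0))), val),
               "empty")
  # determinism of a short training run
  tr2 <- train_unet(tiny, val, epochs = 1, seed = 1)
  expect_identical(tr1$report$val_loss, tr2$report$val_loss)
})

test_that("threshold selection matches exhaustive search with the tie rule", {
  set.seed(17)
  probs <- runif(5000)
  truth <- rbinom(5000, 1, 0.25)
  got <- select_threshold(probs, truth)
  grid <- seq(0.01, 0.99, by = 0.01)
  gaps <- sapply(grid, function(t) {
    pred <- probs >= t
    tp <- sum(pred & truth == 1)
    prec <- if (sum(pred) == 0) 1 else tp / sum(pred)
    rec <- tp / sum(truth == 1)
    abs(prec - rec)
  })
  expect_equal(got, grid[which.min(gaps)])
  expect_lte(gaps[match(got, grid)], min(gaps))
  # perfect predictor: P == R at every threshold, tie broken to 0.01
  expect_equal(select_threshold(c(rep(0.999, 50), rep(0.001, 50)),
                                c(rep(1, 50), rep(0, 50))), 0.01)
  # probs = truth * 0.8 + 0.1: P == R == 1 on (0.1, 0.9]; grid tie -> 0.11
  truth2 <- rbinom(200, 1, 0.4)
  expect_equal(select_threshold(truth2 * 0.8 + 0.1, truth2), 0.11)
})

test_that("segmentation evaluation metrics match hand-enumerated cases", {
  y <- c(1, 1, 0, 0)
  expect_equal(unname(evaluate_segmentation(c(1, 1, 0, 0), y, 0.5)),
               c(1, 1, 1, 1))
  ev0 <- evaluate_segmentation(c(0, 0, 1, 1), y, 0.5)
  expect_equal(unname(ev0[c("dice", "precision", "recall")]), c(0, 0, 0))
  ev <- evaluate_segmentation(c(0.9, 0.4, 0.6, 0.1), y, 0.5)
  expect_equal(unname(ev), c(0.5, 0.5, 0.5, 0.75))
})

test_that("both network input kinds run through the same training harness", {
  for (kind in c("ct", "iodine")) {
    ds <- make_lv_dataset(10, seed = 19, kind = kind)
    tr <- train_unet(list(images = ds$images[, , 1:7], masks = ds$masks[, , 1:7]),
                     list(images = ds$images[, , 8:10], masks = ds$masks[, , 8:10]),
                     epochs = 1, seed = 2)
    expect_s3_class(tr$report, "train_report")
  }
})

test_that("a briefly trained model segments its own domain", {
  tr <- fix_tiny_model()
  ds <- make_lv_dataset(6, seed = 23)
  probs <- predict_unet(tr$model, ds$images)
  ev <- evaluate_segmentation(probs, ds$masks, 0.5)
  expect_gt(ev["auc"], 0.9) # ranking quality after 3 epochs
  # crop-based segmentation returns a full-size mask
  big <- matrix(rnorm(96 * 96), 96, 96)
  mask <- segment_image(tr$model, big)
  expect_identical(dim(mask), c(96L, 96L))
  expect_error(segment_image(tr$model, matrix(0, 32, 32)), "smaller")
})
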
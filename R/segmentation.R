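# Left-ventricle segmentation: composite BCE + (1 - soft Dice) loss,
# intensity/zoom/rotation augmentation, U-Net training with the Adam
# optimizer and a validation-plateau learning-rate schedule,
# precision-recall-balanced threshold selection, and Dice / precision /
# recall / AUC evaluation.

#' Normalize an image to zero mean, unit standard deviation
#'
#' @param image numeric array.
#' @return normalized array.
#' @export
normalize_image <- function(image) {
  s <- stats::sd(image)
  if (s == 0) return(image - mean(image))
  (image - mean(image)) / s
}

soft_dice <- function(pred, truth, smooth = 1) {
  (2 * sum(pred * truth) + smooth) / (sum(pred) + sum(truth) + smooth)
}

#' Composite segmentation loss: BCE + (1 - soft Dice)
#'
#' Binary cross entropy plus one minus the soft Dice coefficient (smoothing
#' constant 1), evaluated over the whole input (single-sample semantics; the
#' training loop averages per-sample Dice over the batch). Probabilities are
#' clamped to `[eps, 1 - eps]` with a warning.
#'
#' @param pred_probs predicted probabilities in (0, 1).
#' @param truth_mask ground-truth labels in {0, 1}, same shape.
#' @param eps clamping constant.
#' @return scalar loss (non-negative; zero iff the prediction is perfect in
#'   the limit `eps -> 0`).
#' @export
composite_loss <- function(pred_probs, truth_mask, eps = 1e-7) {
  if (any(pred_probs < eps | pred_probs > 1 - eps)) {
    warnf("predicted probabilities clamped to [%g, %g]", eps, 1 - eps)
    pred_probs <- clamp(pred_probs, eps, 1 - eps)
  }
  bce <- -mean(truth_mask * log(pred_probs) + (1 - truth_mask) * log(1 - pred_probs))
  bce + (1 - soft_dice(pred_probs, truth_mask))
}

# bilinear sampling of img at (continuous) coordinates; outside -> fill
bilinear_sample <- function(img, xi, yi, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  get <- function(i, j) {
    ok <- i >= 1 & i <= H & j >= 1 & j <= W
    v <- rep(fill, length(i))
    v[ok] <- img[cbind(i[ok], j[ok])]
    v
  }
  v <- get(x0, y0) * (1 - fx) * (1 - fy) + get(x0 + 1, y0) * fx * (1 - fy) +
    get(x0, y0 + 1) * (1 - fx) * fy + get(x0 + 1, y0 + 1) * fx * fy
  matrix(v, H, W)
}

nearest_sample <- function(img, xi, yi, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  i <- round(xi); j <- round(yi)
  ok <- i >= 1 & i <= H & j >= 1 & j <= W
  v <- rep(fill, length(i))
  v[ok] <- img[cbind(i[ok], j[ok])]
  matrix(v, H, W)
}

#' Augment a segmentation sample
#'
#' Random intensity shift, isotropic zoom about the image center, and
#' rotation; the mask receives the identical geometric transform with
#' nearest-neighbour interpolation, and the image is re-normalized.
#'
#' @param sample `list(image =, mask =)` of matching matrices.
#' @param seed RNG seed.
#' @param max_shift intensity shift range (in normalized intensity units).
#' @param max_zoom zoom range half-width (e.g. 0.15 for 0.85x-1.15x).
#' @param max_rotate rotation range half-width, degrees.
#' @return augmented sample.
#' @export
augment <- function(sample, seed = NULL, max_shift = 0.1, max_zoom = 0.15,
                    max_rotate = 15) {
  draws <- with_seed(seed, stats::runif(3, -1, 1))
  shift <- draws[1] * max_shift
  zoom <- 1 + draws[2] * max_zoom
  theta <- draws[3] * max_rotate * pi / 180
  img <- sample$image
  H <- nrow(img); W <- ncol(img)
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  ii <- matrix(seq_len(H), H, W) - ci
  jj <- matrix(seq_len(W), H, W, byrow = TRUE) - cj
  # inverse map: output pixel -> source location (rotate by -theta, scale 1/zoom)
  xi <- (cos(theta) * ii + sin(theta) * jj) / zoom + ci
  yi <- (-sin(theta) * ii + cos(theta) * jj) / zoom + cj
  out_img <- bilinear_sample(img, xi, yi, fill = min(img)) + shift
  out_mask <- nearest_sample(sample$mask, xi, yi, fill = 0)
  list(image = normalize_image(out_img), mask = out_mask)
}

#' Synthetic left-ventricle slice dataset
#'
#' Generates normalized 2D slices emulating contrast-enhanced cardiac
#' micro-CT: an elliptical thorax, a bright elliptical iodinated LV blood
#' pool at variable position/size/orientation, darker lung-like regions,
#' and Gaussian noise. `kind = "iodine"` emulates decomposed iodine maps
#' (LV on a near-zero background).
#'
#' @param n number of samples.
#' @param size image side length.
#' @param seed RNG seed.
#' @param kind `"ct"` or `"iodine"`.
#' @param blur_sigma_px range of the additional Gaussian blur applied to
#'   each image (not the mask) on top of the reconstruction point-spread;
#'   the mask remains the sharp 50% contour.
#' @param psf point-spread kernel applied to every image before the random
#'   Gaussian component; defaults to the package reconstruction operator's
#'   own PSF ([recon_psf()]). `NULL` disables it.
#' @return list with `images` (`size x size x n`), `masks`, `kind`.
#' @export
make_lv_dataset <- function(n, size = 64, seed = 1, kind = c("ct", "iodine"),
                            blur_sigma_px = c(0.3, 1.2), psf = recon_psf()) {
  kind <- match.arg(kind)
  g <- pixel_grid(size, 1)
  blur_mat <- function(sigma) {
    d <- abs(outer(seq_len(size), seq_len(size), `-`))
    K <- exp(-d^2 / (2 * sigma^2))
    K / rowSums(K)
  }
  with_seed(seed, {
    images <- array(0, c(size, size, n))
    masks <- array(0L, c(size, size, n))
    for (k in seq_len(n)) {
      cx <- stats::runif(1, -size * 0.1, size * 0.1)
      cy <- stats::runif(1, -size * 0.1, size * 0.1)
      a <- stats::runif(1, size * 0.11, size * 0.28)
      b <- a * stats::runif(1, 0.75, 1)
      th <- stats::runif(1, 0, pi)
      lv <- ellipse_coverage(g$x, g$y, cx, cy, a, b, th, 1)
      # thorax mostly filling the field of view, as in a cropped cardiac scan
      body <- ellipse_coverage(g$x, g$y, stats::runif(1, -3, 3),
                               stats::runif(1, -3, 3),
                               size * stats::runif(1, 0.48, 0.60),
                               size * stats::runif(1, 0.44, 0.54), 0, 1)
      lungs <- matrix(0, size, size)
      for (s in c(-1, 1)) {
        lungs <- lungs + ellipse_coverage(g$x, g$y, s * size * 0.28,
                                          stats::runif(1, -4, 4),
                                          size * 0.1, size * 0.14, 0, 1)
      }
      img <- if (kind == "ct") {
        # contrast-enhanced attenuation: iodinated LV ~1.3-1.8x the body pool
        0.35 * body - 0.12 * lungs * body +
          0.35 * stats::runif(1, 0.30, 0.80) * lv
      } else {
        0.02 * body + lv * stats::runif(1, 0.85, 1.1)
      }
      if (!is.null(psf)) img <- conv2d_same(img, psf)
      K <- blur_mat(stats::runif(1, blur_sigma_px[1], blur_sigma_px[2]))
      img <- K %*% img %*% t(K)
      img <- img + stats::rnorm(size^2, 0, 0.015)
      images[, , k] <- normalize_image(img)
      masks[, , k] <- as.integer(lv >= 0.5)
    }
    list(images = images, masks = masks, kind = kind)
  })
}

#' Reconstruction-domain left-ventricle training samples
#'
#' Generates segmentation samples through the package's own forward and
#' reconstruction operators: random static LV phantoms are acquired with
#' counting noise, reconstructed by FBP of the cumulative lowest-threshold
#' channel, and center-cropped. Mixing these with [make_lv_dataset()]
#' samples matches the segmenter to the reconstruction domain it will see
#' inside the pipeline.
#'
#' @param n number of samples.
#' @param seed RNG seed.
#' @param size crop side length, pixels.
#' @param grid_n,voxel_mm simulation grid.
#' @param views projection views per sample.
#' @param photons_per_ray counting statistics.
#' @return list with `images`, `masks` as in [make_lv_dataset()].
#' @export
make_lv_recon_samples <- function(n, seed = 1, size = 64, grid_n = 96,
                                  voxel_mm = 0.25, views = 100,
                                  photons_per_ray = 3e4) {
  proj <- projector(grid_n, voxel_mm)
  r0 <- floor((grid_n - size) / 2)
  draws <- with_seed(seed, data.frame(
    vol = stats::runif(n, 0.012, 0.075),
    cx = stats::runif(n, -2, 2), cy = stats::runif(n, -2, 2),
    iod = stats::runif(n, 14, 26),
    ax = stats::runif(n, 8.2, 9.6), ay = stats::runif(n, 7.4, 8.6)))
  images <- array(0, c(size, size, n))
  masks <- array(0L, c(size, size, n))
  for (k in seq_len(n)) {
    ph <- make_dynamic_phantom(n = grid_n, voxel_mm = voxel_mm,
                               dlvv_ml = draws$vol[k], slvv_ml = draws$vol[k],
                               iodine_blood_mgml = draws$iod[k],
                               body_axes_mm = c(draws$ax[k], draws$ay[k]),
                               lv_center_mm = c(draws$cx[k], draws$cy[k]))
    cfg <- acquisition_config(views = views, n_rotations = 1,
                              photons_per_ray = photons_per_ray,
                              seed = stage_seed(seed, paste0("lvsim", k)))
    img <- fbp(acquire(ph, cfg, proj), bin = "sum", proj = proj)
    crop <- img[r0 + seq_len(size), r0 + seq_len(size)]
    images[, , k] <- normalize_image(crop)
    masks[, , k] <- lv_mask(ph, 0)[r0 + seq_len(size), r0 + seq_len(size)]
  }
  list(images = images, masks = masks, kind = "recon-sim")
}

#' Gated-domain left-ventricle training samples
#'
#' Harvests segmentation samples from the pipeline's own gated imaging
#' chain: beating phantoms with randomized volumes, rates and positions are
#' acquired, intrinsically gated, and reconstructed per phase by FBP of the
#' cumulative lowest-threshold channel; every phase slice becomes one
#' sample, labeled with the rendered mask at its bin-center phase. These
#' carry the gated domain's irregular view subsets and residual within-bin
#' motion, which uniformly-sampled static reconstructions do not.
#'
#' @param n_phantoms number of beating phantoms (10 samples each).
#' @param seed RNG seed.
#' @param size crop side length, pixels.
#' @param grid_n,voxel_mm simulation grid.
#' @param views,n_rotations scan protocol.
#' @return list with `images`, `masks` as in [make_lv_dataset()].
#' @export
make_lv_gated_samples <- function(n_phantoms, seed = 1, size = 64,
                                  grid_n = 96, voxel_mm = 0.25,
                                  views = 1000, n_rotations = 5) {
  proj <- projector(grid_n, voxel_mm)
  r0 <- floor((grid_n - size) / 2)
  draws <- with_seed(seed, data.frame(
    hr = stats::runif(n_phantoms, 380, 520),
    dlvv = stats::runif(n_phantoms, 0.030, 0.058),
    ratio = stats::runif(n_phantoms, 0.40, 0.75),
    cx = stats::runif(n_phantoms, -2, 2), cy = stats::runif(n_phantoms, -2, 2),
    iod = stats::runif(n_phantoms, 15, 25)))
  n_phases <- 10
  images <- array(0, c(size, size, n_phantoms * n_phases))
  masks <- array(0L, c(size, size, n_phantoms * n_phases))
  k_out <- 0
  for (k in seq_len(n_phantoms)) {
    ph <- make_dynamic_phantom(n = grid_n, voxel_mm = voxel_mm,
                               heart_rate = draws$hr[k],
                               dlvv_ml = draws$dlvv[k],
                               slvv_ml = draws$dlvv[k] * draws$ratio[k],
                               iodine_blood_mgml = draws$iod[k],
                               lv_center_mm = c(draws$cx[k], draws$cy[k]))
    sino <- acquire(ph, acquisition_config(views = views,
                                           n_rotations = n_rotations,
                                           seed = stage_seed(seed, paste0("gacq", k))),
                    proj)
    gr <- intrinsic_gating(sino, n_phases = n_phases, proj = proj)
    for (p in seq_len(n_phases)) {
      img <- fbp(sino, bin = "sum", subset = gr$phase_subsets[[p]], proj = proj)
      k_out <- k_out + 1
      images[, , k_out] <- normalize_image(img[r0 + seq_len(size), r0 + seq_len(size)])
      # label at the bin-averaged effective area, not the bin center: the
      # raised-cosine curvature makes the within-bin mean area larger than
      # the center area at systole and smaller at diastole (sinc factor)
      shrink <- sin(pi / n_phases) / (pi / n_phases)
      w_eff <- 0.5 + 0.5 * shrink * cos(2 * pi * (p - 1) / n_phases)
      area_eff <- ph$area_s + (ph$area_d - ph$area_s) * w_eff
      cov <- pcct_disk_cov(ph, sqrt(area_eff / pi))
      masks[, , k_out] <- (cov >= 0.5)[r0 + seq_len(size), r0 + seq_len(size)]
    }
  }
  list(images = images, masks = masks, kind = "gated-sim")
}

#' Shuffled train/validation/test split
#'
#' Randomly shuffles sample indices and splits them with the given
#' proportions (training, validation, test), rounding so the three sizes
#' total `n` exactly.
#'
#' @param n number of samples.
#' @param proportions length-3 numeric summing to 1; the default mirrors a
#'   186/38/22 split of 246 samples.
#' @param seed shuffle seed.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_samples <- function(n, proportions = c(186, 38, 22) / 246, seed = 1) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8)
  idx <- with_seed(seed, sample.int(n))
  n_train <- round(n * proportions[1])
  n_val <- round(n * proportions[2])
  list(train = idx[seq_len(n_train)],
       val = idx[n_train + seq_len(n_val)],
       test = idx[(n_train + n_val + 1):n])
}

predict_logits <- function(model, images, batch = 16) {
  n <- dim(images)[3]
  H <- dim(images)[1]; W <- dim(images)[2]
  out <- array(0, dim(images))
  for (s in seq(1, n, by = batch)) {
    ix <- s:min(s + batch - 1, n)
    xb <- array(images[, , ix], c(H * W, length(ix), 1))
    out[, , ix] <- array(unet_forward(model, xb)$logits, c(H, W, length(ix)))
  }
  out
}

#' Predict segmentation probabilities
#'
#' @param model a trained [unet_init()] model.
#' @param images `H x W x n` array of normalized images (or a single
#'   matrix).
#' @return array of voxelwise probabilities, same shape.
#' @export
predict_unet <- function(model, images) {
  if (length(dim(images)) == 2) images <- array(images, c(dim(images), 1))
  sigmoid(predict_logits(model, images))
}

batch_loss_grad <- function(model, xb, yb) {
  # xb, yb: (HW, B, 1); returns loss and dL/dlogits
  fw <- unet_forward(model, xb, record = TRUE)
  p <- clamp(sigmoid(fw$logits), 1e-7, 1 - 1e-7)
  B <- dim(xb)[2]
  ntot <- length(p)
  bce <- -sum(yb * log(p) + (1 - yb) * log(1 - p)) / ntot
  dlog <- (p - yb) / ntot
  dice_sum <- 0
  for (b in seq_len(B)) {
    pb <- p[, b, 1]; yv <- yb[, b, 1]
    sp <- sum(pb); sy <- sum(yv); spy <- sum(pb * yv)
    den <- sp + sy + 1
    dice_sum <- dice_sum + (2 * spy + 1) / den
    ddice_dp <- (2 * yv * den - (2 * spy + 1)) / den^2
    dlog[, b, 1] <- dlog[, b, 1] - (ddice_dp / B) * pb * (1 - pb)
  }
  list(loss = bce + (1 - dice_sum / B), fw = fw, dlogits = dlog)
}

eval_loss <- function(model, images, masks, batch = 16) {
  n <- dim(images)[3]
  H <- dim(images)[1]; W <- dim(images)[2]
  total <- 0; wsum <- 0
  for (s in seq(1, n, by = batch)) {
    ix <- s:min(s + batch - 1, n)
    xb <- array(images[, , ix], c(H * W, length(ix), 1))
    yb <- array(masks[, , ix], c(H * W, length(ix), 1))
    fw <- unet_forward(model, xb)
    p <- clamp(sigmoid(fw$logits), 1e-7, 1 - 1e-7)
    bce <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
    ds <- mean(vapply(seq_along(ix), function(b)
      soft_dice(p[, b, 1], yb[, b, 1]), numeric(1)))
    total <- total + (bce + 1 - ds) * length(ix)
    wsum <- wsum + length(ix)
  }
  total / wsum
}

#' Train a U-Net left-ventricle segmenter
#'
#' Adam optimization of the composite BCE + (1 - soft Dice) loss with
#' seeded shuffling and augmentation. The learning rate decays by
#' `lr_factor` whenever the validation loss has not improved for
#' `patience` epochs; the best-validation parameters are returned. After
#' training, the decision threshold balancing precision and recall on the
#' training set is selected.
#'
#' @param train_set,val_set lists with `images` and `masks` arrays
#'   (`H x W x n`); the sets must be disjoint.
#' @param epochs maximum training epochs.
#' @param lr initial Adam learning rate.
#' @param batch minibatch size.
#' @param patience plateau epochs before a learning-rate decay.
#' @param lr_factor decay factor.
#' @param base,levels U-Net width and depth.
#' @param use_augment apply random augmentation to training batches.
#' @param seed seed controlling initialization, shuffling and augmentation.
#' @return list with `model` (best-validation checkpoint), `report` (class
#'   `train_report`: per-epoch train/val losses, LR decay events, selected
#'   threshold, split sizes, seed).
#' @export
train_unet <- function(train_set, val_set, epochs = 50, lr = 5e-4, batch = 16,
                       patience = 5, lr_factor = 0.1, base = 8, levels = 3,
                       use_augment = TRUE, seed = 1) {
  n_tr <- dim(train_set$images)[3]
  n_va <- dim(val_set$images)[3]
  if (n_tr == 0 || n_va == 0) stopf("empty training or validation set")
  H <- dim(train_set$images)[1]; W <- dim(train_set$images)[2]
  model <- unet_init(size = H, base = base, levels = levels, seed = seed)
  state <- new.env(parent = emptyenv()); state$t <- 0; state$m <- list(); state$v <- list()
  cur_lr <- lr
  train_losses <- val_losses <- numeric(0)
  lr_events <- integer(0)
  best_val <- Inf; best_params <- model$params; best_epoch <- 0
  anchor <- 0  # epoch of last improvement or LR decay
  for (ep in seq_len(epochs)) {
    ord <- with_seed(stage_seed(seed, paste0("shuffle", ep)), sample.int(n_tr))
    ep_loss <- 0; nb <- 0
    for (s in seq(1, n_tr, by = batch)) {
      ix <- ord[s:min(s + batch - 1, n_tr)]
      B <- length(ix)
      xb <- array(0, c(H * W, B, 1)); yb <- array(0, c(H * W, B, 1))
      for (b in seq_len(B)) {
        smp <- list(image = train_set$images[, , ix[b]],
                    mask = train_set$masks[, , ix[b]])
        if (use_augment)
          smp <- augment(smp, seed = stage_seed(seed, sprintf("aug%d_%d", ep, ix[b])))
        xb[, b, 1] <- smp$image
        yb[, b, 1] <- smp$mask
      }
      bl <- batch_loss_grad(model, xb, yb)
      grads <- unet_backward(model, bl$fw$tape, bl$dlogits)
      model$params <- adam_step(model$params, grads, state, cur_lr)
      ep_loss <- ep_loss + bl$loss; nb <- nb + 1
    }
    train_losses <- c(train_losses, ep_loss / nb)
    vl <- eval_loss(model, val_set$images, val_set$masks, batch)
    val_losses <- c(val_losses, vl)
    if (vl < best_val) {
      best_val <- vl; best_params <- model$params; best_epoch <- ep
      anchor <- ep
    } else if (ep - anchor >= patience) {
      cur_lr <- cur_lr * lr_factor
      lr_events <- c(lr_events, ep)
      anchor <- ep
    }
  }
  model$params <- best_params
  probs <- predict_unet(model, train_set$images)
  thr <- select_threshold(probs, train_set$masks)
  report <- structure(list(train_loss = train_losses, val_loss = val_losses,
                           lr_events = lr_events, threshold = thr,
                           best_epoch = best_epoch, best_val = best_val,
                           split_sizes = c(train = n_tr, val = n_va),
                           seed = seed),
                      class = "train_report")
  list(model = model, report = report)
}

precision_recall <- function(pred, truth) {
  tp <- sum(pred & truth)
  prec <- if (sum(pred) == 0) 1 else tp / sum(pred)
  rec <- if (sum(truth) == 0) 1 else tp / sum(truth)
  c(precision = prec, recall = rec)
}

#' Select the decision threshold balancing precision and recall
#'
#' Scans thresholds 0.01 to 0.99 in steps of 0.01 and returns the one
#' minimizing `|precision - recall|` on the supplied (training)
#' predictions; ties break to the lowest threshold.
#'
#' @param pred_probs predicted probabilities.
#' @param truth_mask ground-truth labels.
#' @return scalar threshold in (0, 1).
#' @export
select_threshold <- function(pred_probs, truth_mask) {
  grid <- seq(0.01, 0.99, by = 0.01)
  truth <- truth_mask != 0
  gap <- vapply(grid, function(t) {
    pr <- precision_recall(pred_probs >= t, truth)
    abs(pr[1] - pr[2])
  }, numeric(1))
  grid[which.min(gap)] # which.min takes the first (lowest) on ties
}

auc_mw <- function(scores, labels) {
  # Mann-Whitney AUC (rank-based, ties handled)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a segmentation against its reference
#'
#' Dice, precision and recall of the thresholded prediction, and
#' threshold-free voxelwise AUC (computed on a seeded subsample of at most
#' `max_auc_voxels` voxels).
#'
#' @param pred_probs predicted probabilities.
#' @param truth_mask reference labels.
#' @param threshold decision threshold (from [select_threshold()]).
#' @param max_auc_voxels AUC subsample cap.
#' @param seed subsample seed.
#' @return named numeric: `dice`, `precision`, `recall`, `auc`.
#' @export
evaluate_segmentation <- function(pred_probs, truth_mask, threshold = 0.5,
                                  max_auc_voxels = 1e6, seed = 1) {
  pred <- pred_probs >= threshold
  truth <- truth_mask != 0
  tp <- sum(pred & truth)
  dice <- if (sum(pred) + sum(truth) == 0) 1 else 2 * tp / (sum(pred) + sum(truth))
  pr <- precision_recall(pred, truth)
  sc <- as.vector(pred_probs); lb <- as.vector(truth)
  if (length(sc) > max_auc_voxels) {
    ix <- with_seed(seed, sample.int(length(sc), max_auc_voxels))
    sc <- sc[ix]; lb <- lb[ix]
  }
  c(dice = dice, precision = unname(pr[1]), recall = unname(pr[2]),
    auc = auc_mw(sc, lb))
}

#' Train and evaluate the segmenter on the synthetic slice benchmark
#'
#' Generates `n` synthetic LV slices, splits them with the standard
#' shuffled proportions, trains the default U-Net, and evaluates Dice,
#' precision, recall and AUC on the held-out test split at the
#' precision-recall-balanced threshold.
#'
#' @param n dataset size.
#' @param epochs training epochs.
#' @param seed RNG seed (dataset, split and training derive sub-seeds).
#' @param kind input kind, `"ct"` or `"iodine"` (the two-input comparison
#'   harness: run once with each).
#' @return list with `model`, `report`, `metrics` (held-out), `split`.
#' @export
lv_segmentation_benchmark <- function(n = 200, epochs = 15, seed = 1,
                                      kind = "ct") {
  ds <- make_lv_dataset(n, seed = stage_seed(seed, "lvdata"), kind = kind)
  sp <- split_samples(n, seed = stage_seed(seed, "lvsplit"))
  sets <- lapply(sp, function(ix)
    list(images = ds$images[, , ix, drop = FALSE],
         masks = ds$masks[, , ix, drop = FALSE]))
  tr <- train_unet(sets$train, sets$val, epochs = epochs,
                   seed = stage_seed(seed, "lvtrain"))
  probs <- predict_unet(tr$model, sets$test$images)
  metrics <- evaluate_segmentation(probs, sets$test$masks, tr$report$threshold)
  list(model = tr$model, report = tr$report, metrics = metrics, split = sp,
       sets = sets)
}

#' Train the pipeline segmenter on a domain-matched mixture
#'
#' Trains the default U-Net on synthetic slices mixed with
#' reconstruction-domain samples ([make_lv_recon_samples()]), which removes
#' the systematic boundary bias a purely synthetic-trained model shows on
#' reconstructed images.
#'
#' @param n_synth,n_sim sample counts for the two sources.
#' @param epochs training epochs.
#' @param seed RNG seed.
#' @return list with `model` and `report`.
#' @export
train_pipeline_segmenter <- function(n_synth = 200, n_sim = 64, n_sim_val = 24,
                                     n_gated_phantoms = 6, epochs = 15,
                                     seed = 1) {
  ds <- make_lv_dataset(n_synth, seed = stage_seed(seed, "lvdata"))
  sp <- split_samples(n_synth, seed = stage_seed(seed, "lvsplit"))
  sim <- make_lv_recon_samples(n_sim + n_sim_val, seed = stage_seed(seed, "lvsim"))
  gat <- make_lv_gated_samples(n_gated_phantoms, seed = stage_seed(seed, "lvgated"))
  n_gat <- dim(gat$images)[3]
  gat_val <- seq_len(n_gat) > n_gat - 20 # last two phantoms validate
  sz <- dim(ds$images)[1]
  tr_ix <- sp$train
  n_tr <- length(tr_ix) + n_sim + sum(!gat_val)
  train <- list(
    images = array(c(ds$images[, , tr_ix], sim$images[, , seq_len(n_sim)],
                     gat$images[, , !gat_val]), c(sz, sz, n_tr)),
    masks = array(c(ds$masks[, , tr_ix], sim$masks[, , seq_len(n_sim)],
                    gat$masks[, , !gat_val]), c(sz, sz, n_tr)))
  # validation covers all three domains (synthetic, static-recon, gated) so
  # the best checkpoint cannot drift away from the pipeline's own domain
  sim_val <- n_sim + seq_len(n_sim_val)
  n_va <- length(sp$val) + n_sim_val + sum(gat_val)
  val <- list(
    images = array(c(ds$images[, , sp$val], sim$images[, , sim_val],
                     gat$images[, , gat_val]), c(sz, sz, n_va)),
    masks = array(c(ds$masks[, , sp$val], sim$masks[, , sim_val],
                    gat$masks[, , gat_val]), c(sz, sz, n_va)))
  # volume calibration of a candidate on the gated-domain validation
  # samples: overall signed area error, and the large-vs-small spread that
  # propagates directly into a stroke-volume error
  calib_score <- function(model) {
    gi <- gat$images[, , gat_val, drop = FALSE]
    gm <- gat$masks[, , gat_val, drop = FALSE]
    probs <- predict_unet(model, gi)
    rel <- vapply(seq_len(dim(gi)[3]), function(k) {
      truth <- sum(gm[, , k])
      (sum(probs[, , k] >= 0.5) - truth) / truth
    }, numeric(1))
    sizes <- vapply(seq_len(dim(gi)[3]), function(k) sum(gm[, , k]), numeric(1))
    big <- sizes > stats::median(sizes)
    c(mean = mean(rel), spread = mean(rel[big]) - mean(rel[!big]))
  }
  best <- NULL; best_score <- Inf
  for (attempt in 1:2) {
    tr <- train_unet(train, val, epochs = epochs,
                     seed = stage_seed(seed, paste0("lvtrain",
                                                    if (attempt == 1) "" else attempt)))
    cs <- calib_score(tr$model)
    score <- max(abs(cs))
    if (score < best_score) {
      best <- tr; best_score <- score; best$calibration <- cs
    }
    if (score <= 0.06) break # volume-calibrated on the gated domain
  }
  list(model = best$model, report = best$report, calibration = best$calibration)
}

#' Segment an image with a trained model, cropping to the model size
#'
#' Larger images are segmented on their central `size x size` crop (after
#' normalization) and the prediction is pasted back; pixels outside the
#' crop are background. Probabilities are averaged over the four exact
#' lattice flips (identity, row flip, column flip, both), which suppresses
#' realization-specific boundary errors at negligible cost.
#'
#' @param model trained U-Net.
#' @param image 2D image (any intensity scale; normalized internally).
#' @param threshold decision threshold.
#' @param flip_average average predictions over the four exact flips.
#' @return logical mask of the same size as `image`.
#' @export
segment_image <- function(model, image, threshold = 0.5, flip_average = TRUE) {
  H <- nrow(image); W <- ncol(image)
  sz <- model$size
  if (H < sz || W < sz) stopf("image smaller than the model input (%d)", sz)
  r0 <- floor((H - sz) / 2); c0 <- floor((W - sz) / 2)
  crop <- normalize_image(image[r0 + seq_len(sz), c0 + seq_len(sz)])
  flips <- if (flip_average) list(c(FALSE, FALSE), c(TRUE, FALSE),
                                  c(FALSE, TRUE), c(TRUE, TRUE))
           else list(c(FALSE, FALSE))
  p <- matrix(0, sz, sz)
  for (fl in flips) {
    x <- crop
    if (fl[1]) x <- x[sz:1, ]
    if (fl[2]) x <- x[, sz:1]
    pk <- predict_unet(model, x)[, , 1]
    if (fl[2]) pk <- pk[, sz:1]
    if (fl[1]) pk <- pk[sz:1, ]
    p <- p + pk
  }
  p <- p / length(flips)
  mask <- matrix(FALSE, H, W)
  mask[r0 + seq_len(sz), c0 + seq_len(sz)] <- p >= threshold
  mask
}
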
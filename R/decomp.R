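# Image-domain material decomposition: sensitivity-matrix calibration from
# vials of known concentration, per-voxel (weighted) least-squares inversion
# of the multi-bin signal, and non-negativity enforcement by orthogonal
# subspace projection (iterative active-set removal of negative bases).

#' Calibrate a material sensitivity matrix from vial ROIs
#'
#' Least-squares fit of per-bin ROI mean signals against known vial
#' compositions: solves `S ~ Conc %*% M` for `M` (materials x bins), where
#' each vial contributes one row of mean signals and one row of known
#' concentrations.
#'
#' @param recon_stack `n x n x nbins` array of reconstructed images (mu or
#'   HU, used consistently).
#' @param vials list of vials, each `list(roi = <logical matrix>, conc =
#'   <named numeric>)` giving the known concentration of each basis material
#'   inside the ROI.
#' @param materials character vector of basis material names (default: union
#'   of names used by the vials).
#' @return object of class `sensitivity_matrix`: `$M` (materials x bins),
#'   `$condition` (condition number), `$residuals` of the fit.
#' @export
calibrate_sensitivity <- function(recon_stack, vials, materials = NULL) {
  nb <- dim(recon_stack)[3]
  if (is.null(materials)) materials <- unique(unlist(lapply(vials, function(v) names(v$conc))))
  Conc <- t(vapply(vials, function(v) {
    out <- stats::setNames(numeric(length(materials)), materials)
    out[names(v$conc)] <- v$conc
    out
  }, numeric(length(materials))))
  if (qr(Conc)$rank < length(materials))
    stopf("rank-deficient calibration design: %d vials cannot determine %d materials",
          nrow(Conc), length(materials))
  S <- t(vapply(vials, function(v) {
    vapply(seq_len(nb), function(b) mean(recon_stack[, , b][v$roi]), numeric(1))
  }, numeric(nb)))
  M <- solve(crossprod(Conc), crossprod(Conc, S))
  rownames(M) <- materials
  colnames(M) <- paste0("bin", seq_len(nb))
  sv <- svd(M)$d
  structure(list(M = M, condition = sv[1] / sv[length(sv)],
                 residuals = S - Conc %*% M, materials = materials),
            class = "sensitivity_matrix")
}

#' Per-voxel material decomposition with orthogonal subspace projection
#'
#' Solves the linear system `X = C M` at every voxel for the basis-material
#' concentrations `C` (least squares when bins > materials; optional
#' inverse-variance bin weights). Voxels with negative components are
#' re-solved with the most negative basis removed, repeatedly, until all
#' remaining components are non-negative (removed bases are set to zero) --
#' the orthogonal subspace projection.
#'
#' @param recon_stack `n x n x nbins` array of reconstructed images.
#' @param sens a [calibrate_sensitivity()] result, or a bare
#'   (materials x bins) matrix.
#' @param weights per-bin weights (default equal); alternatively supply
#'   `background_roi`, a logical matrix from which per-bin inverse-variance
#'   weights are estimated.
#' @param background_roi see `weights`.
#' @param condition_warn warn when the sensitivity condition number exceeds
#'   this value.
#' @return object of class `material_maps`: `$maps` named list of `n x n`
#'   concentration images (non-negative), plus the matrix used.
#' @export
decompose <- function(recon_stack, sens, weights = NULL, background_roi = NULL,
                      condition_warn = 1e3) {
  M <- if (inherits(sens, "sensitivity_matrix")) sens$M else sens
  nb <- dim(recon_stack)[3]
  nm <- nrow(M)
  if (nb < nm) stopf("need at least as many bins (%d) as materials (%d)", nb, nm)
  sv <- svd(M)$d
  if (sv[nm] <= sv[1] * 1e-12) stopf("singular sensitivity matrix")
  kappa <- sv[1] / sv[nm]
  if (kappa > condition_warn)
    warnf("sensitivity matrix is ill-conditioned (condition number %.3g)", kappa)
  if (!is.null(background_roi)) {
    v <- vapply(seq_len(nb), function(b) stats::var(recon_stack[, , b][background_roi]),
                numeric(1))
    weights <- 1 / pmax(v, .Machine$double.eps)
  }
  if (is.null(weights)) weights <- rep(1, nb)
  n1 <- dim(recon_stack)[1]; n2 <- dim(recon_stack)[2]
  X <- matrix(recon_stack, n1 * n2, nb)

  solve_subset <- function(X_rows, active) {
    Ma <- M[active, , drop = FALSE]
    B <- Ma %*% (weights * t(Ma))
    X_rows %*% (weights * t(Ma)) %*% solve(B)
  }

  C <- matrix(0, nrow(X), nm, dimnames = list(NULL, rownames(M)))
  active_sets <- list(seq_len(nm))
  rows_for <- list(seq_len(nrow(X)))
  while (length(active_sets) > 0) {
    new_sets <- list(); new_rows <- list()
    for (k in seq_along(active_sets)) {
      act <- active_sets[[k]]; rows <- rows_for[[k]]
      if (length(act) == 0 || length(rows) == 0) next
      Ck <- solve_subset(X[rows, , drop = FALSE], act)
      neg <- Ck < 0
      bad <- which(rowSums(neg) > 0)
      good <- setdiff(seq_along(rows), bad)
      C[rows[good], act] <- Ck[good, , drop = FALSE]
      if (length(bad) > 0) {
        worst <- act[apply(Ck[bad, , drop = FALSE], 1, which.min)]
        for (w in unique(worst)) {
          sub_rows <- rows[bad[worst == w]]
          new_act <- setdiff(act, w)
          new_sets <- c(new_sets, list(new_act))
          new_rows <- c(new_rows, list(sub_rows))
        }
      }
    }
    active_sets <- new_sets; rows_for <- new_rows
  }
  maps <- stats::setNames(lapply(seq_len(nm), function(m) matrix(C[, m], n1, n2)),
                          rownames(M))
  structure(list(maps = maps, M = M, condition = kappa, weights = weights),
            class = "material_maps")
}

#' Windowed RGB composite of material maps
#'
#' Deterministic channel-wise merge for visualization: each map is divided
#' by its window maximum, clamped to `[0, 1]`, and placed in its own
#' channel (R, G, B in map order).
#'
#' @param maps a [decompose()] result or named list of matrices (2 or 3).
#' @param windows numeric vector of window maxima, one per map.
#' @return `n x n x 3` array in `[0, 1]`.
#' @export
composite_rgb <- function(maps, windows) {
  m <- if (inherits(maps, "material_maps")) maps$maps else maps
  if (length(m) < 2 || length(m) > 3) stopf("composite_rgb takes 2 or 3 maps")
  if (length(windows) != length(m)) stopf("one window per map required")
  out <- array(0, c(dim(m[[1]]), 3))
  for (k in seq_along(m)) out[, , k] <- clamp(m[[k]] / windows[k], 0, 1)
  out
}
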
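# Photon-counting acquisition: filtered-bremsstrahlung source spectrum,
# parallel-beam system matrix (pixel-driven, sparse, with exact transpose as
# backprojector), time-stamped energy-binned forward projection with Poisson
# counting noise, and log-normalization.

#' Acquisition configuration
#'
#' @param kvp tube voltage endpoint, keV.
#' @param views number of projection views.
#' @param exposure seconds per view (view period; the view rate is
#'   `1/exposure`).
#' @param thresholds detector energy thresholds, keV, strictly increasing;
#'   bin `b` counts photons in `[thresholds[b], thresholds[b+1])`, the last
#'   bin up to `kvp`.
#' @param photons_per_ray expected air counts per detector pixel per view,
#'   integrated over the whole spectrum (tube current is folded in here).
#' @param n_rotations full gantry rotations over the scan.
#' @param noise logical; apply Poisson counting noise.
#' @param seed RNG seed for the noise.
#' @return object of class `acquisition_config`.
#' @export
acquisition_config <- function(kvp = 80, views = 1000, exposure = 0.010,
                               thresholds = c(25, 34, 50, 60),
                               photons_per_ray = 3e4, n_rotations = 5,
                               noise = TRUE, seed = 1) {
  if (is.unsorted(thresholds, strictly = TRUE)) stopf("thresholds must be strictly increasing")
  if (max(thresholds) >= kvp) stopf("highest threshold must be below kVp")
  if (exposure <= 0) stopf("exposure must be positive")
  if (photons_per_ray <= 0) stopf("photons_per_ray must be positive")
  structure(list(kvp = kvp, views = views, exposure = exposure,
                 thresholds = thresholds, photons_per_ray = photons_per_ray,
                 n_rotations = n_rotations, noise = noise, seed = seed),
            class = "acquisition_config")
}

#' Source spectrum
#'
#' Filtered bremsstrahlung (Kramers shape with an E^-3 filtration term),
#' normalized so the integral over the grid equals `photons_per_ray`.
#'
#' @param kvp tube voltage, keV.
#' @param grid an [energy_grid()].
#' @param photons_per_ray normalization (photons per ray).
#' @param filtration unitless filtration strength.
#' @return photon fluence per keV at each grid energy.
#' @export
source_spectrum <- function(kvp = 80, grid = energy_grid(),
                            photons_per_ray = 3e4, filtration = 2) {
  e <- as.numeric(grid)
  s <- pmax(kvp - e, 0) * e * exp(-filtration * pe_shape(e))
  s * photons_per_ray / (sum(s) * attr(grid, "step"))
}

# ---- parallel-beam projector ------------------------------------------------

#' Parallel-beam projector geometry
#'
#' Pixel-driven projector on a square grid: each pixel splats its value onto
#' the two nearest detector bins with linear weights, scaled by the voxel
#' path length (cm). The backprojector is the exact matrix transpose, so the
#' pair is adjoint by construction.
#'
#' @param n image grid size; `voxel_mm` voxel size in mm.
#' @param ndet number of detector pixels (default covers the grid diagonal).
#' @return object of class `projector` (caches per-angle system matrices).
#' @export
projector <- function(n, voxel_mm, ndet = NULL) {
  if (is.null(ndet)) ndet <- 2L * ceiling(n * sqrt(2) / 2) + 1L
  g <- pixel_grid(n, voxel_mm)
  structure(list(n = n, voxel_mm = voxel_mm, ndet = as.integer(ndet),
                 det_spacing_mm = voxel_mm,
                 px = as.vector(g$x), py = as.vector(g$y),
                 cache = new.env(parent = emptyenv())),
            class = "projector")
}

#' Single-angle system matrix
#'
#' @param proj a [projector()].
#' @param angle projection angle in radians.
#' @return sparse `ndet x n^2` matrix; entries carry the voxel path length in
#'   cm so `A %*% x` is a line integral of `x` per cm.
#' @export
proj_matrix <- function(proj, angle) {
  key <- sprintf("%.9f", angle %% (2 * pi))
  hit <- proj$cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- proj$px * cos(angle) + proj$py * sin(angle)
  u <- s / proj$det_spacing_mm + (proj$ndet + 1) / 2
  i0 <- floor(u)
  w2 <- u - i0
  w1 <- 1 - w2
  path_cm <- proj$voxel_mm / 10
  jj <- seq_along(u)
  rows <- c(i0, i0 + 1)
  cols <- c(jj, jj)
  vals <- c(w1, w2) * path_cm
  keep <- rows >= 1 & rows <= proj$ndet & vals > 0
  A <- Matrix::sparseMatrix(i = rows[keep], j = cols[keep], x = vals[keep],
                            dims = c(proj$ndet, proj$n^2))
  proj$cache[[key]] <- A
  A
}

#' Stacked system matrix for a sequence of angles
#'
#' @param proj a [projector()]; `angles` vector of radians.
#' @return sparse `(length(angles) * ndet) x n^2` matrix, view-major rows.
#' @export
system_matrix <- function(proj, angles) {
  key <- sprintf("sys_%d_%s", length(angles),
                 format(sum(angles * seq_along(angles)), digits = 17))
  hit <- proj$cache[[key]]
  if (!is.null(hit)) return(hit)
  blocks <- lapply(angles, function(a) proj_matrix(proj, a))
  tri <- lapply(seq_along(blocks), function(k) {
    T <- as(blocks[[k]], "TsparseMatrix")
    list(i = T@i + 1L + (k - 1L) * proj$ndet, j = T@j + 1L, x = T@x)
  })
  A <- Matrix::sparseMatrix(i = unlist(lapply(tri, `[[`, "i")),
                            j = unlist(lapply(tri, `[[`, "j")),
                            x = unlist(lapply(tri, `[[`, "x")),
                            dims = c(length(angles) * proj$ndet, proj$n^2))
  proj$cache[[key]] <- A
  A
}

#' Project material concentration maps at one angle
#'
#' @param proj a [projector()].
#' @param maps named list of concentration matrices.
#' @param angle radians.
#' @return `ndet x length(maps)` matrix of concentration line integrals
#'   (concentration x cm).
#' @export
project_maps <- function(proj, maps, angle) {
  A <- proj_matrix(proj, angle)
  out <- vapply(maps, function(m) as.vector(A %*% as.vector(m)),
                numeric(proj$ndet))
  colnames(out) <- names(maps)
  out
}

#' Line integrals of attenuation per energy at one angle
#'
#' @param proj a [projector()]; `maps` concentration maps; `materials`
#'   matching list of [material()]s; `angle` radians; `grid` energies.
#' @return `ndet x length(grid)` matrix of attenuation line integrals
#'   (unitless).
#' @export
project_attenuation <- function(proj, maps, materials, angle, grid = energy_grid()) {
  P <- project_maps(proj, maps, angle)
  mu <- vapply(materials, function(m) mass_attenuation(m, as.numeric(grid), grid),
               numeric(length(grid)))
  P %*% t(mu)
}

# ---- forward model ----------------------------------------------------------

# energy -> bin index (NA below lowest threshold); last bin extends to kvp
bin_index <- function(energies, thresholds, kvp) {
  idx <- findInterval(energies, c(thresholds, kvp + 1e-9))
  idx[idx == 0 | energies > kvp] <- NA
  idx[idx > length(thresholds)] <- NA
  idx
}

#' Simulate a photon-counting acquisition
#'
#' Renders the phantom at each view's cardiac phase (from the view timestamp
#' and the phantom heart rate), forms expected counts per energy bin by
#' spectral integration of the attenuated source, and applies Poisson noise.
#'
#' @param phantom a phantom object (see [make_dynamic_phantom()],
#'   [make_detectability_phantom()], [static_phantom()]).
#' @param config an [acquisition_config()].
#' @param proj optional [projector()]; built from the phantom grid if absent.
#' @return object of class `binned_sinogram` in counts mode: `$data` is a
#'   `ndet x views x nbins` array; `$air` the expected air counts per bin;
#'   plus angles, timestamps, thresholds and geometry metadata.
#' @export
acquire <- function(phantom, config = acquisition_config(), proj = NULL) {
  grid <- energy_grid(to = config$kvp)
  if (is.null(proj)) proj <- projector(phantom$n, phantom$voxel_mm)
  nv <- config$views
  angles <- 2 * pi * config$n_rotations * (seq_len(nv) - 1) / nv
  timestamps <- (seq_len(nv) - 1) * config$exposure
  hr <- phantom$heart_rate
  dynamic <- inherits(phantom, "dynamic_phantom") && !is.na(hr)
  phases <- if (dynamic) (timestamps * hr / 60) %% 1 else rep(0, nv)

  view_rate <- 1 / config$exposure
  sampling_ok <- !dynamic || view_rate > 2 * hr / 60

  mat_names <- names(phantom_state(phantom, 0))
  nm <- length(mat_names)
  P <- matrix(0, nv * proj$ndet, nm) # concentration line integrals, view-major
  if (dynamic) {
    for (v in seq_len(nv)) {
      st <- phantom_state(phantom, phases[v])
      P[((v - 1) * proj$ndet + 1):(v * proj$ndet), ] <-
        project_maps(proj, st, angles[v])
    }
  } else {
    st <- phantom_state(phantom, 0)
    for (v in seq_len(nv)) {
      P[((v - 1) * proj$ndet + 1):(v * proj$ndet), ] <-
        project_maps(proj, st, angles[v])
    }
  }

  e <- as.numeric(grid)
  de <- attr(grid, "step")
  spec <- source_spectrum(config$kvp, grid, config$photons_per_ray)
  mu <- vapply(phantom$materials[mat_names],
               function(m) mass_attenuation(m, e, grid), numeric(length(e)))
  bins <- bin_index(e, config$thresholds, config$kvp)
  nb <- length(config$thresholds)
  lambda <- matrix(0, nv * proj$ndet, nb)
  air <- numeric(nb)
  for (k in seq_along(e)) {
    if (is.na(bins[k])) next
    w <- spec[k] * de
    lambda[, bins[k]] <- lambda[, bins[k]] + w * exp(-(P %*% mu[k, ]))
    air[bins[k]] <- air[bins[k]] + w
  }
  counts <- if (config$noise) {
    with_seed(config$seed,
              matrix(stats::rpois(length(lambda), lambda), nrow(lambda), nb))
  } else lambda
  structure(list(
    data = array(counts, c(proj$ndet, nv, nb))
    , mode = "counts", angles = angles, timestamps = timestamps,
    thresholds = config$thresholds, kvp = config$kvp, air = air,
    exposure = config$exposure, view_rate = view_rate,
    sampling_ok = sampling_ok, phases_truth = phases,
    heart_rate_truth = if (dynamic) hr else NA_real_,
    n = phantom$n, voxel_mm = phantom$voxel_mm, ndet = proj$ndet,
    n_rotations = config$n_rotations, config = config
  ), class = "binned_sinogram")
}

#' Log-normalize a counts sinogram
#'
#' `-log(counts / air)` per bin; zero counts are clamped to 0.5 before the
#' log (the number of clamped pixels is attached as attribute
#' `n_clamped` and warned about).
#'
#' @param sino counts-mode [acquire()] output.
#' @param air expected air counts per bin; defaults to the stored air scan.
#' @return the sinogram in log mode.
#' @export
log_normalize <- function(sino, air = sino$air) {
  if (sino$mode != "counts") stopf("sinogram is already log-normalized")
  if (is.null(air)) stopf("air scan missing")
  if (any(air <= 0)) stopf("air counts must be positive")
  d <- sino$data
  n_clamped <- sum(d < 0.5)
  if (n_clamped > 0) {
    warnf("%d zero/low-count pixels clamped to 0.5 before log", n_clamped)
    d[d < 0.5] <- 0.5
  }
  for (b in seq_along(air)) d[, , b] <- -log(d[, , b] / air[b])
  out <- sino
  out$data <- d
  out$mode <- "log"
  out$n_clamped <- n_clamped
  out
}

# Extract the (ndet x views) matrix for one bin, or the summed-count channel
# ("lowest threshold" cumulative image) when bin = "sum".
sino_channel <- function(sino, bin = 1) {
  if (identical(bin, "sum")) {
    if (sino$mode != "counts") stopf("summed channel requires counts mode")
    list(data = apply(sino$data, c(1, 2), sum), air = sum(sino$air))
  } else {
    list(data = sino$data[, , bin], air = sino$air[bin])
  }
}
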
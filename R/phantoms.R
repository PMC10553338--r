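# Digital phantoms: a dynamic thorax slice with a beating, iodine-enhanced
# left ventricle (optionally carrying a calcified plaque), and the static
# calcium-detectability phantom with cylinders of graded diameter and
# concentration in an iodine background.
#
# Geometry is 2D (one slice) with a configurable slab thickness so that mask
# "volumes" are in mL; all downstream algorithms are dimension-agnostic.
# Rendering uses an area-fraction (linear edge) model so that ROI means and
# mask areas are analytically predictable.

# Pixel-center coordinate grids in mm, centered on the FOV.
pixel_grid <- function(n, voxel_mm) {
  u <- (seq_len(n) - (n + 1) / 2) * voxel_mm
  list(x = matrix(u, n, n), y = matrix(u, n, n, byrow = TRUE))
}

# Area-fraction coverage of a disk over square pixels (linear edge model).
disk_coverage <- function(gx, gy, cx, cy, radius, voxel_mm) {
  if (radius <= 0) return(matrix(0, nrow(gx), ncol(gx)))
  d <- sqrt((gx - cx)^2 + (gy - cy)^2)
  clamp((radius - d) / voxel_mm + 0.5, 0, 1)
}

ellipse_coverage <- function(gx, gy, cx, cy, a, b, theta = 0, voxel_mm) {
  xr <- (gx - cx) * cos(theta) + (gy - cy) * sin(theta)
  yr <- -(gx - cx) * sin(theta) + (gy - cy) * cos(theta)
  # signed pseudo-distance: scaled radius minus 1, mapped back to mm
  d <- (sqrt((xr / a)^2 + (yr / b)^2) - 1) * min(a, b)
  clamp(0.5 - d / voxel_mm, 0, 1)
}

#' Dynamic cardiac phantom
#'
#' A water-equivalent thorax slice containing a beating left ventricle filled
#' with iodinated blood. The LV volume follows a smooth raised-cosine cycle
#' between the diastolic (DLVV) and systolic (SLVV) volumes at the configured
#' heart rate; phase 0 is end-diastole, phase 0.5 end-systole. An optional
#' calcified plaque sits at the myocardial border.
#'
#' Stored ground truth (`$truth`) is measured from the rendered masks, so the
#' diastolic mask volume equals `truth$dlvv_ml` exactly.
#'
#' @param n grid size (pixels per side).
#' @param voxel_mm in-plane voxel size, mm.
#' @param slab_mm slab thickness used to convert mask areas to volumes, mm.
#' @param heart_rate beats per minute; must lie in the murine range
#'   300-600 bpm unless `dlvv_ml == slvv_ml` (motionless phantom).
#' @param dlvv_ml,slvv_ml requested diastolic and systolic LV volumes in mL.
#' @param iodine_blood_mgml blood-pool iodine concentration, mg/mL.
#' @param body_axes_mm semi-axes of the elliptical body, mm.
#' @param lv_center_mm LV center (x, y), mm.
#' @param plaque `NULL`, or `list(ca_mgml=, diameter_mm=)` for a calcified
#'   plaque at the LV border.
#' @param seed stored for provenance; the phantom itself is deterministic.
#' @return object of class `dynamic_phantom`.
#' @export
make_dynamic_phantom <- function(n = 96, voxel_mm = 0.25, slab_mm = 1,
                                 heart_rate = 450,
                                 dlvv_ml = 0.045, slvv_ml = 0.022,
                                 iodine_blood_mgml = 20,
                                 body_axes_mm = c(9, 8),
                                 lv_center_mm = c(-1.2, 0.8),
                                 plaque = NULL, seed = NULL) {
  if (slvv_ml > dlvv_ml) stopf("SLVV (%g) exceeds DLVV (%g)", slvv_ml, dlvv_ml)
  if (dlvv_ml > slvv_ml && (heart_rate < 300 || heart_rate > 600))
    stopf("heart_rate %g bpm outside the expected murine range [300, 600]", heart_rate)
  g <- pixel_grid(n, voxel_mm)
  mats <- material_library()
  body <- ellipse_coverage(g$x, g$y, 0, 0.3, body_axes_mm[1], body_axes_mm[2],
                           voxel_mm = voxel_mm)
  # mask areas (mm^2) realizing the requested volumes over the slab
  area_d <- dlvv_ml * 1000 / slab_mm
  area_s <- slvv_ml * 1000 / slab_mm
  ca_map <- matrix(0, n, n)
  if (!is.null(plaque)) {
    rd <- sqrt(area_d / pi)
    pc <- lv_center_mm + c(rd * 0.9, rd * 0.45)
    ca_map <- plaque$ca_mgml *
      disk_coverage(g$x, g$y, pc[1], pc[2], plaque$diameter_mm / 2, voxel_mm)
  }
  ph <- structure(list(
    n = n, voxel_mm = voxel_mm, slab_mm = slab_mm, grid = g,
    materials = mats[c("water", "iodine", "calcium")],
    heart_rate = heart_rate, area_d = area_d, area_s = area_s,
    iodine_blood_mgml = iodine_blood_mgml, lv_center_mm = lv_center_mm,
    body = body, ca_map = ca_map, seed = seed
  ), class = "dynamic_phantom")
  vd <- lv_volume(lv_mask(ph, 0),   c(voxel_mm, voxel_mm, slab_mm))
  vs <- lv_volume(lv_mask(ph, 0.5), c(voxel_mm, voxel_mm, slab_mm))
  ph$truth <- list(dlvv_ml = vd, slvv_ml = vs, sv_ml = vd - vs,
                   ef_pct = 100 * (vd - vs) / vd, heart_rate = heart_rate)
  ph
}

# Raised-cosine LV area (mm^2) at normalized cardiac phase in [0, 1).
lv_area <- function(phantom, phase) {
  w <- (1 + cos(2 * pi * phase)) / 2
  phantom$area_s + (phantom$area_d - phantom$area_s) * w
}

lv_radius <- function(phantom, phase) sqrt(lv_area(phantom, phase) / pi)

#' Binary left-ventricle mask at a cardiac phase
#'
#' @param phantom a [make_dynamic_phantom()] object.
#' @param phase normalized cardiac phase in `[0, 1)`.
#' @return logical matrix (pixel coverage >= 0.5).
#' @export
lv_mask <- function(phantom, phase) {
  r <- lv_radius(phantom, phase)
  cov <- disk_coverage(phantom$grid$x, phantom$grid$y,
                       phantom$lv_center_mm[1], phantom$lv_center_mm[2],
                       r, phantom$voxel_mm)
  cov >= 0.5
}

# LV disk coverage at an explicit radius (helper for effective-area labels)
pcct_disk_cov <- function(phantom, radius_mm) {
  disk_coverage(phantom$grid$x, phantom$grid$y,
                phantom$lv_center_mm[1], phantom$lv_center_mm[2],
                radius_mm, phantom$voxel_mm)
}

#' Render per-material concentration maps at a cardiac phase
#'
#' @param phantom a phantom object.
#' @param phase normalized cardiac phase (ignored for static phantoms).
#' @return list of concentration matrices named by material (`water` as
#'   water fraction, `iodine`/`calcium` in mg/mL).
#' @export
phantom_state <- function(phantom, phase = 0) UseMethod("phantom_state")

#' @export
phantom_state.dynamic_phantom <- function(phantom, phase = 0) {
  r <- lv_radius(phantom, phase)
  lv <- disk_coverage(phantom$grid$x, phantom$grid$y,
                      phantom$lv_center_mm[1], phantom$lv_center_mm[2],
                      r, phantom$voxel_mm)
  list(water = phantom$body,
       iodine = phantom$iodine_blood_mgml * lv * phantom$body,
       calcium = phantom$ca_map)
}

#' Static uniform phantom from explicit concentration maps
#'
#' Convenience constructor for calibration and test objects (e.g. a uniform
#' water disk).
#'
#' @param maps named list of concentration matrices (names from
#'   [material_library()]).
#' @param voxel_mm voxel size, mm.
#' @param slab_mm slab thickness, mm.
#' @return object of class `static_phantom`.
#' @export
static_phantom <- function(maps, voxel_mm = 0.25, slab_mm = 1) {
  n <- nrow(maps[[1]])
  structure(list(n = n, voxel_mm = voxel_mm, slab_mm = slab_mm, maps = maps,
                 materials = material_library()[names(maps)],
                 heart_rate = NA_real_),
            class = "static_phantom")
}

#' @export
phantom_state.static_phantom <- function(phantom, phase = 0) phantom$maps

#' Calcium detectability phantom
#'
#' Cylinders of graded diameter filled with calcium solutions at several
#' concentrations, plus one iodine row, embedded in an iodinated background
#' disk (the "calcium against iodine" detection task). Cylinder interiors
#' displace the background iodine.
#'
#' @param diameters_mm cylinder diameters (columns of the layout), mm.
#' @param ca_mgml calcium concentrations (one row each), mg/mL.
#' @param iodine_mgml iodine concentration of the iodine row and of the
#'   background, mg/mL.
#' @param n grid size; `voxel_mm` voxel size in mm.
#' @param background_radius_mm radius of the iodinated background disk.
#' @return object of class `detectability_phantom` with `$cylinders`
#'   (data.frame of diameter, material, concentration, center) and rendered
#'   concentration maps.
#' @export
make_detectability_phantom <- function(diameters_mm = c(0.5, 1, 1.5, 2, 2.5),
                                       ca_mgml = c(10, 20, 40),
                                       iodine_mgml = 10,
                                       n = 160, voxel_mm = 0.125,
                                       background_radius_mm = 9.5) {
  g <- pixel_grid(n, voxel_mm)
  rows <- c(paste0("Ca", ca_mgml), paste0("I", iodine_mgml))
  n_rows <- length(rows)
  n_col <- length(diameters_mm)
  xs <- (seq_len(n_col) - (n_col + 1) / 2) * 2.5
  ys <- (seq_len(n_rows) - (n_rows + 1) / 2) * 2.7
  spec <- expand.grid(col = seq_len(n_col), row = seq_len(n_rows))
  cyl <- data.frame(
    diameter_mm = diameters_mm[spec$col],
    material = c(rep("calcium", length(ca_mgml)), "iodine")[spec$row],
    concentration = c(ca_mgml, iodine_mgml)[spec$row],
    cx = xs[spec$col], cy = ys[spec$row]
  )
  # layout validation: pairwise non-overlap and containment
  for (i in seq_len(nrow(cyl))) {
    ri <- cyl$diameter_mm[i] / 2
    if (ri == 0) warnf("cylinder %d has zero diameter: empty insert", i)
    if (sqrt(cyl$cx[i]^2 + cyl$cy[i]^2) + ri > background_radius_mm)
      stopf("cylinder %d extends outside the background disk", i)
    if (i > 1) for (j in seq_len(i - 1)) {
      dij <- sqrt((cyl$cx[i] - cyl$cx[j])^2 + (cyl$cy[i] - cyl$cy[j])^2)
      if (dij < ri + cyl$diameter_mm[j] / 2)
        stopf("cylinders %d and %d overlap", j, i)
    }
  }
  bg <- disk_coverage(g$x, g$y, 0, 0, background_radius_mm, voxel_mm)
  cyl_cov <- lapply(seq_len(nrow(cyl)), function(i)
    disk_coverage(g$x, g$y, cyl$cx[i], cyl$cy[i], cyl$diameter_mm[i] / 2, voxel_mm))
  inside_any <- Reduce(`+`, cyl_cov, matrix(0, n, n))
  iodine_map <- iodine_mgml * bg * pmax(1 - inside_any, 0)
  calcium_map <- matrix(0, n, n)
  for (i in seq_len(nrow(cyl))) {
    m <- cyl_cov[[i]] * cyl$concentration[i]
    if (cyl$material[i] == "calcium") calcium_map <- calcium_map + m
    else iodine_map <- iodine_map + m
  }
  structure(list(n = n, voxel_mm = voxel_mm, slab_mm = 1, grid = g,
                 cylinders = cyl, background_radius_mm = background_radius_mm,
                 iodine_mgml = iodine_mgml,
                 materials = material_library()[c("water", "iodine", "calcium")],
                 maps = list(water = bg, iodine = iodine_map, calcium = calcium_map),
                 cylinder_coverage = cyl_cov,
                 heart_rate = NA_real_),
            class = "detectability_phantom")
}

#' @export
phantom_state.detectability_phantom <- function(phantom, phase = 0) phantom$maps

#' Volume of a binary mask
#'
#' @param mask logical/0-1 matrix or array.
#' @param voxel_size_mm voxel edge lengths in mm; a scalar is treated as
#'   isotropic over 3 dimensions, a length-3 vector as (dx, dy, dz).
#' @return volume in mL.
#' @export
lv_volume <- function(mask, voxel_size_mm) {
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  sum(mask != 0) * prod(voxel_size_mm) / 1000
}
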
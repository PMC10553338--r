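# Spectral attenuation physics: two-basis photoelectric/Compton model with an
# optional K-edge step. Coefficients are calibration parameters of the
# simulator (magnitudes chosen near tabulated values for water, iodine and
# calcium) rather than lookups; downstream stages only require self-consistent,
# K-edge-bearing physics that is linear in concentration.

#' Construct an energy grid
#'
#' Diagnostic X-ray energies in keV used for spectral integration. The grid
#' must cover all detector thresholds.
#'
#' @param from,to,by grid limits and spacing in keV. Defaults cover 10-80 keV.
#' @return object of class `energy_grid`: numeric vector of energies with
#'   attribute `step` (keV).
#' @export
energy_grid <- function(from = 10, to = 80, by = 1) {
  e <- seq(from, to, by = by)
  if (min(e) <= 0) stopf("energies must be positive")
  if (is.unsorted(e, strictly = TRUE)) stopf("energies must be strictly increasing")
  if (max(e) < 60) stopf("energy grid must reach the highest detector threshold (60 keV)")
  structure(e, step = by, class = "energy_grid")
}

# Klein-Nishina total cross-section shape, normalized to 1 at 30 keV.
# Governs the slow energy decline of the Compton basis.
klein_nishina <- function(energy_kev) {
  kn <- function(k) {
    a <- 1 + 2 * k
    (1 + k) / k^2 * (2 * (1 + k) / a - log(a) / k) + log(a) / (2 * k) - (1 + 3 * k) / a^2
  }
  kn(energy_kev / 511) / kn(30 / 511)
}

# Photoelectric basis shape ~ E^-3, normalized to 1 at 30 keV.
pe_shape <- function(energy_kev) (30 / energy_kev)^3

#' Define a basis material
#'
#' A material is a non-negative combination of a photoelectric (E^-3) and a
#' Compton (Klein-Nishina) basis, optionally with a multiplicative K-edge step.
#' Coefficients are per unit concentration: per mg/mL for solutes such as
#' iodine and calcium, per unit water-fraction for water-like media.
#'
#' @param name identifier.
#' @param pe_coeff,cs_coeff non-negative basis weights (1/cm per unit
#'   concentration at 30 keV).
#' @param kedge_energy K-edge position in keV, or `NA` for edge-free materials.
#' @param kedge_jump attenuation ratio across the edge (> 1); the step is
#'   applied multiplicatively to the total attenuation so the across-edge
#'   ratio equals `kedge_jump` exactly.
#' @param concentration_unit `"mg/mL"` or `"fraction"`.
#' @return object of class `material_model`.
#' @export
material <- function(name, pe_coeff, cs_coeff, kedge_energy = NA_real_,
                     kedge_jump = NA_real_, concentration_unit = "mg/mL") {
  if (pe_coeff < 0 || cs_coeff < 0) stopf("basis coefficients must be non-negative")
  if (!is.na(kedge_energy)) {
    if (is.na(kedge_jump) || kedge_jump <= 1) stopf("kedge_jump must exceed 1 when an edge is present")
    if (kedge_energy <= 10 || kedge_energy >= 80) stopf("kedge_energy must lie in (10, 80) keV")
  }
  structure(list(name = name, pe_coeff = pe_coeff, cs_coeff = cs_coeff,
                 kedge_energy = kedge_energy, kedge_jump = kedge_jump,
                 concentration_unit = concentration_unit),
            class = "material_model")
}

#' Built-in material library
#'
#' Water (per unit water fraction), liposomal-iodine solute and calcium
#' (per mg/mL, iodine carrying its 33.2 keV K-edge), and a null material.
#'
#' @return named list of [material()] objects.
#' @export
material_library <- function() {
  list(
    water   = material("water",   0.205,  0.170,  concentration_unit = "fraction"),
    iodine  = material("iodine",  0.0109, 0.0003, kedge_energy = 33.2, kedge_jump = 3.1),
    calcium = material("calcium", 0.0028, 0.0003),
    null    = material("null",    0,      0)
  )
}

#' Mass attenuation per unit concentration
#'
#' Evaluates the two-basis model at the requested energies:
#' `mu(E) = [pe * (30/E)^3 + cs * KN(E)] * step(E)`, where `step` is 1 below
#' the K-edge and `kedge_jump` at and above it.
#'
#' @param mat a [material()].
#' @param energy energies in keV; must lie within `grid`.
#' @param grid an [energy_grid()] defining the admissible range.
#' @return attenuation (1/cm per unit concentration), same length as `energy`.
#' @export
mass_attenuation <- function(mat, energy, grid = energy_grid()) {
  if (any(energy < min(grid)) || any(energy > max(grid)))
    stopf("energy outside grid range [%g, %g] keV", min(grid), max(grid))
  mu <- mat$pe_coeff * pe_shape(energy) + mat$cs_coeff * klein_nishina(energy)
  if (!is.na(mat$kedge_energy)) {
    mu <- mu * ifelse(energy >= mat$kedge_energy, mat$kedge_jump, 1)
  }
  mu
}

# Attenuation (1/cm) of a mixture given per-material concentrations; the
# linearity in concentration is the assumption the decomposition inverts.
mixture_attenuation <- function(materials, concentrations, energy, grid = energy_grid()) {
  stopifnot(length(materials) == length(concentrations))
  mu <- numeric(length(energy))
  for (i in seq_along(materials)) {
    mu <- mu + concentrations[i] * mass_attenuation(materials[[i]], energy, grid)
  }
  mu
}
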
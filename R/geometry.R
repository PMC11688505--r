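# Acquisition geometry and the mean-glandular-dose model.

# flux ratio between the reference and low-dose presets (1231 mGy / 20 mGy)
DOSE_RATIO_REFERENCE <- 1231 / 20

#' Acquisition geometry for a phase-stepping scan
#'
#' @param n_angles projection angles, uniformly spaced over `[0, pi)`.
#' @param n_steps grating steps per stepping curve; at least 4 so the
#'   single-harmonic sinusoid is sufficiently sampled.
#' @param visibility fringe visibility V of the stepping curve, in `[0, 1]`.
#' @param flux_per_step mean photon count per detector pixel per step in the
#'   reference (flat) scan.
#' @param phase_sensitivity dimensionless factor converting the transverse
#'   derivative of the projected refractive decrement into stepping-curve
#'   phase shift (stands in for the hardware-specific wavelength/distance/
#'   grating-period chain).
#' @param exposure_time seconds per step (bookkeeping only).
#' @param seed RNG seed for Poisson noise.
#' @return object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(n_angles = 100L, n_steps = 5L,
                                 visibility = 0.3, flux_per_step = 500,
                                 phase_sensitivity = 24,
                                 exposure_time = 1, seed = 1L) {
  stopifnot_scalar(n_angles, "n_angles", min = 1, integer = TRUE)
  stopifnot_scalar(n_steps, "n_steps", min = 4, integer = TRUE)
  stopifnot_scalar(visibility, "visibility", min = 0, max = 1)
  stopifnot_scalar(flux_per_step, "flux_per_step", min = .Machine$double.xmin)
  stopifnot_scalar(phase_sensitivity, "phase_sensitivity")
  structure(list(n_angles = as.integer(n_angles),
                 n_steps = as.integer(n_steps),
                 visibility = visibility,
                 flux_per_step = flux_per_step,
                 phase_sensitivity = phase_sensitivity,
                 exposure_time = exposure_time,
                 seed = as.integer(seed)),
            class = "acquisition_geometry")
}

#' Total photon budget of a geometry
#'
#' The dose proxy `n_angles * n_steps * flux_per_step`. Trading projection
#' count against per-step exposure (as the paper's protocol does when doubling
#' the projections for Noise2Inverse at half the exposure) conserves it.
#'
#' @param geometry an [acquisition_geometry()].
#' @return a single number.
#' @export
total_photon_budget <- function(geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  geometry$n_angles * geometry$n_steps * geometry$flux_per_step
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf("acquisition_geometry: %d angles x %d steps, V=%.3g, flux=%g/px/step\n",
              x$n_angles, x$n_steps, x$visibility, x$flux_per_step))
  cat(sprintf("  phase sensitivity C=%g, dose proxy=%g photons\n",
              x$phase_sensitivity, total_photon_budget(x)))
  invisible(x)
}

#' Monoenergetic dose-coefficient table
#'
#' Holds per-energy-bin normalized glandular dose coefficients DgN(E), the
#' measured air kerma K(E) of the source spectrum, and the roentgen-to-mGy
#' conversion factor kappa. Air kerma is a measured quantity and enters as
#' data; the table performs no spectral simulation.
#'
#' @param energies energy-bin centers (keV).
#' @param dgn DgN(E) coefficients (mGy/R) per bin.
#' @param kerma measured air kerma per bin (R).
#' @param kappa conversion factor (R/mGy), default 0.114.
#' @return object of class `dgn_table`.
#' @export
dgn_table <- function(energies, dgn, kerma, kappa = 0.114) {
  if (length(energies) == 0L) stop("empty table")
  if (length(dgn) != length(energies) || length(kerma) != length(energies))
    stop("energies, dgn and kerma must have equal lengths")
  if (any(!is.finite(c(energies, dgn, kerma, kappa))) ||
      any(c(energies, dgn, kerma, kappa) < 0))
    stop("all table entries must be finite and non-negative")
  structure(list(energies = energies, dgn = dgn, kerma = kerma, kappa = kappa),
            class = "dgn_table")
}

#' Mean glandular dose from a dose-coefficient table
#'
#' Computes `MGD = sum_E DgN(E) * K(E) * kappa` over the energy bins of the
#' source spectrum.
#'
#' @param table a [dgn_table()].
#' @return dose in mGy.
#' @export
mean_glandular_dose <- function(table) {
  if (!inherits(table, "dgn_table")) stop("table must be a dgn_table")
  sum(table$dgn * table$kerma) * table$kappa
}
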
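# Phase-stepping acquisition simulator.

#' Simulate a phase-stepping scan of a phantom
#'
#' For every projection angle and grating step the expected detector count is
#' `I(s) = F * T * (1 + V * cos(2*pi*s/n_steps + phi))`, `s = 0..n_steps-1`,
#' with `T = exp(-R[mu])` the transmission through the line integral of the
#' attenuation map and `phi = C * d/dx R[delta]` the transverse central
#' difference of the projected refractive decrement scaled by the phase
#' sensitivity. The reference (flat) scan has `T = 1`, `phi = 0`. With noise
#' enabled, counts are Poisson-sampled using the geometry's seed; without
#' noise they are the real-valued expectations. Visibility reduction
#' (dark-field) is not simulated.
#'
#' Recipes whose simulated phase reaches `|phi| >= pi` are rejected: the
#' retrieval chain does not unwrap phase.
#'
#' @param phantom a [make_phantom()] volume; its slices become detector rows.
#' @param geometry an [acquisition_geometry()].
#' @param noise logical; Poisson-sample the counts.
#' @return object of class `stepping_scan` with `sample`
#'   `[angle, step, row, col]`, `reference` `[step, row, col]`, `geometry`
#'   and `angles`.
#' @export
simulate_stepping <- function(phantom, geometry, noise = TRUE) {
  stopifnot(inherits(phantom, "phantom_volume"),
            inherits(geometry, "acquisition_geometry"))
  ny <- phantom$shape[1]; nx <- phantom$shape[2]; nz <- phantom$shape[3]
  expectation <- .stepping_expectation(phantom, geometry)
  .finalize_scan(expectation$sample, expectation$reference, geometry, noise,
                 expectation$angles)
}

# Expected (noise-free) counts for a phantom scan; shared with tests that
# need the forward model's T and phi directly.
.stepping_expectation <- function(phantom, geometry) {
  nx <- phantom$shape[2]; nz <- phantom$shape[3]
  na <- geometry$n_angles; ns <- geometry$n_steps
  V <- geometry$visibility; F0 <- geometry$flux_per_step
  C <- geometry$phase_sensitivity
  angles <- projection_angles(na)
  s <- 0:(ns - 1)
  carrier <- cos(2 * pi * s / ns)                    # reference stepping curve

  trans <- array(0, c(na, nz, nx))
  dphase <- array(0, c(na, nz, nx))
  for (z in seq_len(nz)) {
    rmu <- forward_project(phantom$mu[, , z], angles)
    rdelta <- forward_project(phantom$delta[, , z], angles)
    trans[, z, ] <- exp(-rmu)
    dphase[, z, ] <- t(apply(rdelta, 1L, central_diff)) * C
  }
  if (max(abs(dphase)) >= pi)
    stop(sprintf(paste0("simulated differential phase reaches |phi| = %.3f >= pi; ",
                        "the pipeline does not unwrap phase - reduce delta, ",
                        "phase_sensitivity, or feature gradients"),
                 max(abs(dphase))))

  sample <- array(0, c(na, ns, nz, nx))
  for (si in seq_len(ns)) {
    ph <- 2 * pi * s[si] / ns
    sample[, si, , ] <- F0 * trans * (1 + V * cos(ph + dphase))
  }
  reference <- array(0, c(ns, nz, nx))
  for (si in seq_len(ns)) reference[si, , ] <- F0 * (1 + V * carrier[si])
  list(sample = sample, reference = reference, angles = angles,
       transmission = trans, dphase = dphase)
}

.finalize_scan <- function(sample, reference, geometry, noise, angles) {
  if (min(sample) < 0 || min(reference) < 0)
    stop("negative expected counts; check visibility <= 1")
  if (noise) {
    with_seed(geometry$seed, {
      sample[] <- stats::rpois(length(sample), sample)
      reference[] <- stats::rpois(length(reference), reference)
    })
  }
  structure(list(sample = sample, reference = reference,
                 geometry = geometry, angles = angles, noisy = noise),
            class = "stepping_scan")
}

#' Simulate a flat (no-sample) stepping scan
#'
#' The empty-beam acquisition used for noise-power-spectrum analysis: every
#' pixel sees the bare reference stepping curve; the sample scan differs from
#' the reference only by its Poisson noise realization.
#'
#' @param geometry an [acquisition_geometry()].
#' @param shape detector `c(n_rows, n_cols)` (default one row).
#' @param noise logical; Poisson-sample the counts.
#' @return a `stepping_scan`.
#' @export
simulate_flat_scan <- function(geometry, shape = c(1L, 64L), noise = TRUE) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  if (length(shape) == 1L) shape <- c(1L, shape)
  nz <- as.integer(shape[1]); nx <- as.integer(shape[2])
  na <- geometry$n_angles; ns <- geometry$n_steps
  s <- 0:(ns - 1)
  curve <- geometry$flux_per_step *
    (1 + geometry$visibility * cos(2 * pi * s / ns))
  sample <- array(rep(curve, each = na), c(na, ns, nz, nx))
  reference <- array(curve, c(ns, nz, nx))
  .finalize_scan(sample, reference, geometry, noise, projection_angles(na))
}

#' @export
print.stepping_scan <- function(x, ...) {
  d <- dim(x$sample)
  cat(sprintf("stepping_scan: %d angles x %d steps x %d row(s) x %d cols (%s)\n",
              d[1], d[2], d[3], d[4],
              if (isTRUE(x$noisy)) "Poisson noise" else "noise-free"))
  invisible(x)
}
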
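# Synthetic tissue phantoms with co-registered attenuation and
# refractive-decrement maps.

#' Phantom recipe
#'
#' Describes the composition of the synthetic soft-tissue phantom: a circular
#' water bath, an optional Falcon-tube-like cylinder wall, an optional PMMA
#' rod, a configurable number of elliptical tissue blobs drawn from the listed
#' tissue classes, and thin fiber-like structures that probe detail recovery.
#'
#' All contrast values are per-pixel: `mu` is the linear attenuation
#' coefficient in inverse pixels, `delta` a scaled refractive index decrement.
#' The defaults mimic marbled soft tissue (muscle/adipose/fibrous) immersed in
#' an ethanol-filled tube inside a water bath.
#'
#' @param n_regions number of elliptical tissue blobs.
#' @param n_fibers number of thin fiber structures.
#' @param fiber_width fiber thickness in pixels (<= 3 to stay a "fine detail").
#' @param include_tube draw the cylindrical tube wall.
#' @param include_rod draw a small PMMA-like rod.
#' @param bath_radius_frac water-bath radius as a fraction of the half-width.
#' @param tube_radius_frac tube radius as a fraction of the half-width.
#' @param water,base,tube,rod `c(mu, delta)` pairs for the fixed regions;
#'   `base` fills the tube interior (ethanol-like).
#' @param tissue_classes named list of `c(mu, delta)` pairs the blobs and
#'   fibers are drawn from.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_regions = 6L,
                         n_fibers = 2L,
                         fiber_width = 2L,
                         include_tube = TRUE,
                         include_rod = TRUE,
                         bath_radius_frac = 0.92,
                         tube_radius_frac = 0.66,
                         water = c(mu = 0.020, delta = 0.0040),
                         base = c(mu = 0.018, delta = 0.0042),
                         tube = c(mu = 0.028, delta = 0.0055),
                         rod = c(mu = 0.028, delta = 0.0055),
                         tissue_classes = list(
                           muscle  = c(mu = 0.024, delta = 0.0048),
                           adipose = c(mu = 0.016, delta = 0.0036),
                           fibrous = c(mu = 0.030, delta = 0.0060))) {
  stopifnot_scalar(n_regions, "n_regions", min = 0, integer = TRUE)
  stopifnot_scalar(n_fibers, "n_fibers", min = 0, integer = TRUE)
  stopifnot_scalar(fiber_width, "fiber_width", min = 1, max = 3, integer = TRUE)
  vals <- c(list(water = water, base = base, tube = tube, rod = rod),
            tissue_classes)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 2L || any(!is.finite(v)) || any(v < 0))
      stop(sprintf("contrast pair '%s' must be two non-negative finite values (mu, delta)", nm))
  }
  structure(list(n_regions = as.integer(n_regions),
                 n_fibers = as.integer(n_fibers),
                 fiber_width = as.integer(fiber_width),
                 include_tube = isTRUE(include_tube),
                 include_rod = isTRUE(include_rod),
                 bath_radius_frac = bath_radius_frac,
                 tube_radius_frac = tube_radius_frac,
                 water = water, base = base, tube = tube, rod = rod,
                 tissue_classes = tissue_classes),
            class = "phantom_spec")
}

#' Generate a synthetic phantom volume
#'
#' Builds co-registered attenuation (`mu`) and refractive-decrement (`delta`)
#' maps following a recipe. Outside the water bath both maps are exactly zero;
#' inside, regions carry the per-class contrast pairs. The `labels` map uses
#' 0 = background, 1 = water bath, 2 = tube wall, 3 = tube interior base,
#' 4 = rod, 10+i for the i-th tissue blob and 100+i for the i-th fiber.
#'
#' @param shape `c(n)` or `c(ny, nx)` or `c(ny, nx, n_slices)`; slices share
#'   the macro structure with per-slice blob jitter.
#' @param spec a [phantom_spec()].
#' @param seed integer seed; equal seeds give bit-identical phantoms.
#' @param pixel_size physical pixel pitch (bookkeeping only).
#' @return object of class `phantom_volume` with fields `mu`, `delta`,
#'   `labels` (3D arrays `[ny, nx, n_slices]`) and `pixel_size`.
#' @export
make_phantom <- function(shape, spec = phantom_spec(), seed = 1L,
                         pixel_size = 1) {
  if (length(shape) == 1L) shape <- c(shape, shape)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  if (length(shape) != 3L || any(shape[1:2] < 32L))
    stop("shape must give at least 32x32 pixels per slice")
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  ny <- as.integer(shape[1]); nx <- as.integer(shape[2])
  nz <- as.integer(shape[3])

  mu <- array(0, c(ny, nx, nz))
  delta <- array(0, c(ny, nx, nz))
  labels <- array(0L, c(ny, nx, nz))

  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  half <- min(ny, nx) / 2
  yy <- matrix(seq_len(ny) - cy, ny, nx)
  xx <- matrix(seq_len(nx) - cx, ny, nx, byrow = TRUE)
  rr <- sqrt(yy^2 + xx^2)
  r_bath <- spec$bath_radius_frac * half
  r_tube <- spec$tube_radius_frac * half
  bath <- rr <= r_bath

  with_seed(seed, {
    for (z in seq_len(nz)) {
      m <- matrix(0, ny, nx); d <- matrix(0, ny, nx); lb <- matrix(0L, ny, nx)
      m[bath] <- spec$water["mu"]; d[bath] <- spec$water["delta"]
      lb[bath] <- 1L
      if (spec$include_tube) {
        wall <- rr <= r_tube & rr > r_tube - 1.5
        inner <- rr <= r_tube - 1.5
        m[wall] <- spec$tube["mu"]; d[wall] <- spec$tube["delta"]; lb[wall] <- 2L
        m[inner] <- spec$base["mu"]; d[inner] <- spec$base["delta"]
        lb[inner] <- 3L
        r_in <- r_tube - 1.5
      } else r_in <- r_bath
      if (spec$n_regions > 0L) {
        cls <- spec$tissue_classes
        for (i in seq_len(spec$n_regions)) {
          k <- cls[[(i - 1L) %% length(cls) + 1L]]
          # blob centre well inside the tube interior, radii 3..r_in/3
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- stats::runif(1, 0, 0.6 * r_in)
          bcy <- rad * sin(ang); bcx <- rad * cos(ang)
          a <- stats::runif(1, 3, max(4, r_in / 3))
          b <- stats::runif(1, 3, max(4, r_in / 3))
          th <- stats::runif(1, 0, pi)
          u <- (yy - bcy) * cos(th) + (xx - bcx) * sin(th)
          v <- -(yy - bcy) * sin(th) + (xx - bcx) * cos(th)
          blob <- (u / a)^2 + (v / b)^2 <= 1 & rr <= r_in
          m[blob] <- k["mu"]; d[blob] <- k["delta"]; lb[blob] <- 10L + i
        }
      }
      if (spec$include_rod) {
        rod <- sqrt((yy - 0.45 * r_in)^2 + (xx - 0.45 * r_in)^2) <=
          max(2, 0.12 * r_in) & rr <= r_in
        m[rod] <- spec$rod["mu"]; d[rod] <- spec$rod["delta"]; lb[rod] <- 4L
      }
      if (spec$n_fibers > 0L) {
        k <- spec$tissue_classes[["fibrous"]] %||% spec$tissue_classes[[1L]]
        hw <- spec$fiber_width / 2
        for (i in seq_len(spec$n_fibers)) {
          ang <- stats::runif(1, 0, pi)
          off <- stats::runif(1, -0.4, 0.4) * r_in
          len <- stats::runif(1, 0.5, 0.9) * r_in
          u <- yy * cos(ang) + xx * sin(ang)
          v <- -yy * sin(ang) + xx * cos(ang)
          fib <- abs(u - off) <= hw & abs(v) <= len / 2 & rr <= r_in
          m[fib] <- k["mu"]; d[fib] <- k["delta"]; lb[fib] <- 100L + i
        }
      }
      mu[, , z] <- m; delta[, , z] <- d; labels[, , z] <- lb
    }
  })

  structure(list(mu = mu, delta = delta, labels = labels,
                 pixel_size = pixel_size, shape = c(ny, nx, nz)),
            class = "phantom_volume")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("phantom_volume: %d x %d x %d slice(s)\n",
              x$shape[1], x$shape[2], x$shape[3]))
  cat(sprintf("  mu in [%.4g, %.4g] /px, delta in [%.4g, %.4g]\n",
              min(x$mu), max(x$mu), min(x$delta), max(x$delta)))
  cat(sprintf("  %d labelled regions\n", length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}
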
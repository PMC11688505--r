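# Noise-power-spectrum analysis of no-sample reconstructions.

#' Reconstruct an ensemble of noise-only tomograms
#'
#' Simulates flat (empty-beam) noisy stepping scans, retrieves them, and
#' reconstructs each with the filter matching the signal type. Realizations
#' are independent (seed sequence `seed, seed+1, ...`). With noise disabled
#' the output is exactly zero, since an empty sample leaves `T = 1` and
#' `phi = 0`.
#'
#' @param geometry an [acquisition_geometry()]; its seed field is overridden
#'   per realization.
#' @param signal_type `"attenuation"` or `"electron_density"`.
#' @param n_realizations ensemble size (>= 1).
#' @param seed base seed.
#' @param shape detector `c(n_rows, n_cols)`; reconstructions are
#'   `n_cols x n_cols`.
#' @param noise logical, Poisson noise on/off.
#' @return list of 2D matrices (one slice per realization).
#' @export
noise_only_tomograms <- function(geometry, signal_type = c("attenuation", "electron_density"),
                                 n_realizations = 16L, seed = 1L,
                                 shape = c(1L, 64L), noise = TRUE) {
  signal_type <- match.arg(signal_type)
  stopifnot_scalar(n_realizations, "n_realizations", min = 1, integer = TRUE)
  lapply(seq_len(n_realizations), function(i) {
    g <- geometry
    g$seed <- as.integer(seed + i - 1L)
    scan <- simulate_flat_scan(g, shape, noise = noise)
    sino <- retrieve(scan)
    tomo <- if (signal_type == "attenuation") reconstruct_attenuation(sino)
            else reconstruct_electron_density(sino, phase_sensitivity = g$phase_sensitivity)
    tomo$data[, , 1]
  })
}

#' Radially averaged noise power spectrum
#'
#' Subtracts the ensemble mean from every realization, takes the 2D DFT,
#' averages the squared magnitudes over the ensemble, and bins them by radial
#' spatial frequency `|k|` in cycles/pixel. The DC mode is excluded; bins are
#' equal-width over `(0, 0.5]`. The curve keeps the per-bin mode counts
#' (annulus-area weights) used by [low_frequency_fraction()] and
#' [band_power()], and the spectrum is in arbitrary units (comparisons are
#' ratios within one pipeline run).
#'
#' @param images list of square noise realizations (equal dims).
#' @param n_bins number of radial bins.
#' @return object of class `nps_curve`: `k` (bin centers), `power`,
#'   `weight` (modes per bin), `n_realizations`, `total_power`.
#' @export
nps_radial <- function(images, n_bins = 32L) {
  if (length(images) < 1L) stop("need at least one realization")
  d <- dim(images[[1]])
  if (d[1] != d[2]) stop("images must be square")
  if (!all(vapply(images, function(m) identical(dim(m), d), logical(1))))
    stop("all realizations must share one shape")
  n <- d[1]
  mean_img <- Reduce(`+`, images) / length(images)
  p2 <- matrix(0, n, n)
  for (im in images) p2 <- p2 + Mod(stats::fft(im - mean_img))^2
  p2 <- p2 / length(images)

  k1 <- fft_freq(n)
  kr <- sqrt(outer(k1^2, k1^2, `+`))
  edges <- seq(0, 0.5, length.out = n_bins + 1L)
  bin <- findInterval(kr, edges, rightmost.closed = TRUE)
  bin[kr == 0] <- 0L                     # drop DC
  bin[bin > n_bins] <- 0L                # corners beyond Nyquist radius
  power <- numeric(n_bins); weight <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    weight[b] <- sum(sel)
    power[b] <- if (weight[b] > 0) mean(p2[sel]) else 0
  }
  structure(list(k = (edges[-1] + edges[-length(edges)]) / 2, power = power,
                 weight = weight, n_realizations = length(images),
                 total_power = sum(p2)),
            class = "nps_curve")
}

#' Fraction of noise power below a frequency cutoff
#'
#' `sum(P(k) * w(k), k < k_cut) / sum(P(k) * w(k))` with annulus-area weights
#' `w(k)` (per-bin mode counts); DC is already excluded by [nps_radial()].
#'
#' @param curve an [nps_radial()] curve.
#' @param k_cut cutoff in cycles/pixel, `0 < k_cut < 0.5`.
#' @return fraction in `[0, 1]`.
#' @export
low_frequency_fraction <- function(curve, k_cut) {
  stopifnot(inherits(curve, "nps_curve"))
  if (!length(curve$k)) stop("empty curve")
  stopifnot_scalar(k_cut, "k_cut", min = 1e-12, max = 0.5 - 1e-12)
  tot <- sum(curve$power * curve$weight)
  if (tot == 0) stop("curve carries no power")
  sum(curve$power[curve$k < k_cut] * curve$weight[curve$k < k_cut]) / tot
}

#' Weighted band power of an NPS curve
#'
#' @param curve an [nps_radial()] curve.
#' @param k_lo,k_hi band limits in cycles/pixel.
#' @return sum of `P(k) * w(k)` over bins with `k_lo <= k < k_hi`.
#' @export
band_power <- function(curve, k_lo, k_hi) {
  stopifnot(inherits(curve, "nps_curve"))
  sel <- curve$k >= k_lo & curve$k < k_hi
  sum(curve$power[sel] * curve$weight[sel])
}

#' @export
print.nps_curve <- function(x, ...) {
  cat(sprintf("nps_curve: %d bins over (0, 0.5], %d realization(s), total power %.4g\n",
              length(x$k), x$n_realizations, x$total_power))
  invisible(x)
}
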
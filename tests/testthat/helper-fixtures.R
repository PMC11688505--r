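# Shared fixtures, built in code at test time.

# Uniform-disk phantom (water bath only) with known mu/delta.
disk_phantom <- function(n = 64, mu = 0.01, delta = 0.005, nz = 1L) {
  make_phantom(c(n, n, nz),
               phantom_spec(n_regions = 0L, n_fibers = 0L,
                            include_tube = FALSE, include_rod = FALSE,
                            water = c(mu = mu, delta = delta)),
               seed = 1L)
}

# Small structured phantom for denoising studies.
study_phantom <- function(n = 64, nz = 3L, seed = 11L) {
  make_phantom(c(n, n, nz), phantom_spec(), seed = seed)
}

small_geometry <- function(n_angles = 100L, flux = 500, C = 24, seed = 1L, ...) {
  acquisition_geometry(n_angles = n_angles, flux_per_step = flux,
                       phase_sensitivity = C, seed = seed, ...)
}

# Assemble a sinogram_pair directly from arrays (oracle-side constructor).
manual_sinogram <- function(transmission, dphase, angles) {
  na <- length(angles)
  tr <- if (length(dim(transmission)) == 3L) transmission else
    array(transmission, c(na, 1L, ncol(transmission)))
  dp <- if (length(dim(dphase)) == 3L) dphase else
    array(dphase, c(na, 1L, ncol(dphase)))
  structure(list(transmission = tr, dphase = dp, angles = angles,
                 phase_mask = array(FALSE, dim(tr))),
            class = "sinogram_pair")
}

# Interior disk mask for an n x n grid.
disk_mask <- function(n, radius) {
  cy <- (n + 1) / 2
  yy <- matrix(seq_len(n) - cy, n, n)
  sqrt(yy^2 + t(yy)^2) <= radius
}

# Independent brute-force ray integrator (explicit loops, same geometric
# conventions as the package projector but written separately).
brute_line_integral <- function(img, theta, t_col, step = 0.5) {
  n <- nrow(img)
  c0 <- (n + 1) / 2
  t <- t_col - c0
  L <- sqrt(2) * n / 2 + 1
  u <- seq(-L, L, by = step)
  total <- 0
  for (ui in u) {
    x <- t * cos(theta) - ui * sin(theta)
    y <- t * sin(theta) + ui * cos(theta)
    ri <- y + c0; ci <- x + c0
    i0 <- floor(ri); j0 <- floor(ci)
    fi <- ri - i0; fj <- ci - j0
    v <- 0
    for (di in 0:1) for (dj in 0:1) {
      ii <- i0 + di; jj <- j0 + dj
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= n) {
        w <- (if (di == 0) 1 - fi else fi) * (if (dj == 0) 1 - fj else fj)
        v <- v + w * img[ii, jj]
      }
    }
    total <- total + v
  }
  total * step
}

# Poisson-resample a noiseless scan's sample counts (fast ensemble
# generation). The reference stays at its expectation - the noise-averaged
# reference of the retrieval design - so the noise of disjoint angle
# subsets is element-wise independent, the premise of the split trainer.
resample_scan <- function(scan0, seed) {
  out <- scan0
  set.seed(seed)
  out$sample[] <- rpois(length(scan0$sample), scan0$sample)
  out$noisy <- TRUE
  out
}
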
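test_that("flat stepping curve yields masked phase and zero amplitude", {
  f <- fit_stepping_curve(rep(100, 5))
  expect_equal(f$mean, 100)
  expect_equal(f$amplitude, 0)
  expect_true(f$masked)
  expect_equal(f$phase, 0)
})

test_that("exact single harmonics are fit to machine precision", {
  s <- 0:4
  f <- fit_stepping_curve(100 * (1 + 0.5 * cos(2 * pi * s / 5)))
  expect_equal(f$mean, 100, tolerance = 1e-13)
  expect_equal(f$amplitude, 50, tolerance = 1e-13)
  expect_equal(f$phase, 0, tolerance = 1e-13)
  # shift theorem
  f2 <- fit_stepping_curve(100 * (1 + 0.5 * cos(2 * pi * s / 5 + pi / 2)))
  expect_equal(f2$phase, pi / 2, tolerance = 1e-13)
  expect_error(fit_stepping_curve(rep(1, 3)), "at least 4")
  expect_error(fit_stepping_curve(c(-1, 1, 1, 1, 1)), "non-negative")
})

test_that("identical sample and reference scans retrieve T = 1, phi = 0", {
  geom <- small_geometry(n_angles = 6L)
  scan <- simulate_flat_scan(geom, c(2L, 16L), noise = FALSE)
  sino <- retrieve(scan)
  expect_equal(max(abs(sino$transmission - 1)), 0, tolerance = 1e-13)
  expect_equal(max(abs(sino$dphase)), 0, tolerance = 1e-13)
})

test_that("transmission is the ratio of fitted means", {
  s <- 0:4
  geom <- small_geometry(n_angles = 1L, flux = 100)
  scan <- simulate_flat_scan(geom, c(1L, 1L), noise = FALSE)
  scan$sample[1, , 1, 1] <- 50 * (1 + 0.3 * cos(2 * pi * s / 5))
  scan$reference[, 1, 1] <- 100 * (1 + 0.3 * cos(2 * pi * s / 5))
  expect_equal(retrieve(scan)$transmission[1, 1, 1], 0.5, tolerance = 1e-13)
})

test_that("noiseless retrieval inverts the forward model to machine precision", {
  ph <- study_phantom(64, nz = 1L)
  geom <- small_geometry(n_angles = 100L)
  exp0 <- gbpcct:::.stepping_expectation(ph, geom)
  sino <- retrieve(simulate_stepping(ph, geom, noise = FALSE))
  expect_lt(max(abs(sino$transmission - exp0$transmission) /
                pmax(exp0$transmission, 1e-12)), 1e-12)
  expect_lt(max(abs(sino$dphase - exp0$dphase)), 1e-12)
})

test_that("patchwise retrieval at radius 0 is bit-identical to plain retrieval", {
  ph <- study_phantom(48, nz = 1L, seed = 2L)
  geom <- small_geometry(n_angles = 10L, seed = 7L)
  scan <- simulate_stepping(ph, geom, noise = TRUE)
  expect_identical(retrieve_patchwise(scan, 0L), retrieve(scan))
  expect_error(retrieve_patchwise(scan, 40L), "radius")
})

test_that("patchwise retrieval is exact on homogeneous regions", {
  geom <- small_geometry(n_angles = 4L)
  scan <- simulate_flat_scan(geom, c(5L, 24L), noise = FALSE)
  plain <- retrieve(scan)
  pooled <- retrieve_patchwise(scan, 2L)
  # interior only: zero padding bleeds zeros across the border
  expect_equal(pooled$transmission[, 3, 5:20], plain$transmission[, 3, 5:20],
               tolerance = 1e-12)
})

test_that("patchwise retrieval matches a joint least-squares oracle and blurs edges", {
  # step-edge phantom: transmission drops across half the detector
  ns <- 5L; nx <- 32L
  s <- 0:(ns - 1)
  geom <- small_geometry(n_angles = 1L, flux = 1000)
  scan <- simulate_flat_scan(geom, c(5L, nx), noise = FALSE)
  Ttrue <- matrix(rep(c(rep(1, nx / 2), rep(0.4, nx / 2)), each = 5), 5, nx)
  for (si in seq_len(ns))
    scan$sample[1, si, , ] <- 1000 * Ttrue *
      (1 + 0.3 * cos(2 * pi * s[si] / ns))
  r <- 2L
  pooled <- retrieve_patchwise(scan, r)
  # oracle: explicit joint least squares on the pooled series of each pixel
  design <- cbind(1, cos(2 * pi * s / ns), sin(2 * pi * s / ns))
  for (px in c(10L, 16L, 17L, 25L)) {
    rows <- max(1, 3 - r):min(5, 3 + r)
    cols <- max(1, px - r):min(nx, px + r)
    series <- rep(0, ns)
    for (ri in rows) for (ci in cols)
      series <- series + scan$sample[1, , ri, ci]
    beta <- qr.solve(design, series)
    a_r <- 1000 * length(rows) * length(cols)
    expect_equal(pooled$transmission[1, 3, px], beta[1] / a_r,
                 tolerance = 1e-10)
  }
  # blurring artifact: the pooled 10-90% edge width exceeds the plain one
  plain <- retrieve(scan)
  width_1090 <- function(profile) {
    p <- (max(profile) - profile) / (max(profile) - min(profile))
    sum(p > 0.1 & p < 0.9)
  }
  expect_gt(width_1090(pooled$transmission[1, 3, ]),
            width_1090(plain$transmission[1, 3, ]))
})

test_that("phase variance is invariant to step count at fixed photon budget", {
  total <- 4000
  vars <- vapply(c(4L, 5L, 8L), function(ns) {
    geom <- acquisition_geometry(n_angles = 1L, n_steps = ns,
                                 flux_per_step = total / ns,
                                 phase_sensitivity = 24, seed = 100L + ns)
    sino <- retrieve(simulate_flat_scan(geom, c(1L, 10000L), noise = TRUE))
    stats::var(as.vector(sino$dphase))
  }, numeric(1))
  expect_lt(max(vars) / min(vars) - 1, 0.10)
})

test_that("patchwise variance decreases monotonically with radius", {
  geom <- small_geometry(n_angles = 1L, flux = 300, seed = 31L)
  scan <- simulate_flat_scan(geom, c(40L, 200L), noise = TRUE)
  v <- vapply(0:2, function(r) {
    sino <- retrieve_patchwise(scan, r)
    stats::var(as.vector(sino$dphase[1, 10:30, 20:180]))
  }, numeric(1))
  expect_true(v[1] > v[2] && v[2] > v[3])
})
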
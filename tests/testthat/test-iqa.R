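test_that("rmse follows its closed form and is symmetric", {
  x <- matrix(0.5, 8, 8); y <- matrix(0, 8, 8)
  expect_identical(rmse(x, x), 0)
  expect_equal(rmse(x, y), 0.5)
  set.seed(1)
  a <- matrix(rnorm(100), 10, 10); b <- matrix(rnorm(100), 10, 10)
  # naive double-loop oracle
  acc <- 0
  for (i in 1:10) for (j in 1:10) acc <- acc + (a[i, j] - b[i, j])^2
  expect_equal(rmse(a, b), sqrt(acc / 100), tolerance = 1e-12)
  expect_identical(rmse(a, b), rmse(b, a))
  expect_error(rmse(a, matrix(0, 5, 5)), "shapes")
})

test_that("psnr uses the reference supremum norm and is asymmetric", {
  y <- matrix(c(1, -0.5, 0.25, 0), 2, 2)
  x <- y + 0.5
  expect_equal(psnr(x, y), 20 * log10(1 / 0.5), tolerance = 1e-12)
  p <- psnr(y, y)
  expect_identical(as.numeric(p), Inf)
  expect_true(attr(p, "exact"))
  expect_error(psnr(x, matrix(0, 2, 2)), "all zero")
  # independent reimplementation from the definitions
  set.seed(2)
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  oracle <- 20 * log10(max(abs(b)) / sqrt(mean((a - b)^2)))
  expect_equal(psnr(a, b), oracle, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(psnr(a, b), psnr(b, a))))
})

test_that("ssim is 1 at identity, negative for sign-flipped structure", {
  set.seed(4)
  x <- matrix(rnorm(32 * 32), 32, 32)
  expect_equal(ssim(x, x, data_range = diff(range(x))), 1, tolerance = 1e-12)
  # locally zero-mean anti-correlated structure: the luminance term stays
  # near 1 while the covariance term goes negative
  z <- outer(sin(2 * pi * (1:32) / 4), sin(2 * pi * (1:32) / 4))
  expect_lt(ssim(-z, z, data_range = diff(range(z))), 0)
  expect_error(ssim(x, x, data_range = 0), "data_range")
})

test_that("ssim matches a brute-force sliding-window oracle", {
  set.seed(5)
  n <- 24L
  x <- matrix(runif(n * n), n, n); y <- matrix(runif(n * n), n, n)
  dr <- diff(range(y))
  sig <- 1.5
  rad <- ceiling(3 * sig)
  k1 <- gbpcct:::gauss_kernel1d(sig, radius = rad)
  w <- outer(k1, k1)
  C1 <- (0.01 * dr)^2; C2 <- (0.03 * dr)^2
  vals <- c()
  for (i in (rad + 1):(n - rad)) for (j in (rad + 1):(n - rad)) {
    px <- x[(i - rad):(i + rad), (j - rad):(j + rad)]
    py <- y[(i - rad):(i + rad), (j - rad):(j + rad)]
    mx <- sum(w * px); my <- sum(w * py)
    vx <- sum(w * px^2) - mx^2; vy <- sum(w * py^2) - my^2
    cxy <- sum(w * px * py) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  expect_equal(ssim(x, y, window_sigma = sig, data_range = dr), mean(vals),
               tolerance = 1e-8)
})

test_that("ssim is invariant under common rescaling with matched data range", {
  set.seed(6)
  x <- matrix(rnorm(400), 20, 20); y <- matrix(rnorm(400), 20, 20)
  s1 <- ssim(x, y, data_range = 2)
  s2 <- ssim(3 * x, 3 * y, data_range = 6)
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("edge preservation ratios reduce to set arithmetic", {
  img <- matrix(0, 48, 48)
  img[12:36, 12:36] <- 1                      # sharp square
  expect_equal(unname(edge_preservation(img, img)), c(1, 1))
  # subset case: hand-built edge maps through the formulas
  R <- matrix(FALSE, 8, 8); R[2, 1:8] <- TRUE
  D <- matrix(FALSE, 8, 8); D[2, 1:4] <- TRUE
  inter <- sum(R & D)
  expect_equal(inter / sum(R), 0.5)
  expect_equal(inter / sum(D), 1)
  # blurred copy: package EPR equals explicit set operations on its edge maps
  blur <- gaussian_blur(img, 2)
  p <- canny_params()
  ep <- edge_preservation(blur, img, p)
  Rm <- canny(img, p); Dm <- canny(blur, p)
  expect_equal(ep[["epra"]], sum(Rm & Dm) / sum(Rm))
  expect_equal(ep[["eprr"]], sum(Rm & Dm) / sum(Dm))
  expect_true(all(ep >= 0 & ep <= 1))
  expect_error(edge_preservation(matrix(0, 8, 8), matrix(0, 8, 8)), "no detected edges")
  expect_error(canny_params(low_threshold = 0.3, high_threshold = 0.2), "low")
})

test_that("stack assessment aggregates with the population convention", {
  set.seed(8)
  base <- matrix(0, 40, 40); base[10:30, 10:30] <- 1
  y <- array(c(base, base), c(40, 40, 2))
  x <- y + array(rnorm(3200, sd = 0.05), c(40, 40, 2))
  rep <- assess_stack(x, y)
  expect_identical(nrow(rep$per_slice), 2L)
  for (m in c("psnr", "ssim", "epra", "eprr")) {
    v <- rep$per_slice[[m]]
    row <- rep$summary[rep$summary$metric == m, ]
    expect_equal(row$mean, mean(v))
    expect_equal(row$sd, sqrt(mean((v - mean(v))^2)))   # population sd
  }
  # identical slice pairs: zero spread
  x2 <- array(x[, , 1], c(40, 40, 2))
  y2 <- array(y[, , 1], c(40, 40, 2))
  rep2 <- assess_stack(x2, y2)
  expect_true(all(rep2$summary$sd == 0))
  expect_warning(assess_stack(x[, , 1], y[, , 1]), "fewer than 2")
})

test_that("iqa reports round-trip through CSV bit-exactly", {
  set.seed(9)
  base <- matrix(0, 40, 40); base[10:30, 10:30] <- 1
  y <- array(c(base, base), c(40, 40, 2))
  x <- y + array(rnorm(3200, sd = 0.05), c(40, 40, 2))
  rep <- assess_stack(x, y)
  path <- tempfile(fileext = ".csv")
  write_iqa_report(rep, path)
  back <- read_iqa_report(path)
  expect_identical(back$per_slice$psnr, rep$per_slice$psnr)
  expect_identical(back$per_slice$ssim, rep$per_slice$ssim)
  expect_identical(back$summary$mean, rep$summary$mean)
  expect_identical(back$summary$sd, rep$summary$sd)
})
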
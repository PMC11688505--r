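# Reference-based image quality assessment: RMSE/PSNR, SSIM, Canny-based
# edge-preservation ratios, and the per-stack aggregation protocol.

.as_img <- function(x) {
  if (inherits(x, "tomogram")) x$data else x
}

#' Root-mean-square error between an image and a reference
#'
#' @param x image (matrix, array, or [tomogram()]).
#' @param y reference of identical shape.
#' @return single number `sqrt(mean((x - y)^2))`.
#' @export
rmse <- function(x, y) {
  x <- .as_img(x); y <- .as_img(y)
  if (!identical(dim(x), dim(y))) stop("x and y must have identical shapes")
  sqrt(mean((x - y)^2))
}

#' Peak signal-to-noise ratio
#'
#' `20 * log10(max|y| / RMSE)` where the peak is the supremum norm of the
#' *reference*; asymmetric by construction. A zero RMSE is reported as `Inf`
#' with attribute `exact = TRUE`.
#'
#' @param x image.
#' @param y reference image; must not be all zero.
#' @return PSNR in decibels.
#' @export
psnr <- function(x, y) {
  x <- .as_img(x); y <- .as_img(y)
  if (!identical(dim(x), dim(y))) stop("x and y must have identical shapes")
  peak <- max(abs(y))
  if (peak == 0) stop("reference image is all zero; PSNR undefined")
  r <- rmse(x, y)
  if (r == 0) return(structure(Inf, exact = TRUE))
  20 * log10(peak / r)
}

#' Structural similarity index
#'
#' Canonical local-statistics SSIM with a Gaussian weighting window:
#' per-position luminance term `(2*mu_x*mu_y + C1) / (mu_x^2 + mu_y^2 + C1)`
#' and contrast-structure term `(2*cov_xy + C2) / (var_x + var_y + C2)`, with
#' stabilizers `C1 = (0.01 * data_range)^2`, `C2 = (0.03 * data_range)^2`,
#' averaged over all fully supported window positions. Equals 1 iff the
#' images coincide; can be negative for anti-correlated structure.
#'
#' @param x image (2D matrix or stack; stacks are averaged over slices).
#' @param y reference of identical shape.
#' @param window_sigma Gaussian window width in pixels.
#' @param data_range value range spanned by the reference content; must be
#'   positive.
#' @return mean SSIM.
#' @export
ssim <- function(x, y, window_sigma = 1.5, data_range = NULL) {
  x <- as_stack(.as_img(x)); y <- as_stack(.as_img(y))
  if (!identical(dim(x), dim(y))) stop("x and y must have identical shapes")
  if (is.null(data_range)) data_range <- diff(range(y))
  if (!is.numeric(data_range) || data_range <= 0)
    stop("data_range must be positive")
  mean(vapply(seq_len(dim(x)[3]), function(z)
    .ssim_slice(x[, , z], y[, , z], window_sigma, data_range), numeric(1)))
}

.ssim_slice <- function(x, y, window_sigma, data_range) {
  k <- gauss_kernel1d(window_sigma, radius = max(1L, ceiling(3 * window_sigma)))
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  w <- function(m) .sep_valid(m, k)
  mx <- w(x); my <- w(y)
  vx <- w(x * x) - mx^2
  vy <- w(y * y) - my^2
  cxy <- w(x * y) - mx * my
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

# Separable 'valid' convolution with a symmetric 1D kernel.
.sep_valid <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  conv1 <- function(mm) {               # along columns of mm
    n <- ncol(mm)
    out <- matrix(0, nrow(mm), n - 2L * r)
    for (j in seq_along(k))
      out <- out + k[j] * mm[, j:(j + n - 2L * r - 1L), drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

#' Canny edge-detector parameters
#'
#' @param gaussian_sigma smoothing width in pixels.
#' @param low_threshold,high_threshold hysteresis thresholds as fractions of
#'   the maximum gradient magnitude; `0 < low < high`.
#' @return object of class `canny_params`.
#' @export
canny_params <- function(gaussian_sigma = 1.4, low_threshold = 0.1,
                         high_threshold = 0.2) {
  if (!(low_threshold > 0 && low_threshold < high_threshold))
    stop("need 0 < low_threshold < high_threshold")
  structure(list(gaussian_sigma = gaussian_sigma,
                 low_threshold = low_threshold,
                 high_threshold = high_threshold),
            class = "canny_params")
}

#' Canny edge map
#'
#' Gaussian smoothing, Sobel gradients, quantized non-maximum suppression,
#' and two-threshold hysteresis (thresholds relative to the image's maximum
#' gradient magnitude).
#'
#' @param img 2D matrix.
#' @param p a [canny_params()].
#' @return logical matrix of edge pixels.
#' @export
canny <- function(img, p = canny_params()) {
  stopifnot(is.matrix(img))
  sm <- sep_convolve_reflect(img, gauss_kernel1d(p$gaussian_sigma))
  sob <- function(m, kr, kc) {
    # full 3x3 correlation with reflective borders via two 1D passes
    r <- 1L
    ny <- nrow(m); nx <- ncol(m)
    mi <- m[reflect_index(0:(ny + 1L), ny), , drop = FALSE]
    v <- kr[1] * mi[1:ny, ] + kr[2] * mi[2:(ny + 1L), ] + kr[3] * mi[3:(ny + 2L), ]
    vj <- v[, reflect_index(0:(nx + 1L), nx), drop = FALSE]
    kc[1] * vj[, 1:nx] + kc[2] * vj[, 2:(nx + 1L)] + kc[3] * vj[, 3:(nx + 2L)]
  }
  gy <- sob(sm, c(-1, 0, 1), c(1, 2, 1))   # d/d(row)
  gx <- sob(sm, c(1, 2, 1), c(-1, 0, 1))   # d/d(col)
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, nrow(img), ncol(img)))

  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)   # 0:E-W,1:NE-SW,2:N-S,3:NW-SE
  ny <- nrow(img); nx <- ncol(img)
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  shift_m <- function(m, di, dj) {
    out <- matrix(0, ny, nx)
    i_dst <- max(1, 1 + di):min(ny, ny + di)
    j_dst <- max(1, 1 + dj):min(nx, nx + dj)
    out[i_dst, j_dst] <- m[i_dst - di, j_dst - dj]
    out
  }
  keep <- matrix(FALSE, ny, nx)
  for (s in 0:3) {
    d <- off[[s + 1L]]
    n1 <- shift_m(mag, d[1], d[2])
    n2 <- shift_m(mag, -d[1], -d[2])
    keep <- keep | (sector == s & mag >= n1 & mag >= n2)
  }
  thin <- mag * keep

  strong <- thin >= p$high_threshold * mmax
  weak <- thin >= p$low_threshold * mmax
  # hysteresis: grow strong edges through connected weak pixels (8-neighborhood)
  edges <- strong
  repeat {
    grown <- edges
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      grown <- grown | (shift_m(edges * 1, di, dj) > 0 & weak)
    }
    if (identical(grown, edges)) break
    edges <- grown
  }
  edges
}

#' Edge-preservation ratios from Canny edge maps
#'
#' With `R = Canny(reference)` and `D = Canny(distorted)` under identical
#' parameters, the accuracy `EPRa = |R intersect D| / |R|` measures how many
#' true edges survive, and the robustness `EPRr = |R intersect D| / |D|` how
#' many detected edges are true. An edge-free reference is an error; an
#' edge-free distorted image reports `EPRr = 1` by convention (message
#' emitted).
#'
#' @param x distorted image (2D matrix or tomogram slice).
#' @param y reference image, same shape.
#' @param p shared [canny_params()].
#' @return named vector `c(epra = ..., eprr = ...)`, both in `[0, 1]`.
#' @export
edge_preservation <- function(x, y, p = canny_params()) {
  x <- .as_img(x); y <- .as_img(y)
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 1L) {
    x <- x[, , 1]; y <- y[, , 1]
  }
  if (!identical(dim(x), dim(y))) stop("x and y must have identical shapes")
  R <- canny(y, p)
  D <- canny(x, p)
  nR <- sum(R)
  if (nR == 0) stop("reference image has no detected edges; EPRa undefined")
  inter <- sum(R & D)
  nD <- sum(D)
  eprr <- if (nD == 0) {
    message("distorted image has no detected edges; EPRr = 1 by convention")
    1
  } else inter / nD
  c(epra = inter / nR, eprr = eprr)
}

#' Assess a slice stack against a reference
#'
#' Per-slice PSNR, SSIM, EPRa and EPRr, plus the aggregation protocol:
#' per-metric mean and *population* standard deviation over slices. A
#' single-slice stack reports zero spread with a warning.
#'
#' @param x test [tomogram()] (or array).
#' @param y reference tomogram of equal shape (and signal type, if both are
#'   tomograms).
#' @param window_sigma SSIM window width.
#' @param data_range SSIM data range (default: reference range).
#' @param canny shared [canny_params()] for the EPR metrics.
#' @return object of class `iqa_report`: `per_slice` data frame and
#'   `summary` data frame (metric, mean, sd).
#' @export
assess_stack <- function(x, y, window_sigma = 1.5, data_range = NULL,
                         canny = canny_params()) {
  if (inherits(x, "tomogram") && inherits(y, "tomogram") &&
      !identical(x$signal_type, y$signal_type))
    stop("signal types differ between test and reference tomograms")
  xs <- as_stack(.as_img(x)); ys <- as_stack(.as_img(y))
  if (!identical(dim(xs), dim(ys))) stop("shapes differ")
  nz <- dim(xs)[3]
  if (nz < 2L) warning("fewer than 2 slices; standard deviation reported as 0")
  if (is.null(data_range)) data_range <- diff(range(ys))
  rows <- lapply(seq_len(nz), function(z) {
    ep <- edge_preservation(xs[, , z], ys[, , z], canny)
    data.frame(slice = z,
               psnr = as.numeric(psnr(xs[, , z], ys[, , z])),
               ssim = ssim(xs[, , z], ys[, , z], window_sigma, data_range),
               epra = ep[["epra"]], eprr = ep[["eprr"]])
  })
  per_slice <- do.call(rbind, rows)
  pop_sd <- function(v) if (length(v) < 2L) 0 else sqrt(mean((v - mean(v))^2))
  metrics <- c("psnr", "ssim", "epra", "eprr")
  summary <- data.frame(metric = metrics,
                        mean = vapply(metrics, function(m) mean(per_slice[[m]]), numeric(1)),
                        sd = vapply(metrics, function(m) pop_sd(per_slice[[m]]), numeric(1)),
                        row.names = NULL)
  structure(list(per_slice = per_slice, summary = summary,
                 sd_convention = "population"),
            class = "iqa_report")
}

#' @export
print.iqa_report <- function(x, ...) {
  cat(sprintf("iqa_report over %d slice(s) (mean +/- %s sd):\n",
              nrow(x$per_slice), x$sd_convention))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %s: %.4g +/- %.3g\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}

#' Write / read an IQA report as CSV
#'
#' The per-slice table and the summary are stored in one CSV with a `table`
#' column; full double precision is preserved so a round trip is bit-exact.
#'
#' @param report an [assess_stack()] report.
#' @param path CSV file path.
#' @return `path`, invisibly (writer); an `iqa_report` (reader).
#' @export
write_iqa_report <- function(report, path) {
  fmt <- function(v) sprintf("%.17g", v)
  ps <- data.frame(slice = report$per_slice$slice,
                   psnr = fmt(report$per_slice$psnr),
                   ssim = fmt(report$per_slice$ssim),
                   epra = fmt(report$per_slice$epra),
                   eprr = fmt(report$per_slice$eprr))
  sm <- data.frame(metric = report$summary$metric,
                   mean = fmt(report$summary$mean),
                   sd = fmt(report$summary$sd))
  utils::write.csv(ps, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(sm, paste0(path, ".summary.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_iqa_report
#' @export
read_iqa_report <- function(path) {
  ps <- utils::read.csv(path, colClasses = "character")
  per_slice <- data.frame(slice = as.integer(ps$slice),
                          psnr = as.numeric(ps$psnr),
                          ssim = as.numeric(ps$ssim),
                          epra = as.numeric(ps$epra),
                          eprr = as.numeric(ps$eprr))
  sm <- utils::read.csv(paste0(path, ".summary.csv"), colClasses = "character")
  summary <- data.frame(metric = sm$metric,
                        mean = as.numeric(sm$mean), sd = as.numeric(sm$sd))
  structure(list(per_slice = per_slice, summary = summary,
                 sd_convention = "population"),
            class = "iqa_report")
}
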
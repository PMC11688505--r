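# Reference denoisers: Gaussian blur (the smoothing-filter baseline) and the
# adapter seam for external BM3D / statistical-iterative backends.

#' Gaussian blur of a tomogram
#'
#' Isotropic per-slice Gaussian filtering with reflective borders;
#' `sigma = 0` returns the input unchanged.
#'
#' @param tomo a [tomogram()] (or matrix / array).
#' @param sigma Gaussian width in pixels (>= 0).
#' @return object of the same kind as the input.
#' @export
gaussian_blur <- function(tomo, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single non-negative number")
  if (sigma == 0) return(tomo)
  k <- gauss_kernel1d(sigma)
  blur_stack <- function(a) {
    a <- as_stack(a)
    for (z in seq_len(dim(a)[3])) a[, , z] <- sep_convolve_reflect(a[, , z], k)
    a
  }
  if (inherits(tomo, "tomogram")) {
    out <- tomo
    out$data <- blur_stack(tomo$data)
    out$provenance$denoiser <- sprintf("gaussian(sigma=%g)", sigma)
    out
  } else if (is.matrix(tomo)) {
    blur_stack(tomo)[, , 1]
  } else {
    blur_stack(tomo)
  }
}

#' Background noise level from a region of interest
#'
#' Sample standard deviation over a rectangular background ROI, the value fed
#' to external block-matching denoisers as their noise parameter.
#'
#' @param tomo a [tomogram()] or matrix (first slice is used for stacks).
#' @param roi `c(row0, col0, row1, col1)`, inclusive bounds; area >= 16 px.
#' @return standard deviation estimate.
#' @export
estimate_background_sigma <- function(tomo, roi) {
  img <- as_stack(.as_img(tomo))[, , 1]
  if (length(roi) != 4L) stop("roi must be c(row0, col0, row1, col1)")
  r0 <- roi[1]; c0 <- roi[2]; r1 <- roi[3]; c1 <- roi[4]
  if (r0 < 1 || c0 < 1 || r1 > nrow(img) || c1 > ncol(img))
    stop("roi out of bounds")
  if (r1 < r0 || c1 < c0 || (r1 - r0 + 1) * (c1 - c0 + 1) < 16)
    stop("roi degenerate: need at least 16 pixels")
  stats::sd(img[r0:r1, c0:c1])
}

#' Denoiser specification for the comparison harness
#'
#' @param name one of `"none"`, `"gaussian"`, `"bm3d_external"`,
#'   `"sir_external"`.
#' @param params named list of parameters (`sigma` for gaussian and the
#'   external block-matcher's noise level).
#' @return object of class `denoiser_spec`.
#' @export
denoiser_spec <- function(name, params = list()) {
  known <- c("none", "gaussian", "bm3d_external", "sir_external")
  if (!name %in% known)
    stop(sprintf("unknown denoiser '%s'; expected one of %s", name,
                 paste(known, collapse = ", ")))
  if (name == "gaussian" && is.null(params$sigma))
    stop("gaussian denoiser needs params$sigma")
  if (name %in% c("bm3d_external", "sir_external") && is.null(params$sigma_noise))
    stop(sprintf("%s needs params$sigma_noise (background noise level)", name))
  structure(list(name = name, params = params), class = "denoiser_spec")
}

#' Availability of an external denoising backend
#'
#' @param name backend name as in [denoiser_spec()].
#' @return `TRUE` if the backend can be called in this session.
#' @export
external_backend_available <- function(name) {
  # no external BM3D or statistical-iterative-reconstruction backend ships
  # with the package; slot in site-specific adapters here
  FALSE
}

#' Apply a denoiser specification to a tomogram
#'
#' The adapter seam of the comparison harness: `"none"` is the identity,
#' `"gaussian"` dispatches to [gaussian_blur()], and the external backends
#' (block-matching 3D, statistical iterative reconstruction) raise an
#' actionable error when no adapter is installed - they are third-party
#' tools, not reimplemented here.
#'
#' @param tomo a [tomogram()].
#' @param spec a [denoiser_spec()].
#' @return a [tomogram()]; provenance records the method.
#' @export
run_external <- function(tomo, spec) {
  stopifnot(inherits(tomo, "tomogram"), inherits(spec, "denoiser_spec"))
  switch(spec$name,
    none = tomo,
    gaussian = gaussian_blur(tomo, spec$params$sigma),
    bm3d_external = ,
    sir_external = {
      if (!external_backend_available(spec$name))
        stop(sprintf(paste0("backend '%s' is not installed; register an adapter ",
                            "in external_backend_available()/run_external() to ",
                            "use it"), spec$name))
      stop("unreachable")
    })
}
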
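# Shared numeric helpers.

#' Wrap angles to the half-open interval (-pi, pi]
#'
#' Values equal to -pi (after reduction modulo 2*pi) are mapped to +pi so the
#' interval is half-open on the left, matching the differential-phase sign
#' convention used throughout the package.
#'
#' @param x numeric vector or array of angles in radians.
#' @return object of the same shape with every entry in (-pi, pi].
#' @export
wrap_phase <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w <= -pi + .Machine$double.eps * 4 & !is.na(w)] <-
    w[w <= -pi + .Machine$double.eps * 4 & !is.na(w)] + 2 * pi
  # exact multiples of 2*pi can land on -pi through floating error; the line
  # above folds them back to +pi
  w[w > pi & !is.na(w)] <- pi
  w
}

# Run code with a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# FFT bin frequencies in cycles per sample, matching numpy's fftfreq layout.
fft_freq <- function(n) {
  i <- 0:(n - 1)
  ifelse(i <= n %/% 2 - (n %% 2 == 0), i, i - n) / n
}

# Sampled 1D Gaussian kernel, normalised to unit sum.
gauss_kernel1d <- function(sigma, radius = NULL) {
  if (sigma <= 0) return(1)
  if (is.null(radius)) radius <- max(1L, ceiling(3.5 * sigma))
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution of a matrix with a 1D kernel along rows then columns,
# reflective (mirror-without-repeat) border handling.
sep_convolve_reflect <- function(img, kernel) {
  if (length(kernel) == 1L) return(img)
  r <- (length(kernel) - 1L) %/% 2L
  conv1 <- function(m, along_rows) {
    if (along_rows) m <- t(m)
    n <- ncol(m)
    idx <- reflect_index(seq_len(n + 2L * r) - r, n)
    mp <- m[, idx, drop = FALSE]
    out <- matrix(0, nrow(m), n)
    for (j in seq_along(kernel)) {
      out <- out + kernel[j] * mp[, j:(j + n - 1L), drop = FALSE]
    }
    if (along_rows) t(out) else out
  }
  conv1(conv1(img, FALSE), TRUE)
}

# Mirror indices into 1..n without repeating the border sample (scipy
# 'mirror' / skimage 'reflect' with symmetric=FALSE).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- ((i - 1L) %% p + p) %% p
  ifelse(j < n, j + 1L, p - j + 1L)
}

# Round doubles to the nearest IEEE float32-representable value. Used before
# writing float TIFFs so an emitted array reloads bit-exactly.
snap_float32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
               "numeric", n = length(x), size = 4L)
  dim(y) <- d
  y
}

# Promote a 2D matrix to a one-slice 3D array; pass 3D arrays through.
as_stack <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L))
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a matrix or a 3D array")
}

stopifnot_scalar <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  if (x < min || x > max)
    stop(sprintf("'%s' must be in [%s, %s]", name, format(min), format(max)),
         call. = FALSE)
  invisible(x)
}
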
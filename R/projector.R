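# Parallel-beam forward projector (ray-driven line integrals).

#' Parallel-beam line integrals of an image
#'
#' Computes the Radon transform of a 2D image over the given angles by
#' ray-driven sampling: each detector channel's ray is sampled at `step`-pixel
#' intervals with bilinear interpolation and summed, scaled by the step
#' length. Detector channels coincide with image columns (centered grid), and
#' angles are measured from the column axis, so at angle 0 the integral runs
#' along image rows.
#'
#' @param img 2D matrix (values in inverse pixel units).
#' @param angles projection angles in radians, within `[0, pi)`.
#' @param step ray sampling interval in pixels (default 0.5).
#' @return matrix `[length(angles), ncol(img)]` of line integrals.
#' @export
forward_project <- function(img, angles, step = 0.5) {
  stopifnot(is.matrix(img))
  ny <- nrow(img); nx <- ncol(img)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  t_det <- seq_len(nx) - cx
  half_len <- sqrt(ny^2 + nx^2) / 2 + 1
  u <- seq(-half_len, half_len, by = step)
  out <- matrix(0, length(angles), nx)
  for (a in seq_along(angles)) {
    th <- angles[a]
    ct <- cos(th); st <- sin(th)
    # sample points for all (t, u) pairs; ray direction is (-sin, cos)
    x <- outer(t_det * ct, -u * st, `+`)   # nx x nu
    y <- outer(t_det * st, u * ct, `+`)
    out[a, ] <- .bilinear_sum(img, y + cy, x + cx) * step
  }
  out
}

# Sum of bilinear interpolations of img at (row, col) coordinate matrices,
# by row of the coordinate matrices; points outside the grid contribute 0.
.bilinear_sum <- function(img, ri, ci) {
  ny <- nrow(img); nx <- ncol(img)
  i0 <- floor(ri); j0 <- floor(ci)
  fi <- ri - i0; fj <- ci - j0
  acc <- matrix(0, nrow(ri), ncol(ri))
  for (di in 0:1) for (dj in 0:1) {
    ii <- i0 + di; jj <- j0 + dj
    w <- (if (di == 0) 1 - fi else fi) * (if (dj == 0) 1 - fj else fj)
    ok <- ii >= 1 & ii <= ny & jj >= 1 & jj <= nx
    idx <- which(ok)
    if (length(idx)) {
      v <- numeric(length(w))
      v[idx] <- img[cbind(ii[idx], jj[idx])]
      acc <- acc + w * matrix(v, nrow(ri), ncol(ri))
    }
  }
  rowSums(acc)
}

# Central finite difference along the detector axis with zero padding at the
# edges: the forward model for the differential phase.
central_diff <- function(v) {
  n <- length(v)
  vp <- c(0, v, 0)
  (vp[3:(n + 2)] - vp[1:n]) / 2
}

# Uniform projection angles over [0, pi).
projection_angles <- function(n_angles) {
  (seq_len(n_angles) - 1L) * pi / n_angles
}
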
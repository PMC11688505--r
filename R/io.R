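# File containers: float32 TIFF stacks with YAML sidecars. TIFF floats are
# stored affine-scaled into [0, 1] (the writer's defined range) with the
# affine recorded in the sidecar; data are snapped to float32 before scaling
# so that write -> read round-trips reproduce the emitted array bit-exactly.

.write_float_tiff <- function(stack, path) {
  stack <- as_stack(stack)
  snapped <- snap_float32(stack)
  lo <- min(snapped); hi <- max(snapped)
  scale <- if (hi > lo) hi - lo else 1
  scaled <- snap_float32((snapped - lo) / scale)
  pages <- lapply(seq_len(dim(scaled)[3]), function(z)
    matrix(scaled[, , z], dim(scaled)[1], dim(scaled)[2]))
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   compression = "none", reduce = FALSE))
  list(offset = lo, scale = scale)
}

.aff_str <- function(a) list(offset = sprintf("%.17g", a$offset),
                              scale = sprintf("%.17g", a$scale))
.aff_num <- function(a) list(offset = as.numeric(a$offset),
                             scale = as.numeric(a$scale))

.read_float_tiff <- function(path, affine) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (z in seq_along(pages)) {
    p <- pages[[z]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    arr[, , z] <- p
  }
  arr * affine$scale + affine$offset
}

#' Write / read a tomogram as TIFF + YAML
#'
#' One multi-page float32 TIFF (slice per page) plus a `<path>.yaml` sidecar
#' carrying the value affine, signal type and provenance. The writer returns
#' the tomogram exactly as it will reload (float32-quantized), so callers
#' that keep the return value can rely on bit-exact round trips.
#'
#' @param tomo a [tomogram()].
#' @param path TIFF file path.
#' @return the quantized tomogram, invisibly (writer); a [tomogram()]
#'   (reader).
#' @export
write_tomogram <- function(tomo, path) {
  stopifnot(inherits(tomo, "tomogram"))
  aff <- .write_float_tiff(tomo$data, path)
  meta <- list(kind = "tomogram", signal_type = tomo$signal_type,
               affine = .aff_str(aff),
               dim = dim(as_stack(tomo$data)),
               provenance = .yamlify(tomo$provenance))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  out <- tomo
  out$data <- .read_float_tiff(path, aff)
  invisible(out)
}

#' @rdname write_tomogram
#' @export
read_tomogram <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  data <- .read_float_tiff(path, .aff_num(meta$affine))
  tomogram(data, meta$signal_type, provenance = meta$provenance %||% list())
}

.yamlify <- function(x) {
  rapply(x, function(v) if (is.numeric(v)) as.vector(v) else v,
         how = "replace")
}

#' Write / read a retrieved sinogram pair
#'
#' Two float32 TIFFs (`<prefix>_transmission.tif`, `<prefix>_dphase.tif`,
#' angle per page) plus a YAML sidecar with the angle grid and affines.
#'
#' @param sino a [retrieve()] sinogram pair.
#' @param prefix path prefix.
#' @return `prefix`, invisibly (writer); a `sinogram_pair` (reader).
#' @export
write_sinogram_pair <- function(sino, prefix) {
  stopifnot(inherits(sino, "sinogram_pair"))
  # store as [row, col, angle] pages for TIFF, angle per page
  tr <- aperm(sino$transmission, c(2, 3, 1))
  dp <- aperm(sino$dphase, c(2, 3, 1))
  a1 <- .write_float_tiff(tr, paste0(prefix, "_transmission.tif"))
  a2 <- .write_float_tiff(dp, paste0(prefix, "_dphase.tif"))
  yaml::write_yaml(list(kind = "sinogram_pair",
                        angles = sprintf("%.17g", sino$angles),
                        transmission = .aff_str(a1), dphase = .aff_str(a2),
                        dim = dim(sino$transmission)),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname write_sinogram_pair
#' @export
read_sinogram_pair <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  tr <- .read_float_tiff(paste0(prefix, "_transmission.tif"),
                         .aff_num(meta$transmission))
  dp <- .read_float_tiff(paste0(prefix, "_dphase.tif"), .aff_num(meta$dphase))
  structure(list(transmission = aperm(tr, c(3, 1, 2)),
                 dphase = aperm(dp, c(3, 1, 2)),
                 angles = as.numeric(meta$angles),
                 phase_mask = array(FALSE, unlist(meta$dim))),
            class = "sinogram_pair")
}

#' Write / read a stepping scan
#'
#' A directory with one multi-page TIFF per projection angle (grating step
#' per page), a reference stack, and a `scan.yaml` sidecar with the
#' acquisition geometry. Counts are stored as float32.
#'
#' @param scan a [simulate_stepping()] scan.
#' @param dir output directory (created).
#' @return `dir`, invisibly (writer); a `stepping_scan` (reader).
#' @export
write_stepping_scan <- function(scan, dir) {
  stopifnot(inherits(scan, "stepping_scan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(scan$sample)
  affines <- vector("list", d[1])
  for (a in seq_len(d[1])) {
    st <- aperm(array(scan$sample[a, , , ], dim = d[2:4]), c(2, 3, 1))
    affines[[a]] <- .write_float_tiff(st, file.path(dir, sprintf("angle_%04d.tif", a)))
  }
  ref_aff <- .write_float_tiff(aperm(scan$reference, c(2, 3, 1)),
                               file.path(dir, "reference.tif"))
  g <- scan$geometry
  yaml::write_yaml(list(kind = "stepping_scan", noisy = isTRUE(scan$noisy),
                        dim = d, angles = sprintf("%.17g", scan$angles),
                        geometry = unclass(g),
                        sample_affines = lapply(affines, .aff_str),
                        reference_affine = .aff_str(ref_aff)),
                   file.path(dir, "scan.yaml"))
  invisible(dir)
}

#' @rdname write_stepping_scan
#' @export
read_stepping_scan <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "scan.yaml"))
  d <- unlist(meta$dim)
  sample <- array(0, d)
  for (a in seq_len(d[1])) {
    st <- .read_float_tiff(file.path(dir, sprintf("angle_%04d.tif", a)),
                           .aff_num(meta$sample_affines[[a]]))
    sample[a, , , ] <- aperm(st, c(3, 1, 2))
  }
  reference <- aperm(.read_float_tiff(file.path(dir, "reference.tif"),
                                      .aff_num(meta$reference_affine)),
                     c(3, 1, 2))
  if (isTRUE(meta$noisy)) {
    # Poisson counts are integral by construction; rounding undoes the
    # (sub-0.5) affine quantization of the float32 container exactly
    sample <- round(sample)
    reference <- round(reference)
  }
  g <- meta$geometry
  geometry <- acquisition_geometry(g$n_angles, g$n_steps, g$visibility,
                                   g$flux_per_step, g$phase_sensitivity,
                                   g$exposure_time, g$seed)
  structure(list(sample = sample, reference = reference, geometry = geometry,
                 angles = as.numeric(meta$angles), noisy = isTRUE(meta$noisy)),
            class = "stepping_scan")
}
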
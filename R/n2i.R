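# Noise2Inverse: angle-wise sinogram splitting, X:1 training, split-averaged
# inference, and IQA-guided epoch selection.

#' Split a sinogram into K interleaved angle subsets
#'
#' Angle `i` (0-based) goes to subset `i mod K + 1`, so every subset keeps
#' near-uniform angular coverage and subset sizes differ by at most one.
#' Because Poisson noise is independent across projections, the subsets carry
#' element-wise independent noise - the premise of Noise2Inverse.
#'
#' @param sino a [retrieve()] sinogram pair.
#' @param K number of subsets (>= 2, and at least 2 angles per subset).
#' @return list of K `sinogram_pair` objects, each carrying its
#'   `angle_indices` attribute into reconstruction provenance.
#' @export
split_sinogram <- function(sino, K) {
  stopifnot(inherits(sino, "sinogram_pair"))
  stopifnot_scalar(K, "K", min = 2, integer = TRUE)
  na <- length(sino$angles)
  if (K > na / 2) stop("K must not exceed half the number of angles")
  lapply(seq_len(K), function(j) {
    idx <- which((seq_len(na) - 1L) %% K == (j - 1L))
    sub <- structure(list(
      transmission = sino$transmission[idx, , , drop = FALSE],
      dphase = sino$dphase[idx, , , drop = FALSE],
      angles = sino$angles[idx],
      phase_mask = sino$phase_mask[idx, , , drop = FALSE]),
      class = "sinogram_pair")
    attr(sub, "angle_indices") <- idx
    sub
  })
}

#' Reconstruct the K angle subsets of a sinogram
#'
#' Convenience wrapper producing the split set the Noise2Inverse trainer
#' consumes: each interleaved subset is reconstructed independently with the
#' filter matching `signal_type`, so each member is an unbiased, noise-
#' independent estimate of the full reconstruction.
#'
#' @param sino a `sinogram_pair`.
#' @param K number of splits.
#' @param signal_type `"attenuation"` or `"electron_density"`.
#' @param phase_sensitivity geometry factor `C` (electron-density path only).
#' @param ... further arguments passed to the reconstruction.
#' @return object of class `n2i_split_set`: `K`, list of `tomograms`, their
#'   `angle_subsets`, and the parent angle count.
#' @export
reconstruct_splits <- function(sino, K,
                               signal_type = c("attenuation", "electron_density"),
                               phase_sensitivity = NULL, ...) {
  signal_type <- match.arg(signal_type)
  na <- length(sino$angles)
  subsets <- lapply(seq_len(K), function(j) which((seq_len(na) - 1L) %% K == (j - 1L)))
  if (K < 2 || K > na / 2) stop("K must be in [2, n_angles/2]")
  tomos <- lapply(subsets, function(idx) {
    if (signal_type == "attenuation") reconstruct_attenuation(sino, idx, ...)
    else reconstruct_electron_density(sino, idx,
                                      phase_sensitivity = phase_sensitivity, ...)
  })
  structure(list(K = as.integer(K), tomograms = tomos,
                 angle_subsets = subsets, n_angles = na,
                 signal_type = signal_type),
            class = "n2i_split_set")
}

#' Build X:1 (or 1:X) training pairs from a split set
#'
#' The X:1 strategy pairs, for each held-out subset `j`, the mean of all
#' other sub-reconstructions as input with subset `j` as target. The 1:X
#' variant swaps the roles; it is provided behind the same interface but is
#' not the default.
#'
#' @param splits an [reconstruct_splits()] split set.
#' @param strategy `"X:1"` (default) or `"1:X"`.
#' @return list of K `list(input, target)` pairs of slice stacks.
#' @export
make_training_pairs <- function(splits, strategy = c("X:1", "1:X")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(splits, "n2i_split_set"))
  K <- splits$K
  stacks <- lapply(splits$tomograms, function(t) t$data)
  lapply(seq_len(K), function(j) {
    rest <- Reduce(`+`, stacks[-j]) / (K - 1)
    if (strategy == "X:1") list(input = rest, target = stacks[[j]])
    else list(input = stacks[[j]], target = rest)
  })
}

#' Train the Noise2Inverse network
#'
#' Minimizes the mean squared error between `network(input)` and `target`
#' over randomly cropped square patches of the training pairs. Inputs and
#' targets are normalized by one affine map (zero mean, unit variance over
#' all pairs) that is stored with the run and inverted at inference.
#' Training is deterministic given `seed` (initialization, crop sequence and
#' pair order all draw from one seeded stream).
#'
#' @param pairs output of [make_training_pairs()].
#' @param net_config an [n2i_net_config()].
#' @param epochs training epochs (one pass over all pairs and slices each).
#' @param seed integer seed.
#' @param checkpoint_every record a parameter snapshot every this many
#'   epochs (snapshots feed [select_epoch()]); `Inf` keeps only the final.
#' @return object of class `n2i_run` with the trained `params`,
#'   normalization, `loss_history`, `checkpoints` and metadata.
#' @export
train_n2i <- function(pairs, net_config = n2i_net_config(), epochs = 100L,
                      seed = 1L, checkpoint_every = Inf) {
  stopifnot(length(pairs) >= 1L)
  stopifnot_scalar(epochs, "epochs", min = 1, integer = TRUE)
  all_in <- unlist(lapply(pairs, function(p) p$input))
  norm <- list(center = mean(all_in), scale = stats::sd(all_in))
  if (!is.finite(norm$scale) || norm$scale == 0) norm$scale <- 1
  pairs_n <- lapply(pairs, function(p) list(
    input = (as_stack(p$input) - norm$center) / norm$scale,
    target = (as_stack(p$target) - norm$center) / norm$scale))

  d <- dim(pairs_n[[1]]$input)
  ps <- min(net_config$patch_size, d[1], d[2])
  K <- length(pairs_n)
  nz <- d[3]

  with_seed(seed, {
    params <- net_init(net_config)
    state <- adam_init(params)
    loss_history <- numeric(epochs)
    checkpoints <- list()
    for (ep in seq_len(epochs)) {
      order_p <- sample(K)
      ep_loss <- 0; n_upd <- 0L
      ncrop <- net_config$crops_per_pair %||% 1L
      for (j in order_p) for (z in sample(nz)) for (cr in seq_len(ncrop)) {
        r0 <- if (d[1] > ps) sample(d[1] - ps + 1L, 1L) else 1L
        c0 <- if (d[2] > ps) sample(d[2] - ps + 1L, 1L) else 1L
        x <- pairs_n[[j]]$input[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L), z]
        y <- pairs_n[[j]]$target[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L), z]
        # shared dihedral augmentation: the noise model is isotropic, so
        # flips/rotations multiply the effective training data eightfold
        tf <- sample(0:7, 1L)
        x <- .dihedral(x, tf); y <- .dihedral(y, tf)
        fw <- net_forward(params, x, keep = TRUE)
        loss <- mean((fw$y - y)^2)
        if (!is.finite(loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d; lower the learning rate", ep))
        gr <- net_backward(params, fw, y)
        st <- adam_step(params, gr, state, net_config$lr)
        params <- st$params; state <- st$state
        ep_loss <- ep_loss + loss; n_upd <- n_upd + 1L
      }
      loss_history[ep] <- ep_loss / n_upd
      if (is.finite(checkpoint_every) && ep %% checkpoint_every == 0)
        checkpoints[[length(checkpoints) + 1L]] <-
          list(epoch = ep, params = params)
    }
  })
  if (!length(checkpoints) || checkpoints[[length(checkpoints)]]$epoch < epochs)
    checkpoints[[length(checkpoints) + 1L]] <- list(epoch = epochs, params = params)

  structure(list(params = params, net_config = net_config, norm = norm,
                 strategy = "X:1", epochs_trained = as.integer(epochs),
                 loss_history = loss_history, checkpoints = checkpoints,
                 K = length(pairs), seed = as.integer(seed)),
            class = "n2i_run")
}

#' @export
print.n2i_run <- function(x, ...) {
  cat(sprintf("n2i_run: %d epochs, K=%d, %d parameters, final loss %.3g\n",
              x$epochs_trained, x$K, net_n_params(x$net_config),
              x$loss_history[x$epochs_trained]))
  invisible(x)
}

# One of the 8 square-symmetry transforms (k in 0..7).
.dihedral <- function(m, k) {
  if (k >= 4L) m <- m[, rev(seq_len(ncol(m)))]
  for (r in seq_len(k %% 4L)) m <- t(m[rev(seq_len(nrow(m))), ])
  m
}

# Apply a parameter set to one normalized slice stack.
.predict_stack <- function(params, stack, norm) {
  out <- stack
  for (z in seq_len(dim(stack)[3])) {
    xn <- (stack[, , z] - norm$center) / norm$scale
    out[, , z] <- net_forward(params, xn) * norm$scale + norm$center
  }
  out
}

#' Denoise a split set with a trained Noise2Inverse run
#'
#' Evaluates the network on each of the K held-out input configurations
#' (mean of all subsets but `j`) and averages the K predictions, following
#' the original Noise2Inverse construction.
#'
#' @param run an [train_n2i()] run.
#' @param splits the [reconstruct_splits()] split set (same K).
#' @param params optional parameter snapshot (defaults to the final ones).
#' @return a [tomogram()] with the split set's signal type.
#' @export
denoise_n2i <- function(run, splits, params = NULL) {
  stopifnot(inherits(run, "n2i_run"), inherits(splits, "n2i_split_set"))
  if (run$K != splits$K)
    stop(sprintf("run was trained with K=%d but split set has K=%d", run$K, splits$K))
  if (is.null(params)) params <- run$params
  pairs <- make_training_pairs(splits, strategy = run$strategy)
  preds <- lapply(pairs, function(p) .predict_stack(params, as_stack(p$input), run$norm))
  avg <- Reduce(`+`, preds) / length(preds)
  tomogram(avg, splits$signal_type,
           provenance = list(filter = splits$tomograms[[1]]$provenance$filter,
                             denoiser = "noise2inverse", K = splits$K,
                             epochs = run$epochs_trained))
}

#' Select the best epoch checkpoint against a reference
#'
#' Scores every stored checkpoint's denoised output against a reference
#' tomogram with the chosen metric and returns the epoch maximizing it
#' (earliest epoch on ties) - the guard against noise overfitting.
#'
#' @param run an [train_n2i()] run with checkpoints.
#' @param splits the split set to denoise.
#' @param reference reference [tomogram()] (ground truth or high-dose scan).
#' @param metric `"psnr"` or `"ssim"`.
#' @return list with `epoch`, `metric_values` and the winning `tomogram`.
#' @export
select_epoch <- function(run, splits, reference, metric = "psnr") {
  stopifnot(inherits(reference, "tomogram"))
  if (!metric %in% c("psnr", "ssim"))
    stop(sprintf("unknown metric '%s'; use 'psnr' or 'ssim'", metric))
  vals <- vapply(run$checkpoints, function(cp) {
    den <- denoise_n2i(run, splits, params = cp$params)
    if (metric == "psnr") psnr(den$data, reference$data)
    else ssim(den$data, reference$data,
              data_range = diff(range(reference$data)))
  }, numeric(1))
  best <- which(vals == max(vals))[1]          # earliest of the tie
  list(epoch = run$checkpoints[[best]]$epoch,
       metric = metric, metric_values = vals,
       tomogram = denoise_n2i(run, splits, params = run$checkpoints[[best]]$params))
}
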
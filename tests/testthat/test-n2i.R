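with_seed_params <- function(cfg) {
  set.seed(1)
  gbpcct:::net_init(cfg)      # zero output layer => exact identity
}

make_sino <- function(n = 32L, n_angles = 64L, noise = TRUE, seed = 1L) {
  ph <- study_phantom(n, nz = 1L, seed = 2L)
  geom <- small_geometry(n_angles = n_angles, C = 12, seed = seed)
  retrieve(simulate_stepping(ph, geom, noise = noise))
}

test_that("interleaved splitting follows the i mod K rule", {
  sino <- make_sino(32L, 8L, noise = FALSE)
  sp <- split_sinogram(sino, 2L)
  expect_identical(attr(sp[[1]], "angle_indices"), c(1L, 3L, 5L, 7L))
  expect_identical(attr(sp[[2]], "angle_indices"), c(2L, 4L, 6L, 8L))
  sino9 <- make_sino(32L, 9L, noise = FALSE)
  sp9 <- split_sinogram(sino9, 4L)
  expect_identical(vapply(sp9, function(s) length(s$angles), integer(1)),
                   c(3L, 2L, 2L, 2L))
  expect_error(split_sinogram(sino, 5L), "half")
})

test_that("splits partition the angles for every K and angle count", {
  for (na in c(12L, 17L, 23L, 40L)) {
    sino <- list(transmission = array(1, c(na, 1, 4)),
                 dphase = array(0, c(na, 1, 4)),
                 angles = (seq_len(na) - 1) * pi / na,
                 phase_mask = array(FALSE, c(na, 1, 4)))
    class(sino) <- "sinogram_pair"
    for (K in 2:6) {
      if (K > na / 2) next
      sp <- split_sinogram(sino, K)
      idx <- lapply(sp, attr, "angle_indices")
      expect_identical(sort(unlist(idx)), seq_len(na))      # union, disjoint
      sizes <- lengths(idx)
      expect_lte(max(sizes) - min(sizes), 1L)
    }
  }
})

test_that("X:1 pairs hold out one subset; 1:X swaps roles", {
  sino <- make_sino(32L, 32L)
  sp <- reconstruct_splits(sino, 4L, "attenuation")
  pairs <- make_training_pairs(sp)
  expect_length(pairs, 4L)
  stacks <- lapply(sp$tomograms, function(t) t$data)
  expect_equal(pairs[[2]]$input, (stacks[[1]] + stacks[[3]] + stacks[[4]]) / 3,
               tolerance = 1e-14)
  expect_identical(pairs[[2]]$target, stacks[[2]])
  swapped <- make_training_pairs(sp, strategy = "1:X")
  expect_identical(swapped[[2]]$input, pairs[[2]]$target)
  # K = 2: the two subsets simply swap
  sp2 <- reconstruct_splits(sino, 2L, "attenuation")
  p2 <- make_training_pairs(sp2)
  expect_identical(p2[[1]]$input, p2[[2]]$target)
})

test_that("noiseless splits collapse onto the full reconstruction", {
  sino <- make_sino(32L, 128L, noise = FALSE)
  sp <- reconstruct_splits(sino, 2L, "attenuation")
  full <- reconstruct_attenuation(sino)$data
  pairs <- make_training_pairs(sp)
  # the average of inputs (and of targets) equals the full FBP exactly
  expect_equal(Reduce(`+`, lapply(pairs, `[[`, "input")) / 2, full,
               tolerance = 1e-12)
  expect_equal(Reduce(`+`, lapply(pairs, `[[`, "target")) / 2, full,
               tolerance = 1e-12)
  # each well-sampled noiseless subset reconstruction approximates it
  for (p in pairs) {
    expect_lt(sqrt(mean((p$input - full)^2)) / max(abs(full)), 0.05)
    expect_lt(sqrt(mean((p$target - full)^2)) / max(abs(full)), 0.05)
  }
})

test_that("an untrained network is the identity and denoises to the full FBP", {
  sino <- make_sino(32L, 64L)
  sp <- reconstruct_splits(sino, 2L, "attenuation")
  cfg <- n2i_net_config(channels = 4L, depth = 2L, dilations = c(1L, 2L))
  run <- structure(list(
    params = with_seed_params(cfg), net_config = cfg,
    norm = list(center = 0, scale = 1), strategy = "X:1",
    epochs_trained = 0L, loss_history = numeric(), checkpoints = list(),
    K = 2L, seed = 1L), class = "n2i_run")
  den <- denoise_n2i(run, sp)
  full <- reconstruct_attenuation(sino)$data
  expect_equal(den$data, full, tolerance = 1e-12)
  expect_identical(den$signal_type, "attenuation")
})

test_that("training is seed-deterministic", {
  sino <- make_sino(32L, 64L)
  sp <- reconstruct_splits(sino, 2L, "attenuation")
  pairs <- make_training_pairs(sp)
  cfg <- n2i_net_config(channels = 4L, depth = 2L, dilations = c(1L, 2L),
                        patch_size = 16L, crops_per_pair = 2L)
  r1 <- train_n2i(pairs, cfg, epochs = 5L, seed = 9L)
  r2 <- train_n2i(pairs, cfg, epochs = 5L, seed = 9L)
  expect_identical(r1$loss_history, r2$loss_history)
  expect_identical(r1$params, r2$params)
  r3 <- train_n2i(pairs, cfg, epochs = 5L, seed = 10L)
  expect_false(identical(r3$loss_history, r1$loss_history))
})

test_that("a net starting at the identity keeps zero loss on input==target pairs", {
  sino <- make_sino(32L, 64L, noise = FALSE)
  img <- reconstruct_attenuation(sino)$data
  pairs <- list(list(input = img, target = img),
                list(input = 2 * img, target = 2 * img))
  cfg <- n2i_net_config(channels = 4L, depth = 2L, dilations = c(1L, 2L),
                        patch_size = 16L, crops_per_pair = 2L)
  run <- train_n2i(pairs, cfg, epochs = 5L, seed = 9L)
  expect_lt(run$loss_history[5], 1e-6)
})

test_that("K mismatch between run and splits is rejected", {
  sino <- make_sino(32L, 64L)
  sp2 <- reconstruct_splits(sino, 2L, "attenuation")
  sp4 <- reconstruct_splits(sino, 4L, "attenuation")
  cfg <- n2i_net_config(channels = 4L, depth = 2L, dilations = c(1L, 2L),
                        patch_size = 16L, crops_per_pair = 1L)
  run <- train_n2i(make_training_pairs(sp2), cfg, epochs = 1L, seed = 1L)
  expect_error(denoise_n2i(run, sp4), "K=")
})

test_that("epoch selection maximizes the metric and breaks ties early", {
  sino <- make_sino(32L, 64L, seed = 3L)
  sp <- reconstruct_splits(sino, 2L, "attenuation")
  gt <- reconstruct_attenuation(make_sino(32L, 64L, noise = FALSE))
  cfg <- n2i_net_config(channels = 4L, depth = 2L, dilations = c(1L, 2L),
                        patch_size = 16L, crops_per_pair = 2L)
  run <- train_n2i(make_training_pairs(sp), cfg, epochs = 6L, seed = 2L,
                   checkpoint_every = 2L)
  sel <- select_epoch(run, sp, gt, metric = "psnr")
  expect_identical(sel$epoch,
                   run$checkpoints[[which.max(sel$metric_values)]]$epoch)
  # selected epoch is never worse than the final epoch
  expect_gte(max(sel$metric_values), sel$metric_values[length(sel$metric_values)])
  expect_error(select_epoch(run, sp, gt, metric = "sharpness"), "unknown metric")
  # single checkpoint trivially wins; exact ties return the earliest
  run1 <- run; run1$checkpoints <- run$checkpoints[3]
  expect_identical(select_epoch(run1, sp, gt)$epoch, run$checkpoints[[3]]$epoch)
  run_tie <- run
  run_tie$checkpoints <- list(list(epoch = 1L, params = run$params),
                              list(epoch = 2L, params = run$params))
  expect_identical(select_epoch(run_tie, sp, gt)$epoch, 1L)
})

test_that("self-supervised loss decomposes into ground-truth loss plus noise variance", {
  # frozen network, ensemble over Poisson realizations of one phantom
  n <- 32L
  ph <- study_phantom(n, nz = 1L, seed = 2L)
  geom <- small_geometry(n_angles = 64L, flux = 400, C = 12, seed = 1L)
  scan0 <- simulate_stepping(ph, geom, noise = FALSE)
  # per-subset clean signal: the noiseless reconstruction from subset J's
  # own angles, of which x_J is the unbiased noisy realization
  sino0 <- retrieve(scan0)
  z <- reconstruct_attenuation(sino0,
    which((seq_len(64L) - 1L) %% 2L == 0L))$data[, , 1]

  cfg <- n2i_net_config(channels = 4L, depth = 2L, dilations = c(1L, 2L),
                        patch_size = 16L, crops_per_pair = 2L)
  sp0 <- reconstruct_splits(retrieve(resample_scan(scan0, 999)), 2L, "attenuation")
  frozen <- train_n2i(make_training_pairs(sp0), cfg, epochs = 4L, seed = 5L)

  n_real <- 60L
  ss <- gt <- vv <- numeric(n_real)
  for (i in seq_len(n_real)) {
    sino_i <- retrieve(resample_scan(scan0, 2000L + i))
    sp <- reconstruct_splits(sino_i, 2L, "attenuation")
    x_J <- sp$tomograms[[1]]$data[, , 1]
    x_Jc <- sp$tomograms[[2]]$data[, , 1]
    f <- gbpcct:::.predict_stack(frozen$params, array(x_Jc, c(n, n, 1)),
                                 frozen$norm)[, , 1]
    ss[i] <- mean((f - x_J)^2)
    gt[i] <- mean((f - z)^2)
    vv[i] <- mean((z - x_J)^2)
  }
  expect_lt(abs((mean(ss) - mean(gt)) - mean(vv)) / mean(vv), 0.15)
})
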
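# Scripted study runners: the split-count experiment and the denoiser
# comparison with NPS analysis. Both write a frozen config plus CSV/TIFF
# outputs under one run directory and are bit-reproducible from their seeds.

#' Study configuration
#'
#' Collects every knob of the two scripted experiments. All randomness is
#' derived from `seed`; the dose presets are flux multipliers relative to
#' the geometry's `flux_per_step` (reference = 1231/20 of low, after the
#' measured dose ratio of the low-dose and reference scans).
#'
#' @param name experiment label.
#' @param shape phantom dimensions `c(ny, nx, n_slices)`.
#' @param phantom a [phantom_spec()].
#' @param geometry base [acquisition_geometry()] for the low-dose scan
#'   (single-sampled; the Noise2Inverse scan doubles its angles at half its
#'   flux, keeping the photon budget).
#' @param dose_presets named flux multipliers `c(low, reference)`.
#' @param K_attenuation,K_electron_density split counts per signal type.
#' @param net an [n2i_net_config()].
#' @param epochs,checkpoint_every training schedule.
#' @param ppr_radius patchwise-retrieval neighborhood radius.
#' @param blur_sigma Gaussian-blur baseline width (px).
#' @param nps_realizations ensemble size for noise-power spectra.
#' @param seed master seed.
#' @param out_dir output directory root.
#' @return object of class `run_config`.
#' @export
run_config <- function(name = "study",
                       shape = c(64L, 64L, 3L),
                       phantom = phantom_spec(),
                       geometry = acquisition_geometry(),
                       dose_presets = c(low = 1, reference = DOSE_RATIO_REFERENCE),
                       K_attenuation = 4L,
                       K_electron_density = 2L,
                       net = n2i_net_config(),
                       epochs = 100L,
                       checkpoint_every = 10L,
                       ppr_radius = 1L,
                       blur_sigma = 2,
                       nps_realizations = 12L,
                       seed = 1L,
                       out_dir = tempfile("gbpcct_run_")) {
  cfg <- structure(list(name = name, shape = shape, phantom = phantom,
                        geometry = geometry, dose_presets = dose_presets,
                        K_attenuation = as.integer(K_attenuation),
                        K_electron_density = as.integer(K_electron_density),
                        net = net, epochs = as.integer(epochs),
                        checkpoint_every = as.integer(checkpoint_every),
                        ppr_radius = as.integer(ppr_radius),
                        blur_sigma = blur_sigma,
                        nps_realizations = as.integer(nps_realizations),
                        seed = as.integer(seed), out_dir = out_dir),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Validate a study configuration
#'
#' Enumerates every problem before any computation starts.
#'
#' @param config a [run_config()].
#' @return `config`, invisibly; errors list all failures.
#' @export
validate_run_config <- function(config) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(inherits(config$phantom, "phantom_spec"), "phantom must be a phantom_spec")
  chk(inherits(config$geometry, "acquisition_geometry"),
      "geometry must be an acquisition_geometry")
  chk(inherits(config$net, "n2i_net_config"), "net must be an n2i_net_config")
  chk(length(config$shape) %in% c(2L, 3L) && all(config$shape[1:2] >= 32),
      "shape must give at least 32x32 slices")
  chk(all(c("low", "reference") %in% names(config$dose_presets)),
      "dose_presets must name 'low' and 'reference'")
  chk(config$K_attenuation >= 2, "K_attenuation must be >= 2")
  chk(config$K_electron_density >= 2, "K_electron_density must be >= 2")
  chk(config$epochs >= 1, "epochs must be >= 1")
  chk(is.numeric(config$seed) && length(config$seed) == 1L,
      "seed must be a single integer")
  if (length(problems))
    stop(paste(c("invalid run_config:", paste(" -", problems)), collapse = "\n"))
  invisible(config)
}

# Frozen-config serialization: everything needed to re-run bit-identically.
.freeze_config <- function(config, path) {
  ser <- rapply(unclass(config), function(v) {
    if (is.double(v)) stats::setNames(sprintf("%.17g", v), names(v)) else v
  }, how = "replace")
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Reload a frozen study configuration
#'
#' Reads the `config_frozen.yaml` written at the start of every experiment
#' run; re-running an experiment from the loaded config reproduces all
#' numeric outputs bit-identically (given an `out_dir`).
#'
#' @param path path to a frozen config YAML.
#' @param out_dir output directory for the re-run (default: a fresh tempdir).
#' @return a [run_config()].
#' @export
load_run_config <- function(path, out_dir = tempfile("gbpcct_rerun_")) {
  y <- yaml::read_yaml(path)
  num <- function(v) as.numeric(v)
  pair <- function(v) c(mu = num(v[[1]]), delta = num(v[[2]]))
  g <- y$geometry
  run_config(
    name = y$name,
    shape = as.integer(unlist(y$shape)),
    phantom = do.call(phantom_spec, list(
      n_regions = as.integer(y$phantom$n_regions),
      n_fibers = as.integer(y$phantom$n_fibers),
      fiber_width = as.integer(y$phantom$fiber_width),
      include_tube = isTRUE(y$phantom$include_tube),
      include_rod = isTRUE(y$phantom$include_rod),
      bath_radius_frac = num(y$phantom$bath_radius_frac),
      tube_radius_frac = num(y$phantom$tube_radius_frac),
      water = pair(y$phantom$water),
      base = pair(y$phantom$base),
      tube = pair(y$phantom$tube),
      rod = pair(y$phantom$rod),
      tissue_classes = lapply(y$phantom$tissue_classes, pair))),
    geometry = acquisition_geometry(
      n_angles = as.integer(g$n_angles), n_steps = as.integer(g$n_steps),
      visibility = num(g$visibility), flux_per_step = num(g$flux_per_step),
      phase_sensitivity = num(g$phase_sensitivity),
      exposure_time = num(g$exposure_time), seed = as.integer(g$seed)),
    dose_presets = c(low = num(y$dose_presets[[1]]),
                     reference = num(y$dose_presets[[2]])),
    K_attenuation = as.integer(y$K_attenuation),
    K_electron_density = as.integer(y$K_electron_density),
    net = n2i_net_config(
      channels = as.integer(y$net$channels), depth = as.integer(y$net$depth),
      dilations = as.integer(unlist(y$net$dilations)),
      patch_size = as.integer(y$net$patch_size),
      crops_per_pair = as.integer(y$net$crops_per_pair), lr = num(y$net$lr)),
    epochs = as.integer(y$epochs),
    checkpoint_every = as.integer(y$checkpoint_every),
    ppr_radius = as.integer(y$ppr_radius),
    blur_sigma = num(y$blur_sigma),
    nps_realizations = as.integer(y$nps_realizations),
    seed = as.integer(y$seed),
    out_dir = out_dir)
}

# Common front end: phantom + noiseless ground truth + scans.
.study_inputs <- function(config, oversample = TRUE) {
  geom <- config$geometry
  if (oversample) {
    geom$n_angles <- 2L * geom$n_angles
    geom$flux_per_step <- geom$flux_per_step / 2   # photon budget conserved
  }
  geom$flux_per_step <- geom$flux_per_step * config$dose_presets[["low"]]
  geom$seed <- config$seed
  phantom <- make_phantom(config$shape, config$phantom, seed = config$seed + 1L)
  sino0 <- retrieve(simulate_stepping(phantom, geom, noise = FALSE))
  gt <- list(
    attenuation = reconstruct_attenuation(sino0),
    electron_density = reconstruct_electron_density(
      sino0, phase_sensitivity = geom$phase_sensitivity))
  scan <- simulate_stepping(phantom, geom, noise = TRUE)
  list(phantom = phantom, geometry = geom, scan = scan,
       sino = retrieve(scan), sino0 = sino0, gt = gt)
}

.n2i_for_signal <- function(config, sino, signal_type, gt, K, train_seed) {
  C <- config$geometry$phase_sensitivity
  splits <- reconstruct_splits(sino, K, signal_type, phase_sensitivity = C)
  run <- train_n2i(make_training_pairs(splits), config$net,
                   epochs = config$epochs, seed = train_seed,
                   checkpoint_every = config$checkpoint_every)
  sel <- select_epoch(run, splits, gt, metric = "psnr")
  list(run = run, splits = splits, selection = sel, tomogram = sel$tomogram)
}

#' Split-count experiment
#'
#' The first study: a double-sampled low-dose scan (twice the base angles at
#' half the flux) is split into K = 2 and K = 4 subsets for each signal
#' type; each Noise2Inverse model is trained and epoch-selected against the
#' noiseless ground truth, and scored with the full IQA suite. Emits
#' `iqa_summary.csv` (2 signals x 2 split counts x 4 metrics), per-case
#' difference images, and the frozen config.
#'
#' @param config a [run_config()].
#' @param dry_run validate and print the execution plan without computing.
#' @return list with the summary table, reports and output paths
#'   (invisibly `NULL` for dry runs).
#' @export
run_split_experiment <- function(config = run_config(), dry_run = FALSE) {
  validate_run_config(config)
  if (dry_run) {
    cat("split experiment plan:\n")
    cat(sprintf("  phantom %s, %d+%d angle double-sampled scan, flux %g/step\n",
                paste(config$shape, collapse = "x"),
                config$geometry$n_angles, config$geometry$n_angles,
                config$geometry$flux_per_step / 2))
    cat(sprintf("  K in {2, 4} x {attenuation, electron_density}, %d epochs\n",
                config$epochs))
    cat(sprintf("  outputs under %s\n", config$out_dir))
    return(invisible(NULL))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  .freeze_config(config, file.path(config$out_dir, "config_frozen.yaml"))
  inp <- .study_inputs(config, oversample = TRUE)

  rows <- list()
  reports <- list()
  for (signal in c("attenuation", "electron_density")) {
    for (K in c(2L, 4L)) {
      res <- .n2i_for_signal(config, inp$sino, signal, inp$gt[[signal]], K,
                             train_seed = config$seed + 10L * K +
                               (signal == "electron_density"))
      rep <- assess_stack(res$tomogram, inp$gt[[signal]])
      tag <- sprintf("%s_K%d", signal, K)
      reports[[tag]] <- rep
      write_iqa_report(rep, file.path(config$out_dir, sprintf("iqa_%s.csv", tag)))
      diff <- res$tomogram
      diff$data <- diff$data - inp$gt[[signal]]$data
      write_tomogram(diff, file.path(config$out_dir, sprintf("diff_%s.tif", tag)))
      for (m in rep$summary$metric) {
        rows[[length(rows) + 1L]] <- data.frame(
          signal_type = signal, K = K, metric = m,
          mean = rep$summary$mean[rep$summary$metric == m],
          sd = rep$summary$sd[rep$summary$metric == m])
      }
    }
  }
  summary <- do.call(rbind, rows)
  .write_table(summary, file.path(config$out_dir, "iqa_summary.csv"))
  invisible(list(summary = summary, reports = reports, out_dir = config$out_dir))
}

#' Denoiser comparison experiment
#'
#' The second study: a low-dose scan is processed with plain FBP, patchwise
#' phase retrieval, Gaussian blur (sigma from the background ROI estimate
#' times the configured width), Noise2Inverse (per-signal default split
#' count on the double-sampled, equal-dose scan), and any available external
#' adapters; every method is scored against the reconstruction of a
#' high-flux reference scan (flux ratio `dose_presets["reference"]`).
#' Noise-power-spectrum curves of empty-beam reconstructions are emitted for
#' FBP, blur and Noise2Inverse. Missing external backends are logged and
#' skipped, never fatal.
#'
#' @param config a [run_config()].
#' @param methods methods to run (subset of `c("fbp", "ppr", "gaussian",
#'   "n2i", "bm3d_external", "sir_external")`).
#' @param with_nps compute the NPS comparison (the slowest stage).
#' @return list with the per-signal IQA tables, NPS curves and paths.
#' @export
run_comparison_experiment <- function(config = run_config(),
                                      methods = c("fbp", "ppr", "gaussian", "n2i"),
                                      with_nps = TRUE) {
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  .freeze_config(config, file.path(config$out_dir, "config_frozen.yaml"))
  C <- config$geometry$phase_sensitivity

  # low-dose scan (single-sampled) and high-dose reference measurement
  inp <- .study_inputs(config, oversample = FALSE)
  geom_ref <- inp$geometry
  geom_ref$flux_per_step <- config$geometry$flux_per_step *
    config$dose_presets[["reference"]]
  geom_ref$seed <- config$seed + 500L
  sino_ref <- retrieve(simulate_stepping(inp$phantom, geom_ref, noise = TRUE))
  reference <- list(
    attenuation = reconstruct_attenuation(sino_ref),
    electron_density = reconstruct_electron_density(sino_ref, phase_sensitivity = C))

  recon_for <- function(sino, signal)
    if (signal == "attenuation") reconstruct_attenuation(sino)
    else reconstruct_electron_density(sino, phase_sensitivity = C)

  rows <- list(); tomos <- list()
  for (signal in c("attenuation", "electron_density")) {
    fbp <- recon_for(inp$sino, signal)
    for (method in methods) {
      tomo <- switch(method,
        fbp = fbp,
        ppr = recon_for(retrieve_patchwise(inp$scan, radius = config$ppr_radius),
                        signal),
        gaussian = gaussian_blur(fbp, config$blur_sigma),
        n2i = {
          # equal-dose double-sampled scan, per the acquisition protocol
          cfg2 <- config
          res <- .n2i_for_signal(cfg2, .study_inputs(cfg2, oversample = TRUE)$sino,
                                 signal, reference[[signal]],
                                 K = if (signal == "attenuation")
                                   config$K_attenuation else config$K_electron_density,
                                 train_seed = config$seed + 77L +
                                   (signal == "electron_density"))
          res$tomogram
        },
        bm3d_external = ,
        sir_external = {
          if (!external_backend_available(method)) {
            message(sprintf("backend '%s' unavailable; skipped", method))
            next
          }
          roi <- c(2L, 2L, 9L, 9L)
          run_external(fbp, denoiser_spec(method,
            params = list(sigma_noise = estimate_background_sigma(fbp, roi))))
        })
      rep <- assess_stack(tomo, reference[[signal]])
      tag <- sprintf("%s_%s", signal, method)
      tomos[[tag]] <- write_tomogram(tomo,
        file.path(config$out_dir, sprintf("tomo_%s.tif", tag)))
      write_iqa_report(rep, file.path(config$out_dir, sprintf("iqa_%s.csv", tag)))
      for (m in rep$summary$metric)
        rows[[length(rows) + 1L]] <- data.frame(
          signal_type = signal, method = method, metric = m,
          mean = rep$summary$mean[rep$summary$metric == m],
          sd = rep$summary$sd[rep$summary$metric == m])
    }
  }
  summary <- do.call(rbind, rows)
  .write_table(summary, file.path(config$out_dir, "iqa_summary.csv"))

  nps_curves <- NULL
  if (with_nps) {
    nps_curves <- nps_comparison(inp$geometry, config, config$seed + 900L)
    for (nm in names(nps_curves)) {
      cv <- nps_curves[[nm]]
      .write_table(data.frame(k = cv$k, power = cv$power, weight = cv$weight),
                   file.path(config$out_dir, sprintf("nps_%s.csv", nm)))
    }
  }
  invisible(list(summary = summary, nps = nps_curves, tomograms = tomos,
                 out_dir = config$out_dir))
}

#' Noise-power-spectrum comparison of FBP, blur and Noise2Inverse
#'
#' Reconstructs ensembles of empty-beam noise for both signal types and
#' derives radial NPS curves for the plain FBP, its Gaussian-blurred
#' version, and Noise2Inverse trained on one noise realization's splits
#' (the no-sample analogue of the paper protocol's training-on-itself).
#'
#' @param geometry the (low-dose) [acquisition_geometry()].
#' @param config a [run_config()] (net, epochs, blur sigma, ensemble size).
#' @param seed ensemble seed.
#' @return named list of `nps_curve` objects
#'   (`<signal>_<fbp|blur|n2i>`).
#' @export
nps_comparison <- function(geometry, config, seed = 1L) {
  n <- config$shape[2]
  out <- list()
  for (signal in c("attenuation", "electron_density")) {
    ens <- noise_only_tomograms(geometry, signal,
                                n_realizations = config$nps_realizations,
                                seed = seed, shape = c(1L, n))
    out[[paste0(signal, "_fbp")]] <- nps_radial(ens)
    blurred <- lapply(ens, gaussian_blur, sigma = config$blur_sigma)
    out[[paste0(signal, "_blur")]] <- nps_radial(blurred)

    # N2I trained on the first realization's own splits, then applied to all
    g1 <- geometry; g1$seed <- as.integer(seed + 5000L)
    scan1 <- simulate_flat_scan(g1, c(1L, n), noise = TRUE)
    sino1 <- retrieve(scan1)
    K <- if (signal == "attenuation") config$K_attenuation else config$K_electron_density
    splits <- reconstruct_splits(sino1, K, signal,
                                 phase_sensitivity = geometry$phase_sensitivity)
    run <- train_n2i(make_training_pairs(splits), config$net,
                     epochs = config$epochs, seed = seed + 31L)
    den <- lapply(ens, function(img)
      .predict_stack(run$params, as_stack(img), run$norm)[, , 1])
    out[[paste0(signal, "_n2i")]] <- nps_radial(den)
  }
  out
}

.write_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
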
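# Quantitative validation harness: SSIM scoring against noise-free
# sectioned ground truth, missing-cone OTF analysis, the SSIM-vs-noise
# sweep over the Poisson factor eta, and the moving-sample benchmark.

#' Structural similarity (SSIM) between a reconstruction and ground truth
#'
#' Standard SSIM with a Gaussian weighting window (sigma 1.5, 11 x 11
#' taps) and population statistics. Both images are percentile-normalised
#' (1st/99th) before scoring, and the dynamic range is taken from the
#' normalised ground truth, so reconstructions on arbitrary intensity
#' scales are comparable. The local map is cropped by the window radius
#' before averaging. Two constant images score ~1 under this luminance
#' normalisation (both map to flat zero): a documented edge case.
#'
#' @param x Reconstruction (matrix).
#' @param gt Ground truth (matrix, same shape): the noise-free in-focus
#'   plane blurred with the in-focus PSF.
#' @param normalize Percentile-normalise both inputs first (default TRUE).
#' @param sigma Gaussian window standard deviation in pixels.
#' @return Scalar in (-1, 1]; 1 for identical images.
#' @export
ssim_score <- function(x, gt, normalize = TRUE, sigma = 1.5) {
  if (!all(dim(x) == dim(gt))) stop("images must share shape")
  if (normalize) {
    x <- percentile_norm(x)
    gt <- percentile_norm(gt)
  }
  L <- diff(range(gt))
  if (L <= 0) L <- 1
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  r <- as.integer(3.5 * sigma + 0.5)
  blur <- function(im) gauss_blur_nearest(im, sigma, r)
  mx <- blur(x); my <- blur(gt)
  vx <- blur(x * x) - mx^2
  vy <- blur(gt * gt) - my^2
  cxy <- blur(x * gt) - mx * my
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  ny <- nrow(s); nx2 <- ncol(s)
  if (ny <= 2 * r || nx2 <= 2 * r) return(mean(s))
  mean(s[(r + 1):(ny - r), (r + 1):(nx2 - r)])
}

#' Missing-cone fill ratio of a reconstruction
#'
#' Compares the axial-frequency content of a reconstructed point-source
#' volume with the corresponding widefield volume. The widefield OTF has
#' no support on the kz axis away from DC (the missing cone); a sectioning
#' reconstruction restores it. Both magnitude spectra are DC-normalised and
#' the spectral energy is summed on a one-pixel-radius tube around
#' kx = ky = 0, excluding the kz = 0 plane.
#'
#' @param recon_vol Reconstructed volume, array `c(ny, nx, nz)`.
#' @param widefield_vol Widefield volume of the same point-source scene.
#' @return Ratio (> 1 means axial information was recovered).
#' @export
otf_cone_fill <- function(recon_vol, widefield_vol) {
  if (length(recon_vol) == 0 || length(widefield_vol) == 0) {
    stop("volumes must be nonempty")
  }
  axial_energy <- function(vol) {
    a <- Mod(fft(vol))
    a <- a / a[1, 1, 1]
    d <- dim(a)
    iy <- c(1L, 2L, d[1])  # bin distance <= 1 from DC
    ix <- c(1L, 2L, d[2])
    tube <- rbind(cbind(iy, 1L), cbind(1L, ix[-1]))  # radius-1 cross
    e <- 0
    for (k in 2:d[3]) {
      e <- e + sum(a[cbind(tube[, 1], tube[, 2], k)]^2)
    }
    e
  }
  axial_energy(recon_vol) / axial_energy(widefield_vol)
}

# per-plane sectioned ground truth: each phantom plane blurred with the
# in-focus 2D PSF (no out-of-focus cross-talk) -- the "ideal confocal" image
sectioned_ground_truth <- function(phantom, config, psf_lateral = 49) {
  vol <- if (inherits(phantom, "os_phantom")) phantom$vol else phantom
  odd <- function(n) if (n %% 2 == 0) n - 1L else n
  side <- min(odd(dim(vol)[1]), odd(dim(vol)[2]), psf_lateral)
  psf2 <- defocused_psf_plane(config, c(side, side), 0)
  k3 <- array(psf2, c(dim(psf2), 1))
  conv_centered(vol, k3, k_center = c((side + 1) / 2, (side + 1) / 2, 1))
}

mip <- function(vol, n_slices = NULL) {
  nz <- dim(vol)[3]
  if (is.null(n_slices) || n_slices >= nz) {
    zs <- seq_len(nz)
  } else {
    lo <- floor((nz - n_slices) / 2) + 1
    zs <- lo:(lo + n_slices - 1)
  }
  apply(vol[, , zs, drop = FALSE], c(1, 2), max)
}

recon_volume_by_method <- function(stack, method, est, models = list()) {
  if (method %in% names(models)) {
    return(reconstruct_ml(models[[method]], stack))
  }
  switch(method,
    widefield = widefield_estimate(stack),
    sd = sd_reconstruction(stack),
    corrected = corrected_sd(stack, est),
    filtered = hilo_filtered(stack, phases = est),
    stop("unknown method: ", method))
}

#' SSIM-versus-noise sweep over the Poisson factor
#'
#' The simulation benchmark for reconstruction robustness: a filament-mesh
#' volume is imaged through the striped-illumination volume simulator, the
#' Gaussian + Poisson noise model is applied over a grid of Poisson factors
#' `eta`, each method reconstructs every focal plane, and the maximum
#' intensity projection (default 50 slices) is scored with [ssim_score()]
#' against the noise-free sectioned projection. The noise-free simulation
#' is shared across the `eta` grid, so the sweep isolates the effect of
#' the photon budget.
#'
#' @param eta_grid Poisson factors to test (any order; results are sorted).
#' @param methods Character vector among `"widefield"`, `"sd"`,
#'   `"corrected"`, `"filtered"`, plus any names in `models`.
#' @param n_replicates Independent phantoms per `eta`.
#' @param seed Master seed: phantoms and noise draw from named substreams.
#' @param config,pattern Optics and pattern (defaults: the 600 nm / NA 1.2
#'   / 86 nm voxel reference optics and its optimal pattern frequency).
#' @param shape Phantom voxel counts `c(nz, ny, nx)`.
#' @param n_filaments,thickness_voxels Phantom density parameters.
#' @param mip_slices Slices in the maximum intensity projection.
#' @param gaussian_sigma Fixed Gaussian noise level (photon units).
#' @param models Named list of trained models to include as methods.
#' @return A tibble of class `os_sweep` with one row per
#'   (method, eta, replicate) and columns `method`, `eta`, `replicate`,
#'   `ssim`; sweep parameters and seeds are stored in attributes so the
#'   experiment can be rerun bit-exactly.
#' @seealso [sharp_drop_eta()], [autoplot.os_sweep()]
#' @export
noise_sweep <- function(eta_grid,
                        methods = c("widefield", "sd", "corrected", "filtered"),
                        n_replicates = 5, seed = 1,
                        config = optical_config(1.2, 600, 488, 1.33, 86),
                        pattern = NULL,
                        shape = c(60, 96, 96), n_filaments = 15,
                        thickness_voxels = 2, mip_slices = 50,
                        gaussian_sigma = 1, models = list()) {
  if (is.null(pattern)) {
    pattern <- sinusoidal_pattern(optimal_pattern_frequency(config),
                                  orientation = 0.3, modulation = 0.9)
  }
  eta_grid <- sort(eta_grid)
  rows <- list()
  for (rep_i in seq_len(n_replicates)) {
    ph <- generate_filament_mesh(shape, n_filaments, thickness_voxels,
                                 seed = derive_seed(seed, paste0("phantom", rep_i)),
                                 voxel_nm = config$voxel_nm[1])
    clean <- simulate_volume_scan(ph, config, pattern)
    gt <- mip(sectioned_ground_truth(ph, config), mip_slices)
    for (eta in eta_grid) {
      noisy <- add_noise(clean, noise_model(eta, gaussian_sigma),
                         seed = derive_seed(seed, paste0("noise", rep_i, "_", eta)))
      # the pattern is estimated from the noisy data, as a real pipeline
      # must: estimation collapse at low signal is part of each method's
      # noise response (the stack's configured pattern is the documented
      # fallback when no stripe peak survives)
      est <- suppressWarnings(estimate_pattern_parameters(noisy))
      for (m in methods) {
        rec <- recon_volume_by_method(noisy, m, est, models)
        rows[[length(rows) + 1]] <- tibble::tibble(
          method = m, eta = eta, replicate = rep_i,
          ssim = ssim_score(mip(rec, mip_slices), gt))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "params") <- list(seed = seed, shape = shape,
                              n_filaments = n_filaments,
                              thickness_voxels = thickness_voxels,
                              mip_slices = mip_slices,
                              gaussian_sigma = gaussian_sigma,
                              eta_grid = eta_grid,
                              pattern = pattern, config = config)
  class(out) <- c("os_sweep", class(out))
  out
}

#' Locate the sharp performance drop of each method
#'
#' Operationalises "sharp drop in performance at eta": on the sorted `eta`
#' grid, finds for each method the interval between adjacent grid points
#' with the largest decrease in mean SSIM (going from the brighter to the
#' dimmer point) and reports the dimmer endpoint — the signal level at
#' which performance has collapsed.
#'
#' @param sweep An `os_sweep` from [noise_sweep()].
#' @return Tibble with columns `method`, `drop_eta`, `drop_size`.
#' @export
sharp_drop_eta <- function(sweep) {
  means <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(sweep),
                                            .data$method, .data$eta),
                            ssim = mean(.data$ssim), .groups = "drop")
  do.call(rbind, lapply(split(means, means$method), function(d) {
    d <- d[order(d$eta), ]
    drops <- d$ssim[-1] - d$ssim[-nrow(d)]  # positive = loss when dimming
    i <- which.max(drops)
    tibble::tibble(method = d$method[1], drop_eta = d$eta[i],
                   drop_size = drops[i])
  })) -> res
  tibble::as_tibble(res)
}

#' Moving-sample reconstruction benchmark
#'
#' Simulates OS-SIM acquisition of scenes that move between the three
#' phase frames ([generate_moving_triplet()]), reconstructs each scene with
#' every method, and scores against the ideal sectioned image of the
#' second frame. Subtractive methods develop shadowing/striping artefacts
#' on moving structure, which the stripe-artefact metric (Fourier
#' amplitude at the pattern frequency relative to DC) quantifies.
#'
#' @param n_scenes Number of simulated scenes (default 8).
#' @param max_displacement Per-frame object displacement bound, pixels.
#' @param eta Poisson factor of the added noise.
#' @param seed Master seed.
#' @param methods Classical method names; trained models come via `models`.
#' @param models Named list of trained models (e.g. `list(vsr = fit)`).
#' @param config Optics (default: reference optics).
#' @param pattern Pattern (default: optimal frequency, orientation 0.3).
#' @param shape Scene shape `c(ny, nx)`.
#' @param n_objects Moving objects per scene.
#' @param oof_weight Weight of the out-of-focus background plane.
#' @param gaussian_sigma Gaussian noise level (photon units).
#' @return A tibble of class `os_motion`: one row per (method, scene) with
#'   `ssim` and `stripe_ratio`; parameters in attributes.
#' @export
motion_benchmark <- function(n_scenes = 8, max_displacement = 2, eta = 1e-4,
                             seed = 1,
                             methods = c("widefield", "sd", "corrected",
                                         "filtered"),
                             models = list(),
                             config = optical_config(1.2, 600, 488, 1.33, 86),
                             pattern = NULL, shape = c(64, 64), n_objects = 5,
                             oof_weight = 0.5, gaussian_sigma = 1) {
  if (is.null(pattern)) {
    pattern <- sinusoidal_pattern(optimal_pattern_frequency(config),
                                  orientation = 0.3, modulation = 0.9)
  }
  psf_in <- defocused_psf_plane(config, c(33, 33), 0)
  psf_out <- defocused_psf_plane(config, c(33, 33), 1500)
  rows <- list()
  for (sc in seq_len(n_scenes)) {
    trip <- generate_moving_triplet(shape, n_objects, max_displacement,
                                    seed = derive_seed(seed, paste0("scene", sc)))
    oof <- generate_texture(shape, derive_seed(seed, paste0("oof", sc)), "blobs")
    stack <- simulate_stack(trip$frames, psf_in, pattern, out_of_focus = oof,
                            psf_out = psf_out, oof_weight = oof_weight,
                            pixel_size_nm = config$voxel_nm[3], config = config)
    noisy <- add_noise(stack, noise_model(eta, gaussian_sigma),
                       seed = derive_seed(seed, paste0("mnoise", sc)))
    gt <- conv2_centered(trip$frames[[2]], psf_in)
    est <- tryCatch(suppressWarnings(estimate_pattern_parameters(noisy)),
                    error = function(e) NULL)
    if (is.null(est)) est <- pattern$phase_offsets
    for (m in c(methods, names(models))) {
      rec <- recon_volume_by_method(noisy, m, est, models)
      sa <- stripe_amplitude(rec, pattern$frequency, pattern$orientation,
                             config$voxel_nm[3])
      rows[[length(rows) + 1]] <- tibble::tibble(
        method = m, scene = sc, ssim = ssim_score(rec, gt),
        stripe_ratio = sa$ratio)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "params") <- list(seed = seed, n_scenes = n_scenes,
                              max_displacement = max_displacement, eta = eta,
                              shape = shape, n_objects = n_objects,
                              oof_weight = oof_weight,
                              gaussian_sigma = gaussian_sigma,
                              pattern = pattern, config = config)
  class(out) <- c("os_motion", class(out))
  out
}

# --- tidy/plot methods -----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Summarise a noise sweep
#'
#' @param x An `os_sweep`.
#' @param ... Unused.
#' @return Tibble with per-(method, eta) mean and standard deviation of
#'   SSIM and the replicate count.
#' @exportS3Method generics::tidy
tidy.os_sweep <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$method, .data$eta),
                   mean_ssim = mean(.data$ssim),
                   sd_ssim = stats::sd(.data$ssim),
                   n = dplyr::n(), .groups = "drop")
}

#' Summarise a motion benchmark
#'
#' @param x An `os_motion`.
#' @param ... Unused.
#' @return Tibble with per-method mean/sd SSIM and mean stripe ratio.
#' @exportS3Method generics::tidy
tidy.os_motion <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$method),
                   mean_ssim = mean(.data$ssim),
                   sd_ssim = stats::sd(.data$ssim),
                   mean_stripe_ratio = mean(.data$stripe_ratio),
                   n = dplyr::n(), .groups = "drop")
}

#' Per-epoch training history of a trained model
#'
#' @param x An `os_trained_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `loss_fn`.
#' @exportS3Method generics::tidy
tidy.os_trained_model <- function(x, ...) x$history

#' One-row summary of a trained model
#'
#' @param x An `os_trained_model`.
#' @param ... Unused.
#' @return Tibble with parameter count, epochs, initial/final loss and
#'   divergence flag.
#' @exportS3Method generics::glance
glance.os_trained_model <- function(x, ...) {
  tibble::tibble(kind = x$model$kind,
                 n_parameters = count_parameters(x$model),
                 epochs = nrow(x$history),
                 initial_loss = x$history$loss[1],
                 final_loss = utils::tail(x$history$loss, 1),
                 diverged = x$diverged)
}

#' Plot a noise sweep
#'
#' Mean SSIM (with +/- one standard deviation ribbons) against the Poisson
#' factor on a log axis, one line per reconstruction method.
#'
#' @param object An `os_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.os_sweep <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$eta, y = .data$mean_ssim,
                                  colour = .data$method, fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_ssim - .data$sd_ssim,
                                      ymax = .data$mean_ssim + .data$sd_ssim),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(paste("Poisson factor ", eta)),
                  y = "SSIM vs noise-free sectioned GT",
                  colour = "method", fill = "method") +
    ggplot2::theme_minimal()
}

#' Plot a motion benchmark
#'
#' Per-method mean SSIM with standard-deviation error bars across scenes.
#'
#' @param object An `os_motion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.os_motion <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$mean_ssim)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_ssim - .data$sd_ssim,
                                        ymax = .data$mean_ssim + .data$sd_ssim),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "SSIM vs sectioned GT (second frame)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
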
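# Classical subtractive OS-SIM reconstructions: widefield estimate,
# squared-difference (SD) demodulation, phase-corrected SD for uneven phase
# steps, and HiLo-style high-pass/low-pass fusion with stripe suppression.

phase_frames <- function(stack) {
  stopifnot(inherits(stack, "os_stack"))
  if (dim(stack$frames)[3] != 3) stop("stack must contain exactly 3 phase frames")
  stack$frames
}

# Reconstructions operate plane-wise; 2D stacks return a matrix, volumetric
# stacks an array (ny, nx, nz).
drop_z <- function(vol) if (dim(vol)[3] == 1) vol[, , 1] else vol

# collapse the singleton phase axis of a (ny, nx, 1, nz) slice
squeeze_phase <- function(a) {
  d <- dim(a)
  dim(a) <- d[c(1, 2, 4)]
  a
}

#' Widefield estimate from a phase-stepped stack
#'
#' Per-pixel arithmetic mean of the three phase frames. Because the three
#' phase offsets average to uniform illumination, this equals the image the
#' microscope would record under unstructured excitation (up to the factor
#' 1/2 from the pattern's mean).
#'
#' @param stack An [os_stack()].
#' @return Matrix (or `c(ny, nx, nz)` array for volumetric stacks).
#' @export
widefield_estimate <- function(stack) {
  f <- phase_frames(stack)
  drop_z(squeeze_phase(f[, , 1, , drop = FALSE] + f[, , 2, , drop = FALSE] +
                         f[, , 3, , drop = FALSE]) / 3)
}

#' Squared-difference (SD) reconstruction
#'
#' The classical three-phase demodulation
#' `I_R = sqrt((I1 - I2)^2 + (I2 - I3)^2 + (I1 - I3)^2)`.
#' For an ideally phase-stepped sinusoid of local mean `B` and modulation
#' `m` the output is the constant `sqrt(4.5) * B * m`, independent of the
#' local stripe phase, so in-focus (modulated) structure is extracted and
#' unmodulated background cancels. The pairwise differences amplify noise,
#' which is this method's known weakness at low photon counts.
#'
#' @param stack An [os_stack()].
#' @return Matrix (or array for volumetric stacks), nonnegative.
#' @export
sd_reconstruction <- function(stack) {
  f <- phase_frames(stack)
  i1 <- f[, , 1, , drop = FALSE]; i2 <- f[, , 2, , drop = FALSE]
  i3 <- f[, , 3, , drop = FALSE]
  out <- sqrt((i1 - i2)^2 + (i2 - i3)^2 + (i1 - i3)^2)
  drop_z(squeeze_phase(out))
}

# tan-half-angle weights for the corrected SD combination; errors on
# degenerate phase triples.
corrected_sd_weights <- function(phi) {
  stopifnot(length(phi) == 3)
  d12 <- phi[1] - phi[2]; d23 <- phi[2] - phi[3]; d31 <- phi[3] - phi[1]
  wrap <- function(x) atan2(sin(x), cos(x))
  pairs <- list(c(1, 2), c(2, 3), c(3, 1))
  for (i in seq_along(pairs)) {
    d <- c(d12, d23, d31)[i]
    if (abs(abs(wrap(d)) - pi) < 1e-3) {
      stop("degenerate phases: |phi", pairs[[i]][1], " - phi", pairs[[i]][2],
           "| is within 1e-3 of the tan pole at pi")
    }
    if (abs(wrap(d)) < 1e-3) {
      stop("degenerate phases: phi", pairs[[i]][1], " and phi", pairs[[i]][2],
           " coincide (no phase diversity)")
    }
  }
  t23 <- tan(d23 / 2); t31 <- tan(d31 / 2)
  denom <- sin(d23 / 2) * sin(d31 / 2) * (t31 + t23)
  if (abs(denom) < 1e-8) {
    stop("degenerate phases: quadrature weight is singular for phases ",
         paste(round(phi, 4), collapse = ", "))
  }
  # (I1-I2)^2 + (w Q)^2 = 4 A^2 sin^2(d12/2) for stripe amplitude A; the
  # prefactor rescales the output to sqrt(4.5) * A, plain SD's scale at
  # ideal phase steps, for every non-degenerate phase triple.
  list(t23 = t23, t31 = t31, w = sin(d12 / 2) / denom,
       prefactor = sqrt(4.5) / (2 * abs(sin(d12 / 2))))
}

#' Phase-corrected squared-difference reconstruction
#'
#' Generalises [sd_reconstruction()] to uneven phase steps. With measured
#' pattern phases `phi_1..3`, the difference `I1 - I2` and the tan-half-angle
#' weighted combination
#' `Q = (I2 - I3) tan((phi3 - phi1)/2) + (I1 - I3) tan((phi2 - phi3)/2)`
#' form (after scaling `Q` by a phase-dependent quadrature weight `w`) two
#' signals exactly in quadrature in the local stripe phase:
#' `(I1 - I2)^2 + (w Q)^2 = 4 A^2 sin^2((phi1 - phi2)/2)` for local stripe
#' amplitude `A`, independent of the stripe's spatial phase. The
#' reconstruction is this root rescaled to `sqrt(4.5) * A`, the scale of
#' plain SD at ideal phase steps, so the two methods coincide for ideal
#' steps and the corrected method stays constant under phase-step errors
#' that leave plain SD striped.
#'
#' @param stack An [os_stack()].
#' @param phases A numeric length-3 vector of pattern phases (radians), an
#'   `os_pattern_estimate` from [estimate_pattern_parameters()], or `NULL`
#'   to estimate them from the stack.
#' @return Matrix (or array for volumetric stacks), nonnegative.
#' @export
corrected_sd <- function(stack, phases = NULL) {
  f <- phase_frames(stack)
  if (is.null(phases)) phases <- estimate_pattern_parameters(stack)
  phi <- if (inherits(phases, "os_pattern_estimate")) phases$phases else phases
  if (any(!is.finite(phi))) stop("phases must be finite")
  wts <- corrected_sd_weights(phi)
  i1 <- f[, , 1, , drop = FALSE]; i2 <- f[, , 2, , drop = FALSE]
  i3 <- f[, , 3, , drop = FALSE]
  q <- (i2 - i3) * wts$t31 + (i1 - i3) * wts$t23
  out <- wts$prefactor * sqrt((i1 - i2)^2 + (wts$w * q)^2)
  drop_z(squeeze_phase(out))
}

#' Estimate pattern parameters from a raw stack
#'
#' Recovers the illumination pattern from the data: the stripe frequency
#' and orientation from the dominant non-DC peak of the mean power
#' spectrum (refined to sub-bin precision by maximising the continuous
#' Fourier magnitude), the per-frame pattern phases from the complex
#' argument of each frame's Fourier coefficient at that frequency, and a
#' modulation-depth estimate from the peak-to-DC amplitude ratio. Only
#' phase differences between frames are meaningful.
#'
#' @param stack An [os_stack()] containing a detectable stripe component.
#'   For volumetric stacks the central plane is used.
#' @param dc_exclude_bins Radius (in frequency bins) of the DC region
#'   excluded from the peak search.
#' @param min_peak_snr Minimum ratio of peak power to the median non-DC
#'   power; below this the estimate is flagged low-confidence and the
#'   stack's configured pattern (if any) is returned instead.
#' @return An object of class `os_pattern_estimate` with fields
#'   `frequency` (cycles/um), `orientation` (rad), `phases` (length 3,
#'   rad, reported modulo 2pi), `modulation` and `low_confidence`.
#' @export
estimate_pattern_parameters <- function(stack, dc_exclude_bins = 3,
                                        min_peak_snr = 10, max_planes = 16) {
  f <- phase_frames(stack)
  nz <- n_z(stack)
  zs <- unique(round(seq(1, nz, length.out = min(nz, max_planes))))
  ny <- dim(f)[1]; nx <- dim(f)[2]
  px <- stack$pixel_size_nm / 1000
  # static object content cancels in the pairwise frame differences, leaving
  # only the phase-stepped carrier (and noise): far more robust than
  # searching the raw spectrum, whose low-frequency object power can dwarf
  # the stripe. Volumetric stacks average the difference spectra over
  # planes, since the lateral carrier is shared by all focal positions.
  diffs <- list()
  for (z in zs) {
    diffs <- c(diffs, list(f[, , 1, z] - f[, , 2, z],
                           f[, , 2, z] - f[, , 3, z],
                           f[, , 3, z] - f[, , 1, z]))
  }
  p <- Reduce(`+`, lapply(diffs, function(im) Mod(fft(im - mean(im)))^2)) /
    length(diffs)
  fx <- fft_freq(nx, px); fy <- fft_freq(ny, px)
  bin_r <- sqrt(outer((fy / fy[2])^2, (fx / fx[2])^2, `+`))
  mask <- bin_r >= dc_exclude_bins
  med <- stats::median(p[mask])
  peak_idx <- which(p == max(p[mask]) & mask, arr.ind = TRUE)[1, ]
  snr <- p[peak_idx[1], peak_idx[2]] / max(med, .Machine$double.xmin)
  if (snr < min_peak_snr) {
    if (!is.null(stack$pattern)) {
      warning("no stripe peak above the noise floor; falling back to the ",
              "stack's configured pattern (low confidence)")
      pat <- stack$pattern
      return(structure(list(frequency = pat$frequency,
                            orientation = pat$orientation,
                            phases = pat$phase_offsets %% (2 * pi),
                            modulation = pat$modulation,
                            low_confidence = TRUE),
                       class = "os_pattern_estimate"))
    }
    stop("no stripe peak above the noise floor and no configured pattern ",
         "to fall back to")
  }
  f0 <- c(fx[peak_idx[2]], fy[peak_idx[1]])
  score <- function(fv) {
    -sum(vapply(diffs, function(im) Mod(dtft_point(im, fv[1], fv[2], px))^2,
                numeric(1)))
  }
  opt <- stats::optim(f0, score, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 400,
                                     parscale = c(fx[2], fy[2])))
  fv <- opt$par
  # canonical half-plane: fx > 0 (or fy > 0 on the fx = 0 line)
  if (fv[1] < 0 || (abs(fv[1]) < 1e-9 && fv[2] < 0)) fv <- -fv
  peaks <- vapply(1:3, function(n) {
    sum(vapply(zs, function(z) dtft_point(f[, , n, z], fv[1], fv[2], px),
               complex(1)))
  }, complex(1)) / length(zs)
  dcs <- vapply(1:3, function(n) mean(f[, , n, zs]), numeric(1))
  structure(list(frequency = sqrt(sum(fv^2)),
                 orientation = atan2(fv[2], fv[1]),
                 phases = (Arg(peaks)) %% (2 * pi),
                 modulation = min(1, 2 * mean(Mod(peaks)) / max(mean(dcs), 1e-12)),
                 low_confidence = FALSE),
            class = "os_pattern_estimate")
}

#' @export
print.os_pattern_estimate <- function(x, ...) {
  cat("<os_pattern_estimate> nu =", round(x$frequency, 4), "cycles/um, theta =",
      round(x$orientation, 4), "rad, phases =",
      paste(round(x$phases, 3), collapse = ", "),
      ", m =", round(x$modulation, 3),
      if (isTRUE(x$low_confidence)) "(LOW CONFIDENCE)" else "", "\n")
  invisible(x)
}

#' HiLo filtering parameters
#'
#' @param alpha Mixing weight in `[0, 1]` between high-pass widefield
#'   content (`alpha`) and low-pass sectioned content (`1 - alpha`).
#' @param filter_cutoff Gaussian filter cutoff in cycles/um; high-pass and
#'   low-pass are complementary (`HP = 1 - LP`).
#' @param notch_width Width (cycles/um) of the annular stripe-suppression
#'   notch centred on the pattern frequency.
#' @return An object of class `os_hilo_params`.
#' @export
hilo_params <- function(alpha, filter_cutoff, notch_width) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (filter_cutoff <= 0 || notch_width <= 0) stop("cutoffs must be positive")
  structure(list(alpha = alpha, filter_cutoff = filter_cutoff,
                 notch_width = notch_width),
            class = "os_hilo_params")
}

radial_freq_grid <- function(ny, nx, px) {
  fx <- fft_freq(nx, px); fy <- fft_freq(ny, px)
  sqrt(outer(fy^2, fx^2, `+`))
}

gaussian_lowpass <- function(img, cutoff, pixel_size_nm) {
  fr <- radial_freq_grid(nrow(img), ncol(img), pixel_size_nm / 1000)
  Re(fft(fft(img) * exp(-fr^2 / (2 * cutoff^2)), inverse = TRUE)) / length(img)
}

#' Annular stripe-suppression notch filter
#'
#' Attenuates spatial frequencies near the pattern frequency with a
#' Gaussian annular notch `1 - exp(-(|k| - nu_p)^2 / (2 width^2))`,
#' removing residual stripe artefacts from a reconstruction.
#'
#' @param img Image matrix.
#' @param frequency Pattern frequency, cycles/um.
#' @param width Notch width, cycles/um.
#' @param pixel_size_nm Pixel pitch in nanometres.
#' @return Filtered image.
#' @export
notch_filter <- function(img, frequency, width, pixel_size_nm = 86) {
  fr <- radial_freq_grid(nrow(img), ncol(img), pixel_size_nm / 1000)
  gain <- 1 - exp(-(fr - frequency)^2 / (2 * width^2))
  Re(fft(fft(img) * gain, inverse = TRUE)) / length(img)
}

#' HiLo-filtered SD reconstruction
#'
#' Fuses the high-spatial-frequency content of the widefield estimate with
#' the low-frequency content of the phase-corrected SD reconstruction,
#' `alpha * HP(widefield) + (1 - alpha) * LP(corrected SD)`, then applies
#' the stripe-suppression [notch_filter()] at the pattern frequency. The
#' low-pass sectioned image supplies background rejection while the less
#' noisy widefield image supplies fine detail, mitigating SD noise
#' amplification. `HP` and `LP` are complementary Gaussian frequency
#' filters.
#'
#' Defaults follow the pattern estimate: `filter_cutoff` is half the
#' estimated pattern frequency, `notch_width` a tenth of it, and `alpha`
#' is the estimated modulation depth clipped to `[0.1, 0.9]`.
#'
#' @param stack An [os_stack()].
#' @param params An [hilo_params()] or `NULL` for the defaults above.
#' @param phases Pattern estimate passed to [corrected_sd()]; `NULL`
#'   estimates it from the stack.
#' @return Matrix (or array for volumetric stacks), clipped at zero.
#' @export
hilo_filtered <- function(stack, params = NULL, phases = NULL) {
  if (is.null(phases)) phases <- estimate_pattern_parameters(stack)
  freq <- if (inherits(phases, "os_pattern_estimate")) phases$frequency
          else stack$pattern$frequency
  if (is.null(params)) {
    m <- if (inherits(phases, "os_pattern_estimate")) phases$modulation else 0.5
    params <- hilo_params(alpha = min(0.9, max(0.1, m)),
                          filter_cutoff = freq / 2, notch_width = 0.1 * freq)
  }
  stopifnot(inherits(params, "os_hilo_params"))
  wf <- widefield_estimate(stack)
  csd <- corrected_sd(stack, phases)
  one_plane <- function(wf2, csd2) {
    lp_wf <- gaussian_lowpass(wf2, params$filter_cutoff, stack$pixel_size_nm)
    hp_wf <- wf2 - lp_wf
    lp_sd <- gaussian_lowpass(csd2, params$filter_cutoff, stack$pixel_size_nm)
    fused <- params$alpha * hp_wf + (1 - params$alpha) * lp_sd
    clip0(notch_filter(fused, freq, params$notch_width, stack$pixel_size_nm))
  }
  if (is.matrix(wf)) return(one_plane(wf, csd))
  out <- array(0, dim(wf))
  for (z in seq_len(dim(wf)[3])) out[, , z] <- one_plane(wf[, , z], csd[, , z])
  out
}

#' Reconstruct a stack with a named method
#'
#' Convenience dispatcher over the classical reconstructions (and trained
#' models via [reconstruct_ml()]), returning the image together with its
#' provenance.
#'
#' @param stack An [os_stack()].
#' @param method One of `"widefield"`, `"sd"`, `"corrected"`, `"filtered"`,
#'   or a trained model object from [train_network()].
#' @param ... Passed to the underlying method (`phases`, `params`, ...).
#' @return An object of class `os_recon`: list with `image` (matrix or
#'   array), `method`, `params` and `pattern_estimate` (when one was
#'   computed).
#' @export
reconstruct <- function(stack, method = "sd", ...) {
  est <- NULL
  if (is.character(method)) {
    method <- match.arg(method, c("widefield", "sd", "corrected", "filtered"))
    img <- switch(method,
      widefield = widefield_estimate(stack),
      sd = sd_reconstruction(stack),
      corrected = {
        est <- estimate_pattern_parameters(stack)
        corrected_sd(stack, est, ...)
      },
      filtered = {
        est <- estimate_pattern_parameters(stack)
        hilo_filtered(stack, phases = est, ...)
      })
    name <- method
  } else {
    img <- reconstruct_ml(method, stack, ...)
    name <- paste0("ml-", method$kind %||% "model")
  }
  structure(list(image = img, method = name, params = list(...),
                 pattern_estimate = est),
            class = "os_recon")
}

#' @export
print.os_recon <- function(x, ...) {
  d <- dim(x$image)
  cat("<os_recon>", x$method, ":", paste(d, collapse = " x "), "\n")
  invisible(x)
}
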
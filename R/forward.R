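#' Raw OS-SIM stack container
#'
#' Holds the raw phase-stepped frames together with the provenance needed to
#' reconstruct them: the illumination pattern, optics, noise model (if any)
#' and pixel pitch. Frames are stored as an array of dimension
#' `c(ny, nx, 3, nz)`; purely 2D acquisitions have `nz = 1`.
#'
#' @param frames Array `c(ny, nx, 3)` or `c(ny, nx, 3, nz)`, nonnegative.
#' @param pattern The [sinusoidal_pattern()] used (or `NULL` if unknown).
#' @param optics The [optical_config()] used (or `NULL`).
#' @param noise The [noise_model()] applied (or `NULL` for noise-free).
#' @param pixel_size_nm Lateral pixel pitch in nanometres.
#' @param meta Free-form provenance list (seeds, weights, generator values).
#' @return An object of class `os_stack`.
#' @export
os_stack <- function(frames, pattern = NULL, optics = NULL, noise = NULL,
                     pixel_size_nm = 86, meta = list()) {
  if (length(dim(frames)) == 3) dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 4 || dim(frames)[3] != 3) {
    stop("frames must have dimension c(ny, nx, 3[, nz]): exactly 3 phase frames")
  }
  if (any(frames < 0)) stop("raw frames must be nonnegative")
  structure(list(frames = frames, pattern = pattern, optics = optics,
                 noise = noise, pixel_size_nm = pixel_size_nm, meta = meta),
            class = "os_stack")
}

#' @export
print.os_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("<os_stack>", d[1], "x", d[2], "px, 3 phases,", d[4], "z plane(s);",
      if (is.null(x$noise)) "noise-free" else
        paste0("noisy (eta = ", format(x$noise$eta), ")"), "\n")
  invisible(x)
}

n_z <- function(stack) dim(stack$frames)[4]

#' Gaussian + Poisson camera noise model
#'
#' The signal level is parameterised by the Poisson factor `eta`: before
#' sampling, the noise-free stack is normalised so its maximum equals
#' `peak_intensity_norm` (default `1e-6`), and each pixel's photon
#' expectation is `value * eta * photon_scale`. With the defaults the peak
#' expected photon count is `eta * 1e6`: 100 photons at `eta = 1e-4`, 20 at
#' `2e-5`, 5 at `5e-6` — a low-photon regime where reconstruction noise
#' amplification matters. Gaussian read-like noise of standard deviation
#' `gaussian_sigma` (photon-equivalent units) is added after Poisson
#' sampling and the result is clipped at zero.
#'
#' @param eta Poisson signal factor (> 0); lower values mean fewer photons.
#' @param gaussian_sigma Gaussian noise standard deviation in
#'   photon-equivalent units; fixed across `eta` by default.
#' @param photon_scale Fixed photon conversion scale (`1e12`).
#' @param peak_intensity_norm Normalisation constant for the stack peak
#'   before Poisson sampling (`1e-6`).
#' @return An object of class `os_noise_model`.
#' @export
noise_model <- function(eta, gaussian_sigma = 1, photon_scale = 1e12,
                        peak_intensity_norm = 1e-6) {
  if (!is.finite(eta) || eta <= 0) stop("Poisson factor eta must be positive")
  if (gaussian_sigma < 0) stop("gaussian_sigma must be nonnegative")
  structure(list(eta = eta, gaussian_sigma = gaussian_sigma,
                 photon_scale = photon_scale,
                 peak_intensity_norm = peak_intensity_norm),
            class = "os_noise_model")
}

#' Simulate a noise-free two-plane OS-SIM acquisition
#'
#' Image formation for one focal plane: the in-focus structure (and
#' optionally a second, out-of-focus plane) is multiplied by each phase of
#' the striped excitation, blurred by the corresponding PSF, and the two
#' planes are merged by weighted addition:
#' `frame_n = blur(in_focus * P_n, psf_in) +
#'  oof_weight * blur(out_of_focus * P_n', psf_out)`
#' where `P_n'` is the same pattern with its modulation depth scaled by the
#' defocus envelope (out-of-focus structure sees almost unmodulated light,
#' which is what makes subtractive sectioning possible).
#'
#' For moving-sample simulations `in_focus` may be a list of three frames
#' (one per phase step), e.g. from [generate_moving_triplet()].
#'
#' @param in_focus Matrix, or list of 3 matrices (video mode).
#' @param psf_in In-focus 2D PSF kernel (odd-sized, sums to 1), e.g. from
#'   [defocused_psf_plane()] with zero defocus.
#' @param pattern An [sinusoidal_pattern()].
#' @param out_of_focus Optional background plane (same shape).
#' @param psf_out Out-of-focus 2D PSF kernel; required when `out_of_focus`
#'   is given.
#' @param oof_weight Nonnegative weight of the out-of-focus plane.
#' @param oof_modulation_factor Factor in `[0, 1]` multiplying the pattern
#'   modulation seen by the out-of-focus plane. Default `NULL` computes it
#'   with [modulation_envelope()] from `config` and the `defocus_nm`
#'   attribute of `psf_out` when available, and otherwise uses 0 (a deeply
#'   defocused plane is effectively uniformly illuminated).
#' @param pixel_size_nm Lateral pixel pitch in nanometres.
#' @param config Optional [optical_config()] recorded in the stack and used
#'   for the defocus envelope.
#' @return A noise-free [os_stack()].
#' @export
simulate_stack <- function(in_focus, psf_in, pattern, out_of_focus = NULL,
                           psf_out = NULL, oof_weight = 0,
                           oof_modulation_factor = NULL,
                           pixel_size_nm = 86, config = NULL) {
  stopifnot(inherits(pattern, "os_pattern"), oof_weight >= 0)
  frames_in <- if (is.list(in_focus)) in_focus else list(in_focus, in_focus, in_focus)
  if (inherits(in_focus, "os_triplet")) frames_in <- in_focus$frames
  if (length(frames_in) != 3) stop("video-mode input must supply exactly 3 frames")
  shp <- dim(frames_in[[1]])
  for (f in frames_in) if (!all(dim(f) == shp)) stop("all in-focus frames must share shape")
  if (!is.null(out_of_focus) && !all(dim(out_of_focus) == shp)) {
    stop("in_focus and out_of_focus must share shape")
  }
  if (!is.null(out_of_focus) && is.null(psf_out)) {
    stop("psf_out is required when out_of_focus is given")
  }
  if (is.null(oof_modulation_factor)) {
    dz <- attr(psf_out, "defocus_nm")
    oof_modulation_factor <-
      if (!is.null(config) && !is.null(dz)) modulation_envelope(dz, config) else 0
  }
  oof_pattern <- pattern
  oof_pattern$modulation <- pattern$modulation * oof_modulation_factor
  out <- array(0, c(shp, 3))
  for (n in 1:3) {
    pn <- render_pattern(pattern, shp, n, pixel_size_nm)
    frame <- conv2_centered(frames_in[[n]] * pn, psf_in)
    if (!is.null(out_of_focus)) {
      pn_oof <- render_pattern(oof_pattern, shp, n, pixel_size_nm)
      frame <- frame + oof_weight * conv2_centered(out_of_focus * pn_oof, psf_out)
    }
    out[, , n] <- frame
  }
  os_stack(clip0(out), pattern = pattern, optics = config,
           pixel_size_nm = pixel_size_nm,
           meta = list(oof_weight = oof_weight,
                       oof_modulation_factor = oof_modulation_factor,
                       video = is.list(in_focus) || inherits(in_focus, "os_triplet")))
}

#' Simulate a volumetric OS-SIM scan of a 3D phantom
#'
#' For every focal position the phantom is multiplied by the 3D excitation
#' pattern focused there — stripes whose modulation depth decays axially
#' with [modulation_envelope()] — and the fluorescent response is blurred by
#' the full 3D widefield PSF; the camera samples the focal plane. Writing
#' the pattern as DC plus a modulated carrier, the whole scan reduces to
#' four 3D convolutions (one widefield term shared by all phases plus one
#' carrier term per phase, the carrier kernel being the PSF weighted by the
#' axial envelope), which is how it is computed here.
#'
#' @param phantom An `os_phantom` (or plain `c(ny, nx, nz)` array).
#' @param config An [optical_config()]; its voxel size must match the
#'   phantom's.
#' @param pattern An [sinusoidal_pattern()].
#' @param noise Optional [noise_model()] applied via [add_noise()].
#' @param seed Seed for the noise (required when `noise` is given).
#' @param psf_shape Optional `c(nz, ny, nx)` for the PSF kernel; default is
#'   a 49 x 49 lateral kernel and an axial extent covering +/- ~1.7 um.
#' @return An [os_stack()] with a z axis (`frames` dim `c(ny, nx, 3, nz)`).
#' @export
simulate_volume_scan <- function(phantom, config, pattern, noise = NULL,
                                 seed = NULL, psf_shape = NULL) {
  vol <- if (inherits(phantom, "os_phantom")) phantom$vol else phantom
  stopifnot(inherits(config, "os_optics"), inherits(pattern, "os_pattern"))
  if (inherits(phantom, "os_phantom") &&
      !isTRUE(all.equal(phantom$voxel_nm, config$voxel_nm[1]))) {
    stop("phantom voxel size does not match the optical configuration")
  }
  d <- dim(vol)  # (ny, nx, nz)
  if (is.null(psf_shape)) {
    odd <- function(n) if (n %% 2 == 0) n - 1L else n
    psf_shape <- c(min(odd(d[3]), 41L), min(odd(d[1]), 49L), min(odd(d[2]), 49L))
  }
  psf <- compute_psf(config, psf_shape)
  dz <- config$voxel_nm[1]
  z_off <- (seq_len(dim(psf$vol)[3]) - psf$focus_index) * dz
  env <- modulation_envelope(z_off, config)
  psf_mod <- sweep(psf$vol, 3, env, `*`)
  px <- config$voxel_nm[3]
  # z-independent carrier grids, one per phase
  xs <- (seq_len(d[2]) - 1) * px / 1000
  ys <- (seq_len(d[1]) - 1) * px / 1000
  base_arg <- 2 * pi * pattern$frequency *
    outer(ys * sin(pattern$orientation), xs * cos(pattern$orientation), `+`)
  wf <- conv_centered(vol, psf$vol,
                      k_center = c(floor(psf_shape[2] / 2) + 1,
                                   floor(psf_shape[3] / 2) + 1, psf$focus_index))
  frames <- array(0, c(d[1], d[2], 3, d[3]))
  for (n in 1:3) {
    carrier <- cos(base_arg + pattern$phase_offsets[n])
    g <- vol * as.vector(carrier)  # broadcast over z (column-major)
    s <- conv_centered(g, psf_mod,
                       k_center = c(floor(psf_shape[2] / 2) + 1,
                                    floor(psf_shape[3] / 2) + 1, psf$focus_index))
    frames[, , n, ] <- (wf + pattern$modulation * s) / 2
  }
  stack <- os_stack(clip0(frames), pattern = pattern, optics = config,
                    pixel_size_nm = px,
                    meta = list(phantom_params =
                                  if (inherits(phantom, "os_phantom")) phantom$params,
                                psf_shape = psf_shape))
  if (!is.null(noise)) stack <- add_noise(stack, noise, seed)
  stack
}

#' Apply the Gaussian + Poisson noise model to a stack
#'
#' Normalises the stack so its maximum equals the model's
#' `peak_intensity_norm`, replaces each value `v` by
#' `Poisson(v * eta * photon_scale) + Normal(0, gaussian_sigma)` and clips
#' at zero. Output frames are in photon-equivalent units. Reproducible from
#' the seed.
#'
#' @param stack A noise-free [os_stack()].
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return A noisy [os_stack()] (with `noise` recorded; the normalisation
#'   factor is stored in `meta$photon_per_input`).
#' @export
add_noise <- function(stack, noise, seed = 1) {
  stopifnot(inherits(stack, "os_stack"), inherits(noise, "os_noise_model"))
  if (!is.null(stack$noise)) warning("stack already carries noise; adding more")
  peak <- max(stack$frames)
  if (peak <= 0) stop("cannot add noise to an all-zero stack")
  scale <- noise$peak_intensity_norm / peak * noise$eta * noise$photon_scale
  lambda <- stack$frames * scale
  noisy <- with_local_seed(seed, {
    v <- stats::rpois(length(lambda), lambda) +
      stats::rnorm(length(lambda), 0, noise$gaussian_sigma)
    array(v, dim(lambda))
  })
  out <- stack
  out$frames <- clip0(noisy)
  out$noise <- noise
  out$meta$photon_per_input <- scale
  out$meta$noise_seed <- seed
  out
}

#' Configuration of the randomised training-example generator
#'
#' Parameter ranges from which [make_training_example()] draws: each
#' two-element numeric is a `c(min, max)` range sampled uniformly
#' (log-uniformly for `eta`). Randomising optics and pattern makes trained
#' models generalise across microscopes and imaging conditions.
#'
#' @param shape `c(ny, nx)` of the generated images.
#' @param pixel_size_nm Pixel pitch in nanometres.
#' @param pattern_frequency Range, cycles/um.
#' @param orientation Range, radians.
#' @param modulation Range of stripe modulation depth.
#' @param na Range of numerical aperture.
#' @param lambda_em_nm,lambda_ex_nm,ri Fixed optics values.
#' @param oof_weight Range of out-of-focus mixing weight.
#' @param defocus_nm Range of the out-of-focus plane's defocus.
#' @param eta Range of the Poisson factor (sampled log-uniformly).
#' @param gaussian_sigma Fixed Gaussian noise level (photon units).
#' @param mode `"static"` (single in-focus image) or `"video"` (three-frame
#'   moving scene, the mode used for motion-robust training).
#' @param max_displacement Range of per-frame object displacement (video
#'   mode), pixels.
#' @param texture_kinds Texture kinds to draw in-focus/out-of-focus
#'   structure from (see [generate_texture()]).
#' @param psf_size Odd lateral size of the 2D PSF kernels.
#' @return An object of class `os_generator_config`.
#' @export
training_generator_config <- function(shape = c(64, 64), pixel_size_nm = 86,
                                      pattern_frequency = c(1.6, 2.6),
                                      orientation = c(0, 2 * pi),
                                      modulation = c(0.6, 1),
                                      na = c(1.0, 1.3),
                                      lambda_em_nm = 600, lambda_ex_nm = 488,
                                      ri = 1.33,
                                      oof_weight = c(0.2, 1),
                                      defocus_nm = c(1000, 2500),
                                      eta = c(5e-6, 2e-4),
                                      gaussian_sigma = 1,
                                      mode = c("static", "video"),
                                      max_displacement = c(0, 3),
                                      texture_kinds = c("multiscale-noise",
                                                        "blobs", "filaments-2d"),
                                      psf_size = 33) {
  mode <- match.arg(mode)
  for (rng in list(pattern_frequency, orientation, modulation, na, oof_weight,
                   defocus_nm, eta, max_displacement)) {
    if (length(rng) != 2 || any(!is.finite(rng)) || rng[2] < rng[1]) {
      stop("parameter ranges must be finite c(min, max) with max >= min")
    }
  }
  if (length(texture_kinds) < 1) stop("texture_kinds must be nonempty")
  structure(list(shape = shape, pixel_size_nm = pixel_size_nm,
                 pattern_frequency = pattern_frequency, orientation = orientation,
                 modulation = modulation, na = na,
                 lambda_em_nm = lambda_em_nm, lambda_ex_nm = lambda_ex_nm, ri = ri,
                 oof_weight = oof_weight, defocus_nm = defocus_nm, eta = eta,
                 gaussian_sigma = gaussian_sigma, mode = mode,
                 max_displacement = max_displacement,
                 texture_kinds = texture_kinds, psf_size = psf_size),
            class = "os_generator_config")
}

runif1 <- function(rng) stats::runif(1, rng[1], rng[2])

#' Draw one randomised training example
#'
#' Samples all simulation parameters uniformly from the generator config's
#' ranges, builds a phase-stepped stack with [simulate_stack()] (in video
#' mode the three in-focus planes come from a [generate_moving_triplet()]
#' scene) and applies [add_noise()]. The supervised target is the
#' diffraction-limited sectioned image: the in-focus plane (the second
#' frame, in video mode) convolved with the drawn in-focus PSF.
#'
#' @param gen A [training_generator_config()].
#' @param seed Integer seed; the example is a pure function of
#'   `(gen, seed)`.
#' @return A list of class `os_training_example` with `input` (noisy
#'   [os_stack()]), `target` (matrix) and `params` (all drawn values and
#'   component seeds, sufficient to regenerate the example bit-exactly).
#' @export
make_training_example <- function(gen, seed = 1) {
  stopifnot(inherits(gen, "os_generator_config"))
  params <- with_local_seed(derive_seed(seed, "params"), {
    list(frequency = runif1(gen$pattern_frequency),
         orientation = runif1(gen$orientation),
         modulation = runif1(gen$modulation),
         na = runif1(gen$na),
         oof_weight = runif1(gen$oof_weight),
         defocus_nm = runif1(gen$defocus_nm),
         eta = exp(runif1(log(gen$eta))),
         max_displacement = runif1(gen$max_displacement),
         kind_in = sample(gen$texture_kinds, 1),
         kind_out = sample(gen$texture_kinds, 1))
  })
  params$seed <- seed
  params$texture_seed_in <- derive_seed(seed, "texture_in")
  params$texture_seed_out <- derive_seed(seed, "texture_out")
  params$noise_seed <- derive_seed(seed, "noise")
  cfg <- optical_config(params$na, gen$lambda_em_nm, gen$lambda_ex_nm, gen$ri,
                        gen$pixel_size_nm)
  pat <- sinusoidal_pattern(params$frequency, params$orientation, params$modulation)
  psf_in <- defocused_psf_plane(cfg, c(gen$psf_size, gen$psf_size), 0)
  psf_out <- defocused_psf_plane(cfg, c(gen$psf_size, gen$psf_size),
                                 params$defocus_nm)
  oof <- generate_texture(gen$shape, params$texture_seed_out, params$kind_out)
  if (gen$mode == "video") {
    trip <- generate_moving_triplet(gen$shape, n_objects = 6,
                                    max_displacement = params$max_displacement,
                                    seed = params$texture_seed_in)
    in_focus <- trip$frames
    gt_plane <- trip$frames[[2]]
  } else {
    in_focus <- generate_texture(gen$shape, params$texture_seed_in, params$kind_in)
    gt_plane <- in_focus
  }
  stack <- simulate_stack(in_focus, psf_in, pat, out_of_focus = oof,
                          psf_out = psf_out, oof_weight = params$oof_weight,
                          oof_modulation_factor =
                            modulation_envelope(params$defocus_nm, cfg),
                          pixel_size_nm = gen$pixel_size_nm, config = cfg)
  noisy <- add_noise(stack, noise_model(params$eta, gen$gaussian_sigma),
                     params$noise_seed)
  target <- conv2_centered(gt_plane, psf_in)
  structure(list(input = noisy, target = target, params = params, mode = gen$mode),
            class = "os_training_example")
}
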
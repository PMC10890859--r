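#' Optical configuration for an OS-SIM microscope
#'
#' Bundles the parameters that determine the point spread function (PSF),
#' optical transfer function (OTF) and the optimal striped-illumination
#' frequency: objective numerical aperture, emission and excitation
#' wavelengths, immersion refractive index, and the voxel pitch of the
#' acquisition grid.
#'
#' @param na Numerical aperture of the objective (dimensionless, must be
#'   strictly smaller than `ri`).
#' @param lambda_em_nm Emission wavelength in nanometres.
#' @param lambda_ex_nm Excitation wavelength in nanometres.
#' @param ri Refractive index of the immersion/sample medium.
#' @param voxel_nm Voxel pitch in nanometres, length-3 numeric `c(z, y, x)`
#'   or a scalar for isotropic voxels.
#'
#' @return An object of class `os_optics`.
#' @examples
#' cfg <- optical_config(na = 1.2, lambda_em_nm = 600, lambda_ex_nm = 488,
#'                       ri = 1.33, voxel_nm = 86)
#' optimal_pattern_frequency(cfg)
#' @export
optical_config <- function(na, lambda_em_nm, lambda_ex_nm = lambda_em_nm,
                           ri = 1.33, voxel_nm = 86) {
  if (length(voxel_nm) == 1) voxel_nm <- rep(voxel_nm, 3)
  stopifnot(length(voxel_nm) == 3)
  if (!is.finite(na) || na <= 0) stop("numerical aperture must be positive")
  if (na >= ri) {
    stop("invalid optics: numerical aperture (", na,
         ") must be smaller than the refractive index (", ri, ")")
  }
  if (any(c(lambda_em_nm, lambda_ex_nm) <= 0)) stop("wavelengths must be positive")
  if (any(voxel_nm <= 0)) stop("voxel sizes must be positive")
  structure(
    list(na = na, lambda_em_nm = lambda_em_nm, lambda_ex_nm = lambda_ex_nm,
         ri = ri, voxel_nm = voxel_nm),
    class = "os_optics"
  )
}

#' @export
print.os_optics <- function(x, ...) {
  cat("<os_optics> NA =", x$na, " lambda_em =", x$lambda_em_nm,
      "nm  lambda_ex =", x$lambda_ex_nm, "nm  n =", x$ri,
      " voxel(z,y,x) =", paste(x$voxel_nm, collapse = "x"), "nm\n")
  invisible(x)
}

# Scalar Born-Wolf amplitude on one defocus plane, evaluated by Simpson
# quadrature over the normalised aperture radius. `radii_nm` is a vector of
# lateral distances from the optical axis, `z_nm` the defocus.
born_wolf_amplitude <- function(radii_nm, z_nm, na, lambda_nm, ri, n_rho = 101) {
  k <- 2 * pi / lambda_nm
  rho <- seq(0, 1, length.out = n_rho)
  # Simpson weights (n_rho odd)
  w <- rep(c(4, 2), length.out = n_rho)
  w[1] <- 1; w[n_rho] <- 1
  w <- w * (rho[2] - rho[1]) / 3
  defocus <- exp(-0.5i * k * rho^2 * z_nm * na^2 / ri)
  weights <- w * defocus * rho
  j0 <- besselJ(outer(radii_nm, rho) * (k * na), 0)
  as.vector(j0 %*% weights)
}

#' Compute a 3D point spread function (Born-Wolf model)
#'
#' Evaluates the scalar Born-Wolf defocus integral by numerical quadrature
#' over the aperture, producing a diffraction-limited widefield PSF sampled
#' on the configured voxel grid. The result is normalised to unit total
#' intensity and has its focal plane at the volume's central z index (for an
#' even z count, at index `floor(nz / 2) + 1`).
#'
#' @param config An [optical_config()] object.
#' @param shape Integer vector `c(nz, ny, nx)` of voxel counts. `ny` and `nx`
#'   must be odd so the focus falls on a grid point.
#'
#' @return An object of class `os_psf`: a list with `vol` (array of dim
#'   `c(ny, nx, nz)`, nonnegative, summing to 1), `voxel_nm`, and
#'   `focus_index` (z index of the focal plane).
#' @seealso [compute_otf()], [defocused_psf_plane()]
#' @export
compute_psf <- function(config, shape) {
  stopifnot(inherits(config, "os_optics"), length(shape) == 3)
  nz <- as.integer(shape[1]); ny <- as.integer(shape[2]); nx <- as.integer(shape[3])
  if (ny %% 2 == 0 || nx %% 2 == 0) {
    stop("ny and nx must be odd so that the focus is a grid point")
  }
  dz <- config$voxel_nm[1]; dy <- config$voxel_nm[2]; dx <- config$voxel_nm[3]
  airy_r1 <- 0.61 * config$lambda_em_nm / config$na
  if (((min(ny, nx) - 1) / 2) * min(dy, dx) < airy_r1) {
    warning("PSF grid smaller than the first Airy ring (",
            round(airy_r1), " nm); the PSF will be truncated")
  }
  cz <- floor(nz / 2) + 1L
  ys <- (seq_len(ny) - (floor(ny / 2) + 1)) * dy
  xs <- (seq_len(nx) - (floor(nx / 2) + 1)) * dx
  r <- sqrt(outer(ys^2, xs^2, `+`))
  ru <- sort(unique(as.vector(r)))
  ridx <- match(r, ru)
  vol <- array(0, c(ny, nx, nz))
  for (iz in seq_len(nz)) {
    z <- (iz - cz) * dz
    amp <- born_wolf_amplitude(ru, z, config$na, config$lambda_em_nm, config$ri)
    inten <- Mod(amp)^2
    vol[, , iz] <- matrix(inten[ridx], ny, nx)
  }
  vol <- vol / sum(vol)
  structure(list(vol = vol, voxel_nm = config$voxel_nm, focus_index = cz,
                 config = config),
            class = "os_psf")
}

#' Single defocused PSF plane for two-plane (2D) simulations
#'
#' Evaluates the Born-Wolf intensity on one z plane at the given defocus and
#' normalises it to unit sum: a defocused planar structure contributes the
#' same integrated intensity as an in-focus one, only blurred.
#'
#' @param config An [optical_config()] object.
#' @param shape_yx `c(ny, nx)`, both odd.
#' @param defocus_nm Defocus distance in nanometres (0 for the in-focus
#'   plane; default 1500 nm for a typical out-of-focus background plane).
#' @return A `ny` x `nx` matrix summing to 1, with attribute `defocus_nm`.
#' @export
defocused_psf_plane <- function(config, shape_yx, defocus_nm = 1500) {
  stopifnot(inherits(config, "os_optics"), length(shape_yx) == 2)
  ny <- as.integer(shape_yx[1]); nx <- as.integer(shape_yx[2])
  if (ny %% 2 == 0 || nx %% 2 == 0) stop("ny and nx must be odd")
  dy <- config$voxel_nm[2]; dx <- config$voxel_nm[3]
  ys <- (seq_len(ny) - (floor(ny / 2) + 1)) * dy
  xs <- (seq_len(nx) - (floor(nx / 2) + 1)) * dx
  r <- sqrt(outer(ys^2, xs^2, `+`))
  ru <- sort(unique(as.vector(r)))
  amp <- born_wolf_amplitude(ru, defocus_nm, config$na, config$lambda_em_nm, config$ri)
  img <- matrix((Mod(amp)^2)[match(r, ru)], ny, nx)
  img <- img / sum(img)
  attr(img, "defocus_nm") <- defocus_nm
  img
}

#' Compute the optical transfer function of a PSF
#'
#' Discrete Fourier transform of the PSF volume (focus rolled to the origin
#' so the spectrum's phase is that of a centred PSF), normalised to unity at
#' DC. For a real PSF the spectrum is Hermitian-symmetric; for a widefield
#' PSF its support is the classical double-cone region with the missing cone
#' of axial frequencies around the kz axis.
#'
#' @param psf An `os_psf` object (or a plain 3D array with attribute
#'   handling left to the caller).
#' @return An object of class `os_otf`: list with `spectrum` (complex array,
#'   dim `c(ny, nx, nz)` in FFT layout, DC at `[1,1,1]`) and `freq_step_um`
#'   (cycles/um per index step along y, x, z).
#' @export
compute_otf <- function(psf) {
  stopifnot(inherits(psf, "os_psf"))
  vol <- psf$vol
  s <- sum(vol)
  if (abs(s - 1) > 1e-6) {
    warning("PSF is not normalised (sum = ", format(s), "); rescaling")
    vol <- vol / s
  }
  d <- dim(vol)
  center <- c(floor(d[1] / 2) + 1, floor(d[2] / 2) + 1, psf$focus_index)
  spec <- fft(ifftshift_to_origin(vol, center))
  spec <- spec / Re(spec[1, 1, 1])
  step <- 1000 / (d * psf$voxel_nm[c(2, 3, 1)])  # cycles/um along y, x, z
  structure(list(spectrum = spec, freq_step_um = step, dim = d),
            class = "os_otf")
}

#' Optimal stripe frequency for OS-SIM
#'
#' The illumination pattern's spatial frequency should be half the maximum
#' frequency the microscope can observe, i.e. half of the incoherent cutoff
#' `2 NA / lambda_ex`:
#' `nu_opt = NA / lambda_ex` (in cycles/um).
#'
#' @param config An [optical_config()] object.
#' @return Spatial frequency in cycles/um.
#' @export
optimal_pattern_frequency <- function(config) {
  stopifnot(inherits(config, "os_optics"))
  1000 * config$na / config$lambda_ex_nm
}

#' Sinusoidal illumination pattern
#'
#' Describes the striped excitation: spatial frequency, stripe orientation,
#' modulation depth `m`, and the list of phase offsets stepped between the
#' raw frames. The default offsets `0, 2pi/3, 4pi/3` give a uniform average
#' illumination across the three frames.
#'
#' @param frequency Spatial frequency in cycles/um.
#' @param orientation Stripe orientation in radians (0 = stripes varying
#'   along x).
#' @param modulation Modulation depth `m` in `[0, 1]`.
#' @param phase_offsets Numeric vector of phase offsets in radians.
#' @return An object of class `os_pattern`.
#' @export
sinusoidal_pattern <- function(frequency, orientation = 0, modulation = 1,
                               phase_offsets = 2 * (0:2) * pi / 3) {
  if (frequency <= 0) stop("pattern frequency must be positive")
  if (modulation < 0 || modulation > 1) stop("modulation depth must lie in [0, 1]")
  structure(list(frequency = frequency, orientation = orientation,
                 modulation = modulation, phase_offsets = phase_offsets),
            class = "os_pattern")
}

#' Render one phase of a sinusoidal pattern
#'
#' Evaluates `(1 + m cos(2 pi nu (x cos theta + y sin theta) + phi)) / 2` on
#' the physical pixel grid. Normalising to mean 1/2 makes the mean of the
#' three default phase images spatially constant (uniform average
#' illumination), so a noise-free widefield image is exactly half the
#' fluorophore density image.
#'
#' @param pattern An [sinusoidal_pattern()] object.
#' @param shape `c(ny, nx)` pixel counts.
#' @param phase_index 1-based index into `pattern$phase_offsets`.
#' @param pixel_size_nm Pixel pitch in nanometres.
#' @return A `ny` x `nx` matrix with values in `[(1 - m)/2, (1 + m)/2]`.
#' @export
render_pattern <- function(pattern, shape, phase_index, pixel_size_nm = 86) {
  stopifnot(inherits(pattern, "os_pattern"))
  if (phase_index < 1 || phase_index > length(pattern$phase_offsets)) {
    stop("phase_index out of range: pattern has ",
         length(pattern$phase_offsets), " phase offsets")
  }
  ny <- shape[1]; nx <- shape[2]
  px <- pixel_size_nm / 1000
  xs <- (seq_len(nx) - 1) * px
  ys <- (seq_len(ny) - 1) * px
  arg <- 2 * pi * pattern$frequency *
    outer(ys * sin(pattern$orientation), xs * cos(pattern$orientation), `+`) +
    pattern$phase_offsets[phase_index]
  (1 + pattern$modulation * cos(arg)) / 2
}

#' Axial modulation envelope of the excitation pattern
#'
#' The stripe modulation depth decays with defocus; this envelope models the
#' decay as a Gaussian in defocus,
#' `m(z) = m0 * exp(-(z / z_m)^2)` with `z_m = n * lambda_ex / NA^2`,
#' the natural axial scale of the excitation transfer function. This decay
#' is the physical basis of optical sectioning: only in-focus structure is
#' strongly striped.
#'
#' @param defocus_nm Defocus in nanometres (scalar or vector).
#' @param config An [optical_config()] object.
#' @return Envelope factor(s) in `(0, 1]` multiplying the in-focus
#'   modulation depth.
#' @export
modulation_envelope <- function(defocus_nm, config) {
  z_m <- config$ri * config$lambda_ex_nm / config$na^2
  exp(-(defocus_nm / z_m)^2)
}
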
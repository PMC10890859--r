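# Internal numerical helpers: FFT convolution, frequency grids, seeded RNG
# streams, image normalisation. Nothing here is exported.

# Next FFT-friendly size (factors 2, 3, 5 only).
good_fft_size <- function(n) {
  while (TRUE) {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# DFT sample frequencies, spacing d (returns cycles per unit of d).
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-ceiling((n - 1) / 2), -1L))
  k / (n * d)
}

# Run code with a private, reproducible RNG state; the caller's RNG stream is
# untouched so generators behave as pure functions of their seed.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a named sub-seed from a run-level seed
#'
#' All randomness in a pipeline can flow from one master seed through named
#' substreams (e.g. `"phantom"`, `"noise"`, `"training"`), so adding a new
#' consumer of randomness never perturbs existing streams. The result is a
#' stable integer below 2^31.
#'
#' @param seed Master integer seed.
#' @param stream Substream name.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435) %% 2147483647)
}

# Cyclic shift so that the element at `center` (vector of indices) moves to
# [1, 1, ...]; used to place a centred convolution kernel at the FFT origin.
ifftshift_to_origin <- function(arr, center) {
  d <- dim(arr)
  idx <- lapply(seq_along(d), function(i) {
    ((seq_len(d[i]) - 1 + (center[i] - 1)) %% d[i]) + 1
  })
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

pad_array <- function(arr, dims) {
  out <- array(0, dims)
  idx <- lapply(dim(arr), seq_len)
  do.call(`[<-`, c(list(out), idx, list(value = arr)))
}

# Linear "same" convolution of an image/volume with a centred kernel, done in
# frequency space with zero padding so there is no wrap-around.
#' @rdname conv2_centered
#' @param k_center Kernel centre indices (default: the central element).
#' @export
conv_centered <- function(x, kernel, k_center = NULL, pad = TRUE) {
  dx <- dim(x)
  dk <- dim(kernel)
  stopifnot(length(dx) == length(dk))
  if (is.null(k_center)) k_center <- floor(dk / 2) + 1
  if (pad) {
    pdims <- vapply(dx + dk - 1L, good_fft_size, integer(1))
  } else {
    pdims <- dx
  }
  xp <- pad_array(x, pdims)
  kp <- array(0, pdims)
  # place kernel with its centre at `k_center`, then roll centre to origin
  idx <- lapply(dk, seq_len)
  kp <- do.call(`[<-`, c(list(kp), idx, list(value = kernel)))
  kp <- ifftshift_to_origin(kp, k_center)
  out <- Re(fft(fft(xp) * fft(kp), inverse = TRUE)) / prod(pdims)
  idx <- lapply(dx, seq_len)
  do.call(`[`, c(list(out), idx, list(drop = FALSE)))
}

#' Linear convolution with a centred kernel
#'
#' Same-size convolution of an image (`conv2_centered()`) or volume
#' (`conv_centered()`) with a centred kernel, evaluated in frequency space
#' with zero padding so periodic wrap-around never touches the result.
#' Useful for computing diffraction-limited ground-truth images (structure
#' convolved with a PSF plane from [defocused_psf_plane()]).
#'
#' @param x,img Input array/matrix.
#' @param kernel Centred kernel (odd-sized for a symmetric result).
#' @param pad Zero-pad to avoid wrap-around (default TRUE).
#' @return Array/matrix of the input's shape.
#' @export
conv2_centered <- function(img, kernel, pad = TRUE) {
  out <- conv_centered(img, kernel, pad = pad)
  dim(out) <- dim(img)
  out
}

# Complex DTFT coefficient of a 2D image at a continuous spatial frequency
# (fx, fy) in cycles/um; normalised by pixel count so DC equals the mean.
dtft_point <- function(img, fx, fy, pixel_um) {
  ny <- nrow(img); nx <- ncol(img)
  xs <- (seq_len(nx) - 1) * pixel_um
  ys <- (seq_len(ny) - 1) * pixel_um
  ex <- exp(-2i * pi * fx * xs)
  ey <- exp(-2i * pi * fy * ys)
  as.complex((ey %*% img %*% ex)[1, 1] / (nx * ny))
}

#' Stripe amplitude of an image at a pattern frequency
#'
#' Continuous-frequency Fourier amplitude of an image at a sinusoidal
#' pattern's frequency and orientation, relative to its DC level — the
#' stripe-artefact metric used by the motion benchmark. The image mean is
#' removed before evaluation so DC leakage cannot mask stripe-free images
#' at off-bin frequencies.
#'
#' @param img Image matrix.
#' @param frequency Pattern frequency, cycles/um.
#' @param orientation Pattern orientation, radians.
#' @param pixel_size_nm Pixel pitch in nanometres.
#' @return List with `amplitude` (per-pixel Fourier amplitude), `dc` and
#'   `ratio` (amplitude / DC).
#' @export
stripe_amplitude <- function(img, frequency, orientation, pixel_size_nm) {
  px <- pixel_size_nm / 1000
  fx <- frequency * cos(orientation)
  fy <- frequency * sin(orientation)
  dc <- mean(img)
  # remove the mean first: spectral leakage from DC would otherwise mask
  # genuinely stripe-free images at off-bin frequencies
  peak <- dtft_point(img - dc, fx, fy, px)
  list(amplitude = Mod(peak), dc = abs(dc),
       ratio = if (abs(dc) > 0) Mod(peak) / abs(dc) else Inf)
}

# Subpixel rigid translation by (dy, dx) pixels via a Fourier phase ramp.
fourier_translate <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  ky <- fft_freq(ny)
  kx <- fft_freq(nx)
  ramp <- exp(-2i * pi * outer(ky * dy, kx * dx, `+`))
  Re(fft(fft(img) * ramp, inverse = TRUE)) / (ny * nx)
}

# Percentile normalisation to [0, 1] (clipped); the evaluation module's
# standard intensity normalisation before SSIM scoring.
percentile_norm <- function(x, lo = 0.01, hi = 0.99) {
  q <- stats::quantile(x, c(lo, hi), names = FALSE)
  if (diff(q) <= .Machine$double.eps) return(array(0, dim(x)))
  y <- (x - q[1]) / (q[2] - q[1])
  y[y < 0] <- 0
  y[y > 1] <- 1
  y
}

# Separable Gaussian blur with edge replication ("nearest" padding), sampled
# kernel truncated at `radius` sigmas-equivalent taps. Matches the windowing
# used by the SSIM implementation.
gauss_kernel_1d <- function(sigma, radius) {
  x <- seq(-radius, radius)
  k <- exp(-0.5 * (x / sigma)^2)
  k / sum(k)
}

blur_nearest_1d <- function(mat, k, margin) {
  r <- (length(k) - 1) / 2
  n <- if (margin == 1) nrow(mat) else ncol(mat)
  idx <- pmin(pmax(seq.int(1 - r, n + r), 1L), n)
  if (margin == 1) {
    padded <- mat[idx, , drop = FALSE]
    out <- matrix(0, nrow(mat), ncol(mat))
    for (j in seq_along(k)) out <- out + k[j] * padded[seq_len(n) + j - 1, , drop = FALSE]
  } else {
    padded <- mat[, idx, drop = FALSE]
    out <- matrix(0, nrow(mat), ncol(mat))
    for (j in seq_along(k)) out <- out + k[j] * padded[, seq_len(n) + j - 1, drop = FALSE]
  }
  out
}

gauss_blur_nearest <- function(img, sigma, radius = as.integer(3.5 * sigma + 0.5)) {
  k <- gauss_kernel_1d(sigma, radius)
  blur_nearest_1d(blur_nearest_1d(img, k, 1), k, 2)
}

# Radially averaged power spectrum of a 2D image (DC excluded).
radial_power_spectrum <- function(img, pixel_um = 1) {
  ny <- nrow(img); nx <- ncol(img)
  p <- Mod(fft(img - mean(img)))^2
  fx <- fft_freq(nx, pixel_um)
  fy <- fft_freq(ny, pixel_um)
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  nb <- floor(min(ny, nx) / 2)
  fmax <- min(max(abs(fx)), max(abs(fy)))
  bins <- cut(fr, breaks = seq(0, fmax, length.out = nb + 1), include.lowest = TRUE)
  pw <- tapply(p, bins, mean)
  ctr <- (head(seq(0, fmax, length.out = nb + 1), -1) +
          tail(seq(0, fmax, length.out = nb + 1), -1)) / 2
  keep <- !is.na(pw) & ctr > 0
  list(freq = ctr[keep], power = as.numeric(pw[keep]))
}

clip0 <- function(x) {
  x[x < 0] <- 0
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
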
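# Born-Wolf PSF, OTF and illumination-pattern properties.

cfg <- ref_config()
psf <- compute_psf(cfg, c(33, 65, 65))
otf <- compute_otf(psf)

test_that("PSF satisfies its invariants: normalisation, symmetry, focal peak", {
  expect_true(all(psf$vol >= 0))
  expect_equal(sum(psf$vol), 1, tolerance = 1e-6)
  # centrosymmetric in x and y
  expect_equal(psf$vol, psf$vol[65:1, , , drop = FALSE], ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_equal(psf$vol, psf$vol[, 65:1, , drop = FALSE], ignore_attr = TRUE,
               tolerance = 1e-6)
  # brightest plane is the focal plane
  plane_max <- apply(psf$vol, 3, max)
  expect_identical(which.max(plane_max), as.integer(psf$focus_index))
})

test_that("lateral FWHM is within 15% of the Abbe width lambda/(2 NA)", {
  plane <- psf$vol[, , psf$focus_index]
  prof <- plane[33, ] / max(plane[33, ])
  xs <- (seq_len(65) - 33) * 86
  f <- stats::approxfun(xs, prof)
  lo <- stats::uniroot(function(x) f(x) - 0.5, c(-400, 0))$root
  hi <- stats::uniroot(function(x) f(x) - 0.5, c(0, 400))$root
  abbe <- 600 / (2 * 1.2)  # 250 nm
  expect_lt(abs((hi - lo) - abbe) / abbe, 0.15)
})

test_that("PSF energy is conserved across a grid of optical configurations", {
  for (na in c(0.8, 1.0, 1.2)) {
    for (lam in c(520, 680)) {
      p <- compute_psf(optical_config(na, lam, ri = 1.33, voxel_nm = 100),
                       c(9, 33, 33))
      expect_equal(sum(p$vol), 1, tolerance = 1e-6)
    }
  }
})

test_that("PSF input contracts: invalid optics, even lateral shape, truncation", {
  expect_error(optical_config(1.4, 600, ri = 1.33), "refractive index")
  expect_error(compute_psf(cfg, c(9, 32, 33)), "odd")
  expect_warning(compute_psf(cfg, c(3, 5, 5)), "Airy")
})

test_that("OTF is DC-normalised, Hermitian, and confined to the classical cutoff", {
  expect_equal(Re(otf$spectrum[1, 1, 1]), 1)
  expect_lt(Mod(Im(otf$spectrum[1, 1, 1])), 1e-12)
  # Hermitian symmetry of the spectrum of a real PSF
  s <- otf$spectrum
  conj_flip <- Conj(s[c(1, 65:2), c(1, 65:2), c(1, 33:2)])
  expect_lt(max(Mod(s - conj_flip)), 1e-8)
  # magnitude below 1e-3 outside the lateral cutoff 2 NA / lambda_em
  fr <- sqrt(outer(fft_freq(65, 0.086)^2, fft_freq(65, 0.086)^2, `+`))
  cutoff <- 2 * 1.2 / 0.6
  expect_lt(max(Mod(s[, , 1])[fr > cutoff]), 1e-3)
})

test_that("widefield OTF has the missing cone: almost no energy on the kz axis", {
  axial <- Mod(otf$spectrum[1, 1, -1])^2
  dc_plane <- sum(Mod(otf$spectrum[, , 1])^2)
  expect_lt(sum(axial) / dc_plane, 0.01)
})

test_that("supported OTF radius scales linearly with NA", {
  radius_of <- function(na) {
    p <- compute_psf(optical_config(na, 600, ri = 1.45, voxel_nm = 60),
                     c(5, 65, 65))
    o <- compute_otf(p)
    m <- Mod(o$spectrum[, , 1])
    fr <- sqrt(outer(fft_freq(65, 0.060)^2, fft_freq(65, 0.060)^2, `+`))
    max(fr[m > 1e-3])
  }
  r <- vapply(c(0.6, 0.9, 1.2), radius_of, numeric(1))
  expect_equal(r[2] / r[1], 1.5, tolerance = 0.08)
  expect_equal(r[3] / r[1], 2.0, tolerance = 0.08)
})

test_that("optimal pattern frequency is NA/lambda_ex and scales linearly in NA", {
  expect_equal(optimal_pattern_frequency(
    optical_config(1.2, 600, 488, 1.33, 86)), 2.459, tolerance = 1e-3)
  expect_equal(optimal_pattern_frequency(
    optical_config(1.2, 600, 600, 1.33, 86)), 2.0, tolerance = 1e-12)
  c1 <- optical_config(0.65, 600, 600, 1.33, 86)
  c2 <- optical_config(1.30, 600, 600, 1.52, 86)
  expect_equal(optimal_pattern_frequency(c2),
               2 * optimal_pattern_frequency(c1))
})

test_that("rendered pattern obeys range, phase stepping and uniform average", {
  pat <- sinusoidal_pattern(2.0, 0.3, 0.8)
  imgs <- lapply(1:3, function(n) render_pattern(pat, c(32, 32), n, 86))
  for (im in imgs) {
    expect_gte(min(im), (1 - 0.8) / 2 - 1e-12)
    expect_lte(max(im), (1 + 0.8) / 2 + 1e-12)
  }
  # default offsets are 2 (n-1) pi / 3
  expect_equal(pat$phase_offsets, c(0, 2 * pi / 3, 4 * pi / 3))
  # per-pixel mean over the three phases is exactly 1/2
  avg <- Reduce(`+`, imgs) / 3
  expect_lt(max(abs(avg - 0.5)), 1e-9)
  # zero modulation renders a constant 1/2
  flat <- render_pattern(sinusoidal_pattern(2.0, 0, 0), c(16, 16), 2, 86)
  expect_equal(flat, matrix(0.5, 16, 16))
  expect_error(render_pattern(pat, c(16, 16), 4, 86), "out of range")
})

test_that("axial modulation envelope decays on the n lambda / NA^2 scale", {
  expect_equal(modulation_envelope(0, cfg), 1)
  z_m <- 1.33 * 488 / 1.2^2
  expect_equal(modulation_envelope(z_m, cfg), exp(-1))
  expect_lt(modulation_envelope(1500, cfg), 1e-4)
})
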
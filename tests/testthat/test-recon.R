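# Classical subtractive reconstructions and pattern-parameter estimation.

cfg <- ref_config()

test_that("widefield estimate: identity, linearity, frame-count contract", {
  f <- array(rep(generate_texture(c(32, 32), 1, "blobs"), 3), c(32, 32, 3))
  st <- os_stack(f)
  expect_equal(widefield_estimate(st), f[, , 1], tolerance = 1e-12)
  a <- textured_stack(2, shape = c(32, 32))
  b <- a; b$frames <- 2 * a$frames
  expect_equal(widefield_estimate(b), 2 * widefield_estimate(a),
               tolerance = 1e-12)
  expect_error(os_stack(array(1, c(8, 8, 2))), "3 phase")
})

test_that("widefield of an ideal phase-stepped triplet is stripe-free", {
  st <- uniform_plane_stack()
  wf <- widefield_estimate(st)
  sa <- stripe_amplitude(wf, 2.0, 0.3, 86)
  expect_lt(sa$ratio, 1e-6)
})

test_that("SD of a uniform sinusoidal plane is the constant sqrt(4.5) B m", {
  B <- 2; m <- 0.9
  st <- uniform_plane_stack(B = B, modulation = m)
  out <- sd_reconstruction(st)
  expect_equal(mean(out), sqrt(4.5) * B * m, tolerance = 1e-12)
  expect_lt(stats::sd(as.vector(out)) / mean(out), 1e-12)
  # identical frames give exactly zero
  idf <- os_stack(array(rep(matrix(1, 8, 8), 3), c(8, 8, 3)))
  expect_true(all(sd_reconstruction(idf) == 0))
})

test_that("SD and corrected SD obey phase-relabelling and scaling symmetries", {
  st <- textured_stack(4, shape = c(48, 48))
  perm <- st; perm$frames <- st$frames[, , c(2, 3, 1), , drop = FALSE]
  expect_equal(sd_reconstruction(st), sd_reconstruction(perm),
               tolerance = 1e-12)
  phi <- c(0, 2 * pi / 3, 4 * pi / 3)
  expect_equal(corrected_sd(st, phi), corrected_sd(perm, phi[c(2, 3, 1)]),
               tolerance = 1e-9)
  sc <- st; sc$frames <- 3.7 * st$frames
  expect_equal(sd_reconstruction(sc), 3.7 * sd_reconstruction(st),
               tolerance = 1e-9)
  expect_equal(corrected_sd(sc, phi), 3.7 * corrected_sd(st, phi),
               tolerance = 1e-9)
})

test_that("corrected SD demodulates any non-degenerate phase triple exactly", {
  # brute-force oracle: per-pixel nonlinear least squares for (B, A, theta)
  # in I_n = B + A cos(theta + phi_n), fitted with optim
  set.seed(31)
  phi <- c(0.2, 1.7, 4.1)
  theta <- matrix(stats::runif(16, 0, 2 * pi), 4, 4)
  A <- matrix(stats::runif(16, 0.5, 2), 4, 4)
  B <- matrix(stats::runif(16, 2, 4), 4, 4)
  fr <- array(0, c(4, 4, 3))
  for (n in 1:3) fr[, , n] <- B + A * cos(theta + phi[n])
  out <- corrected_sd(os_stack(fr), phi)
  for (i in 1:4) for (j in 1:4) {
    obs <- fr[i, j, ]
    fit <- stats::optim(c(mean(obs), 1, 1), function(p) {
      sum((obs - (p[1] + p[2] * cos(p[3] + phi)))^2)
    }, method = "BFGS")
    expect_equal(out[i, j], sqrt(4.5) * abs(fit$par[2]), tolerance = 1e-4)
  }
})

test_that("corrected SD is constant on ideal uniform planes and matches SD", {
  st <- uniform_plane_stack(B = 1.5, modulation = 0.7)
  csd <- corrected_sd(st, c(0, 2 * pi / 3, 4 * pi / 3))
  expect_lt(stats::sd(as.vector(csd)) / mean(csd), 0.01)
  expect_equal(mean(csd), sqrt(4.5) * 1.5 * 0.7, tolerance = 1e-9)
})

test_that("corrected SD suppresses the residual stripes of uneven stepping", {
  phi_err <- c(0, 2 * pi / 3 + 0.2, 4 * pi / 3)
  st <- uniform_plane_stack(phase_offsets = phi_err)
  res_sd <- sd_reconstruction(st)
  res_csd <- corrected_sd(st, phi_err)
  # SD residual appears at the pattern frequency and its double
  a_sd <- stripe_amplitude(res_sd, 2.0, 0.3, 86)$amplitude +
    stripe_amplitude(res_sd, 4.0, 0.3, 86)$amplitude
  a_csd <- stripe_amplitude(res_csd, 2.0, 0.3, 86)$amplitude +
    stripe_amplitude(res_csd, 4.0, 0.3, 86)$amplitude
  expect_lt(a_csd, 0.5 * a_sd)
})

test_that("degenerate phase triples raise informative errors", {
  st <- textured_stack(6, shape = c(32, 32))
  expect_error(corrected_sd(st, c(0, pi, 0.4)), "tan pole")
  expect_error(corrected_sd(st, c(0.3, 0.3, 2)), "coincide")
  expect_error(corrected_sd(st, c(0, NA, 1)), "finite")
})

test_that("pattern estimation recovers frequency, orientation and phases", {
  st <- textured_stack(7, shape = c(96, 96))
  est <- estimate_pattern_parameters(st)
  expect_false(est$low_confidence)
  expect_lt(abs(est$frequency - 2.0) / 2.0, 0.005)
  expect_lt(abs(est$orientation - 0.3), 0.02)
  wrap <- function(x) atan2(sin(x), cos(x))
  expect_lt(abs(wrap(est$phases[2] - est$phases[1]) - 2 * pi / 3), 0.05)
  expect_lt(abs(wrap(est$phases[3] - est$phases[2]) - 2 * pi / 3), 0.05)
})

test_that("a global phase offset leaves estimated phase differences unchanged", {
  # uniform-plane scenes with a carrier aligned to DFT bins in both axes:
  # no object spectrum and no spectral leakage at the stripe peak, so the
  # estimator's phase differences must be exactly offset-invariant
  field <- 64 * 0.086
  nu <- sqrt(10^2 + 4^2) / field
  th <- atan2(4, 10)
  st1 <- uniform_plane_stack(shape = c(64, 64), frequency = nu,
                             orientation = th)
  st2 <- uniform_plane_stack(shape = c(64, 64), frequency = nu,
                             orientation = th,
                             phase_offsets = 0.63 + 2 * (0:2) * pi / 3)
  e1 <- estimate_pattern_parameters(st1)
  e2 <- estimate_pattern_parameters(st2)
  wrap <- function(x) atan2(sin(x), cos(x))
  expect_equal(wrap(e1$phases[2] - e1$phases[1]),
               wrap(e2$phases[2] - e2$phases[1]), tolerance = 1e-6)
  expect_equal(wrap(e1$phases[3] - e1$phases[1]),
               wrap(e2$phases[3] - e2$phases[1]), tolerance = 1e-6)
})

test_that("phase estimation error shrinks with signal level", {
  st <- textured_stack(9, shape = c(64, 64))
  err_at <- function(eta) {
    mean(vapply(1:3, function(r) {
      noisy <- add_noise(st, noise_model(eta), seed = 100 * r)
      e <- suppressWarnings(estimate_pattern_parameters(noisy))
      wrap <- function(x) atan2(sin(x), cos(x))
      abs(wrap(e$phases[2] - e$phases[1]) - 2 * pi / 3) +
        abs(wrap(e$phases[3] - e$phases[2]) - 2 * pi / 3)
    }, numeric(1)))
  }
  e_lo <- err_at(5e-5)
  e_hi <- err_at(5e-4)
  expect_lt(e_hi, e_lo + 0.02)  # decreasing over a decade, within noise
})

test_that("estimation falls back to the configured pattern when stripes vanish", {
  st <- textured_stack(10, shape = c(48, 48), modulation = 0)
  expect_warning(est <- estimate_pattern_parameters(st), "low confidence")
  expect_true(est$low_confidence)
  expect_equal(est$frequency, 2.0)
  st$pattern <- NULL
  expect_error(suppressWarnings(estimate_pattern_parameters(st)), "no stripe peak")
})

test_that("HiLo mixing endpoints isolate their respective branches", {
  st <- textured_stack(12, shape = c(64, 64))
  est <- estimate_pattern_parameters(st)
  p1 <- hilo_params(1, est$frequency / 2, 0.1 * est$frequency)
  p0 <- hilo_params(0, est$frequency / 2, 0.1 * est$frequency)
  wf <- widefield_estimate(st)
  csd <- corrected_sd(st, est)
  lp <- function(img) ossim:::gaussian_lowpass(img, est$frequency / 2, 86)
  notch <- function(img) notch_filter(img, est$frequency,
                                      0.1 * est$frequency, 86)
  expect_equal(hilo_filtered(st, p1, est),
               ossim:::clip0(notch(wf - lp(wf))), tolerance = 1e-9)
  expect_equal(hilo_filtered(st, p0, est),
               ossim:::clip0(notch(lp(csd))), tolerance = 1e-9)
  expect_error(hilo_params(1.2, 1, 0.2), "alpha")
})

test_that("the notch filter suppresses a pure pattern-frequency sinusoid", {
  pat <- ref_pattern(1)
  stripe <- render_pattern(pat, c(96, 96), 1, 86) - 0.5
  before <- stripe_amplitude(stripe, 2.0, 0.3, 86)$amplitude
  after <- stripe_amplitude(notch_filter(stripe, 2.0, 0.2, 86),
                            2.0, 0.3, 86)$amplitude
  expect_lte(after, 0.1 * before)
})

test_that("all methods reject out-of-focus structure better than widefield", {
  st_full <- textured_stack(14, shape = c(64, 64), with_oof = TRUE)
  st_in <- textured_stack(14, shape = c(64, 64), with_oof = FALSE)
  est <- estimate_pattern_parameters(st_in)
  resid <- function(m) {
    rf <- ossim:::recon_volume_by_method(st_full, m, est)
    ri <- ossim:::recon_volume_by_method(st_in, m, est)
    sum((rf - ri)^2) / sum(ri^2)
  }
  r_wf <- resid("widefield")
  for (m in c("sd", "corrected", "filtered")) expect_lt(resid(m), r_wf)
})

test_that("reconstruct() dispatcher returns provenance", {
  st <- textured_stack(15, shape = c(48, 48))
  r <- reconstruct(st, "filtered")
  expect_s3_class(r, "os_recon")
  expect_identical(r$method, "filtered")
  expect_false(is.null(r$pattern_estimate))
  expect_identical(dim(r$image), c(48L, 48L))
})
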
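# Image formation: patterned excitation, blurring, plane mixing, volume
# scanning, and the Gaussian + Poisson noise model.

cfg <- ref_config()

test_that("zero modulation gives three identical frames", {
  tex <- generate_texture(c(48, 48), 1, "blobs")
  psf <- defocused_psf_plane(cfg, c(17, 17), 0)
  st <- simulate_stack(tex, psf, sinusoidal_pattern(2, 0.3, 0), config = cfg)
  expect_equal(st$frames[, , 1, 1], st$frames[, , 2, 1], tolerance = 1e-12)
  expect_equal(st$frames[, , 2, 1], st$frames[, , 3, 1], tolerance = 1e-12)
})

test_that("delta PSF and no background reproduce in_focus x pattern exactly", {
  tex <- generate_texture(c(32, 32), 2, "multiscale-noise")
  delta <- matrix(0, 17, 17); delta[9, 9] <- 1
  pat <- sinusoidal_pattern(2, 0.3, 0.8)
  st <- simulate_stack(tex, delta, pat, pixel_size_nm = 86)
  for (n in 1:3) {
    expect_equal(st$frames[, , n, 1],
                 tex * render_pattern(pat, c(32, 32), n, 86),
                 tolerance = 1e-9)
  }
})

test_that("mean of the three frames equals the widefield forward model", {
  tex <- generate_texture(c(48, 48), 3, "blobs")
  oof <- generate_texture(c(48, 48), 4, "multiscale-noise")
  psf_in <- defocused_psf_plane(cfg, c(33, 33), 0)
  psf_out <- defocused_psf_plane(cfg, c(33, 33), 1500)
  st <- simulate_stack(tex, psf_in, ref_pattern(), out_of_focus = oof,
                       psf_out = psf_out, oof_weight = 0.7, config = cfg)
  wf <- widefield_estimate(st)
  expected <- conv2_centered(tex, psf_in) / 2 +
    0.7 * conv2_centered(oof, psf_out) / 2
  expect_equal(wf, expected, tolerance = 1e-6)
})

test_that("widefield estimate is invariant under phase permutation", {
  st <- textured_stack(5)
  perm <- st
  perm$frames <- st$frames[, , c(3, 1, 2), , drop = FALSE]
  expect_equal(widefield_estimate(st), widefield_estimate(perm),
               tolerance = 1e-12)
})

test_that("shape mismatches and missing PSFs are rejected", {
  tex <- generate_texture(c(32, 32), 1, "blobs")
  oof <- generate_texture(c(48, 48), 1, "blobs")
  psf <- defocused_psf_plane(cfg, c(17, 17), 0)
  expect_error(simulate_stack(tex, psf, ref_pattern(), out_of_focus = oof,
                              psf_out = psf), "share shape")
  expect_error(simulate_stack(tex, psf, ref_pattern(),
                              out_of_focus = tex), "psf_out")
})

test_that("volume scan: determinism, shape contract, axial stripe selectivity", {
  vol <- array(0, c(32, 32, 36))
  vol[8:24, 8:24, 18] <- generate_texture(c(17, 17), 8, "blobs")
  pat <- ref_pattern()
  s1 <- simulate_volume_scan(vol, cfg, pat)
  s2 <- simulate_volume_scan(vol, cfg, pat)
  expect_identical(s1$frames, s2$frames)
  expect_identical(dim(s1$frames), c(32L, 32L, 3L, 36L))
  # stripes (visible in the frame differences) are strongest at the plane
  # holding the structure and collapse >= 1 um away
  amp_at <- function(z) {
    stripe_amplitude(s1$frames[, , 1, z] - s1$frames[, , 2, z],
                     pat$frequency, pat$orientation, 86)$amplitude
  }
  expect_gt(amp_at(18), 10 * amp_at(6))   # 12 planes ~ 1.03 um defocus
  expect_gt(amp_at(18), 10 * amp_at(30))
})

test_that("noise model: determinism, contracts, high-photon limit", {
  st <- textured_stack(11, shape = c(32, 32))
  expect_error(noise_model(0), "positive")
  expect_error(noise_model(-1e-5), "positive")
  n1 <- add_noise(st, noise_model(1e-4), seed = 3)
  n2 <- add_noise(st, noise_model(1e-4), seed = 3)
  expect_identical(n1$frames, n2$frames)
  expect_true(all(n1$frames >= 0))
  # eta large enough for >= 1e8 expected photons at the peak: relative
  # deviation shrinks as 1/sqrt(lambda)
  big <- add_noise(st, noise_model(100, gaussian_sigma = 0), seed = 4)
  rel <- (big$frames / big$meta$photon_per_input - st$frames) / max(st$frames)
  expect_lt(sqrt(mean(rel^2)), 1e-3)
})

test_that("per-pixel noise statistics match lambda + sigma^2", {
  st <- textured_stack(13, shape = c(16, 16))
  nm <- noise_model(2e-5, gaussian_sigma = 1.5)
  draws <- vapply(1:1000, function(s) {
    add_noise(st, nm, seed = s)$frames[8, 8, 1, 1]
  }, numeric(1))
  lam <- st$frames[8, 8, 1, 1] / max(st$frames) *
    nm$peak_intensity_norm * nm$eta * nm$photon_scale
  se <- sqrt((lam + 1.5^2) / 1000)
  expect_lt(abs(mean(draws) - lam), 3 * se)
  # variance within Monte-Carlo error (chi-square 99% band ~ +/-11%)
  expect_lt(abs(stats::var(draws) / (lam + 1.5^2) - 1), 0.15)
})

test_that("training examples are reproducible and store exact provenance", {
  gen <- training_generator_config(shape = c(32, 32), psf_size = 17)
  e1 <- make_training_example(gen, seed = 9)
  e2 <- make_training_example(gen, seed = 9)
  expect_identical(e1$input$frames, e2$input$frames)
  expect_identical(e1$target, e2$target)
  # ground truth recomputed bit-exactly from the stored parameters
  cfg_d <- optical_config(e1$params$na, gen$lambda_em_nm, gen$lambda_ex_nm,
                          gen$ri, gen$pixel_size_nm)
  psf_in <- defocused_psf_plane(cfg_d, c(17, 17), 0)
  tex <- generate_texture(gen$shape, e1$params$texture_seed_in,
                          e1$params$kind_in)
  expect_identical(e1$target, conv2_centered(tex, psf_in))
})

test_that("drawn parameters cover their configured ranges", {
  gen <- training_generator_config(shape = c(24, 24), psf_size = 17)
  mods <- vapply(1:200, function(s) {
    make_training_example(gen, seed = s)$params$modulation
  }, numeric(1))
  span <- diff(range(mods)) / diff(gen$modulation)
  expect_gte(span, 0.8)
})

test_that("degenerate generator ranges are rejected", {
  expect_error(training_generator_config(modulation = c(0.9, 0.3)), "max >= min")
  expect_error(training_generator_config(eta = c(1e-4)), "max >= min")
})

test_that("video-mode examples target the sectioned second frame", {
  gen <- training_generator_config(shape = c(32, 32), psf_size = 17,
                                   mode = "video")
  ex <- make_training_example(gen, seed = 21)
  cfg_d <- optical_config(ex$params$na, gen$lambda_em_nm, gen$lambda_ex_nm,
                          gen$ri, gen$pixel_size_nm)
  psf_in <- defocused_psf_plane(cfg_d, c(17, 17), 0)
  trip <- generate_moving_triplet(gen$shape, n_objects = 6,
                                  max_displacement = ex$params$max_displacement,
                                  seed = ex$params$texture_seed_in)
  expect_identical(ex$target, conv2_centered(trip$frames[[2]], psf_in))
})
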
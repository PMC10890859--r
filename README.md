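# ossim

Simulation and reconstruction for **optically sectioned structured
illumination microscopy (OS-SIM)**, for microscopists and methods
developers who want to study — or train — OS-SIM reconstruction
algorithms without a microscope.

In OS-SIM a fluorescent sample is excited with a sinusoidal stripe
pattern and imaged with widefield detection. The stripe modulation depth
is highest in the focal plane and decays rapidly with defocus, so three
images acquired with the pattern stepped in phase by `0, 2π/3, 4π/3`
contain the in-focus structure as the only *modulated* component. The
classical squared-difference (SD) demodulation

```
I_R = sqrt((I1 − I2)² + (I2 − I3)² + (I1 − I3)²)
```

extracts it — on an ideally stepped sinusoid of mean `B` and modulation
`m` it returns the constant `√4.5·B·m` — but it amplifies noise and
breaks down under phase-step errors and sample motion. This package
implements the full tool chain around that problem:

* a physically grounded **forward simulator**: scalar Born–Wolf PSFs and
  OTFs, sinusoidal patterns with a defocus-dependent modulation envelope,
  2D two-plane and full 3D volume-scan image formation, and a
  Poisson + Gaussian noise model parameterised by a photon-budget factor
  `η` (peak expectation `η × 10⁶` photons);
* **phantom generators**: 3D filament meshes, procedural textures, and
  moving-object frame triplets — all pure functions of a seed;
* the three **classical reconstructions**: SD, phase-corrected SD for
  uneven phase stepping (a tan-half-angle quadrature combination), and
  HiLo-style high-/low-pass fusion with an annular stripe-suppression
  notch, plus data-driven pattern estimation from the frame-difference
  spectrum;
* two **trainable reconstruction networks** — a residual channel
  attention CNN (RCAN) and a shifted-window attention video network
  (VSR) that fuses the three frames jointly for motion robustness —
  implemented on a compact reverse-mode autodiff engine, trained with
  Adam and an MSE→L1 loss switch on simulator output;
* an **evaluation harness**: SSIM scoring against noise-free sectioned
  ground truth, missing-cone OTF analysis, an SSIM-versus-`η` noise
  sweep, and an eight-scene motion benchmark, returning tidy tibbles
  with `tidy()`/`autoplot()` methods;
* multi-page float32 TIFF + JSON-sidecar I/O and a small CLI
  (`inst/cli/ossim.R`) with `simulate`, `reconstruct` and `evaluate`
  subcommands.

## Worked example

Simulate a noisy two-plane acquisition, estimate the pattern from the
data, and compare reconstructions against the ideal sectioned image:

```r
library(ossim)

cfg <- optical_config(na = 1.2, lambda_em_nm = 600, lambda_ex_nm = 488,
                      ri = 1.33, voxel_nm = 86)
pat <- sinusoidal_pattern(frequency = optimal_pattern_frequency(cfg),
                          orientation = 0.3, modulation = 0.9)

in_focus  <- generate_texture(c(96, 96), seed = 1, kind = "filaments-2d")
out_focus <- generate_texture(c(96, 96), seed = 2, kind = "blobs")
psf_in  <- defocused_psf_plane(cfg, c(33, 33), defocus_nm = 0)
psf_out <- defocused_psf_plane(cfg, c(33, 33), defocus_nm = 1500)

stack <- simulate_stack(in_focus, psf_in, pat,
                        out_of_focus = out_focus, psf_out = psf_out,
                        oof_weight = 0.8, config = cfg)
stack <- add_noise(stack, noise_model(eta = 1e-4), seed = 7)
stack
#> <os_stack> 96 x 96 px, 3 phases, 1 z plane(s); noisy (eta = 1e-04)

est <- estimate_pattern_parameters(stack)
est
#> <os_pattern_estimate> nu = 2.4557 cycles/um, theta = 0.2994 rad,
#>   phases = 0.148, 2.198, 4.465 , m = 0.122

gt <- conv2_centered(in_focus, psf_in)   # ideal sectioned image
round(c(widefield = ssim_score(widefield_estimate(stack), gt),
        sd        = ssim_score(sd_reconstruction(stack), gt),
        corrected = ssim_score(corrected_sd(stack, est), gt),
        filtered  = ssim_score(hilo_filtered(stack, phases = est), gt)), 3)
#> widefield        sd corrected  filtered
#>     0.605     0.407     0.407     0.578
```

The pattern estimate recovers the true frequency (2.459 cycles/µm) to
0.2% and the `2π/3` phase steps to a few hundredths of a radian from the
noisy data alone. At this photon budget (100 expected photons at the
brightest pixel) the numbers show the method's central tension: SD
removes the out-of-focus blobs but amplifies noise so strongly that it
scores *below* the widefield image, while the filtered variant recovers
most of the gap. Training the bundled networks shifts this trade-off —
see `vignette("os-sim-methods")` and `?train_network`.

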
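# Shared fixtures: the reference optics of the simulation study and small
# reusable builders. Everything is generated in code; nothing is read from
# disk.

ref_config <- function() optical_config(na = 1.2, lambda_em_nm = 600,
                                        lambda_ex_nm = 488, ri = 1.33,
                                        voxel_nm = 86)

ref_pattern <- function(modulation = 0.9) {
  sinusoidal_pattern(frequency = 2.0, orientation = 0.3,
                     modulation = modulation)
}

# uniform fluorophore plane under the pattern: I_n = B (1 + m cos(...)),
# the closed-form scene for the demodulation identities
uniform_plane_stack <- function(B = 2, modulation = 0.9, shape = c(64, 64),
                                phase_offsets = 2 * (0:2) * pi / 3,
                                frequency = 2.0, orientation = 0.3) {
  pat <- sinusoidal_pattern(frequency, orientation, modulation, phase_offsets)
  frames <- array(0, c(shape, 3))
  for (n in 1:3) frames[, , n] <- 2 * B * render_pattern(pat, shape, n, 86)
  os_stack(frames, pattern = sinusoidal_pattern(frequency, orientation,
                                                modulation),
           pixel_size_nm = 86)
}

# small textured stack through the 2D forward model
textured_stack <- function(seed = 7, shape = c(64, 64), modulation = 0.9,
                           phase_offsets = 2 * (0:2) * pi / 3,
                           with_oof = FALSE, oof_weight = 1) {
  cfg <- ref_config()
  pat <- sinusoidal_pattern(2.0, 0.3, modulation, phase_offsets)
  tex <- generate_texture(shape, seed, "multiscale-noise")
  psf_in <- defocused_psf_plane(cfg, c(33, 33), 0)
  if (with_oof) {
    oof <- generate_texture(shape, seed + 1, "blobs")
    psf_out <- defocused_psf_plane(cfg, c(33, 33), 1500)
    simulate_stack(tex, psf_in, pat, out_of_focus = oof, psf_out = psf_out,
                   oof_weight = oof_weight, pixel_size_nm = 86, config = cfg)
  } else {
    simulate_stack(tex, psf_in, pat, pixel_size_nm = 86, config = cfg)
  }
}

# 26-connectivity flood fill; used as the filament-connectivity oracle
n_components_26 <- function(vol) {
  d <- dim(vol)
  lab <- array(0L, d)
  idx <- which(vol > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  comp <- 0L
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    if (lab[p[1], p[2], p[3]] > 0) next
    comp <- comp + 1L
    queue <- matrix(p, 1)
    lab[p[1], p[2], p[3]] <- comp
    while (nrow(queue) > 0) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      nb <- sweep(off, 2, cur, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      for (j in seq_len(nrow(nb))) {
        q <- nb[j, ]
        if (vol[q[1], q[2], q[3]] > 0 && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- comp
          queue <- rbind(queue, q)
        }
      }
    }
  }
  comp
}

tiny_rcan <- function(seed = 1) {
  build_rcan(rcan_config(n_groups = 1, blocks_per_group = 2, n_filters = 8,
                         ca_reduction = 4), seed = seed)
}

tiny_vsr <- function(seed = 1) {
  build_vsr(vsr_config(n_wcabs = 2, swin_per_wcab = 2, window_size = 8,
                       n_heads = 2, embed_dim = 16, ca_reduction = 4),
            seed = seed)
}
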
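#' Generate a 3D filament-mesh phantom
#'
#' Builds a ground-truth volume of randomly oriented, smoothly curving
#' filaments: each filament is a random-walk space curve (direction
#' perturbed by small Gaussian kicks and reflected at the volume faces)
#' dilated to the requested thickness. Filament voxels have intensity 1,
#' background 0. This emulates the cytoskeleton-like meshes used to
#' validate optical-sectioning reconstructions in simulation.
#'
#' @param shape Integer `c(nz, ny, nx)` voxel counts (all at least 16).
#' @param n_filaments Number of filaments (0 gives an empty volume).
#' @param thickness_voxels Filament diameter in voxels (>= 1).
#' @param seed Integer seed; the phantom is a pure function of
#'   `(shape, n_filaments, thickness_voxels, seed)`.
#' @param voxel_nm Voxel pitch recorded in the result (metadata only).
#' @return An object of class `os_phantom`: list with `vol` (array dim
#'   `c(ny, nx, nz)`, values in `[0, 1]`), `voxel_nm` and `params`.
#' @export
generate_filament_mesh <- function(shape, n_filaments = 20, thickness_voxels = 2,
                                   seed = 1, voxel_nm = 86) {
  stopifnot(length(shape) == 3, n_filaments >= 0, thickness_voxels >= 1)
  if (min(shape) < 16) stop("phantom shape must be at least 16 voxels per axis")
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  vol <- array(0, c(ny, nx, nz))
  r <- thickness_voxels / 2
  ri <- ceiling(r)
  off <- as.matrix(expand.grid(dy = -ri:ri, dx = -ri:ri, dz = -ri:ri))
  off <- off[sqrt(rowSums(off^2)) <= r + 1e-9, , drop = FALSE]
  if (nrow(off) == 0) off <- matrix(0, 1, 3)
  with_local_seed(seed, {
    for (f in seq_len(n_filaments)) {
      pos <- c(stats::runif(1, 2, ny - 1), stats::runif(1, 2, nx - 1),
               stats::runif(1, 2, nz - 1))
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      n_steps <- round(stats::runif(1, 0.8, 2.0) * max(ny, nx, nz) * 2)
      step <- 0.5
      pts <- matrix(0, n_steps, 3)
      for (s in seq_len(n_steps)) {
        dir <- dir + stats::rnorm(3, sd = 0.12)
        dir <- dir / sqrt(sum(dir^2))
        pos <- pos + step * dir
        # reflect at the faces
        lim <- c(ny, nx, nz)
        for (d in 1:3) {
          if (pos[d] < 1) { pos[d] <- 2 - pos[d]; dir[d] <- -dir[d] }
          if (pos[d] > lim[d]) { pos[d] <- 2 * lim[d] - pos[d]; dir[d] <- -dir[d] }
        }
        pts[s, ] <- pos
      }
      ctr <- round(pts)
      for (s in seq_len(nrow(ctr))) {
        vy <- ctr[s, 1] + off[, 1]; vx <- ctr[s, 2] + off[, 2]; vz <- ctr[s, 3] + off[, 3]
        ok <- vy >= 1 & vy <= ny & vx >= 1 & vx <= nx & vz >= 1 & vz <= nz
        vol[cbind(vy[ok], vx[ok], vz[ok])] <- 1
      }
    }
  })
  structure(list(vol = vol, voxel_nm = voxel_nm,
                 params = list(kind = "filament_mesh", shape = shape,
                               n_filaments = n_filaments,
                               thickness_voxels = thickness_voxels, seed = seed)),
            class = "os_phantom")
}

#' Generate a procedural 2D texture
#'
#' Self-contained stand-ins for the diverse natural-image structure used to
#' train reconstruction networks. Three kinds are provided:
#' `"multiscale-noise"` (spectrally broad filtered noise spanning several
#' octaves), `"blobs"` (random Gaussian spots of varied size and weight) and
#' `"filaments-2d"` (dilated 2D random walks). All outputs are min-max
#' normalised to `[0, 1]` and are pure functions of `(shape, seed, kind)`.
#'
#' @param shape `c(ny, nx)` pixel counts.
#' @param seed Integer seed.
#' @param kind One of `"multiscale-noise"`, `"blobs"`, `"filaments-2d"`.
#' @return A `ny` x `nx` matrix with values in `[0, 1]`.
#' @export
generate_texture <- function(shape, seed = 1,
                             kind = c("multiscale-noise", "blobs", "filaments-2d")) {
  kind <- match.arg(kind)
  ny <- shape[1]; nx <- shape[2]
  img <- with_local_seed(seed, {
    switch(kind,
      "multiscale-noise" = {
        acc <- matrix(0, ny, nx)
        for (s in c(1, 2, 4, 8, 16)) {
          noise <- matrix(stats::rnorm(ny * nx), ny, nx)
          acc <- acc + gauss_blur_nearest(noise, s) * sqrt(s)
        }
        acc
      },
      "blobs" = {
        acc <- matrix(0, ny, nx)
        n <- round(ny * nx / 180)
        cy <- stats::runif(n, 1, ny); cx <- stats::runif(n, 1, nx)
        sg <- stats::runif(n, 1, 6); am <- stats::runif(n, 0.3, 1)
        ys <- seq_len(ny); xs <- seq_len(nx)
        for (i in seq_len(n)) {
          acc <- acc + am[i] * outer(exp(-(ys - cy[i])^2 / (2 * sg[i]^2)),
                                     exp(-(xs - cx[i])^2 / (2 * sg[i]^2)))
        }
        acc
      },
      "filaments-2d" = {
        acc <- matrix(0, ny, nx)
        n <- max(3, round(max(ny, nx) / 12))
        for (f in seq_len(n)) {
          pos <- c(stats::runif(1, 2, ny - 1), stats::runif(1, 2, nx - 1))
          ang <- stats::runif(1, 0, 2 * pi)
          for (s in seq_len(round(2.5 * max(ny, nx)))) {
            ang <- ang + stats::rnorm(1, sd = 0.15)
            pos <- pos + 0.5 * c(sin(ang), cos(ang))
            if (pos[1] < 1) { pos[1] <- 2 - pos[1]; ang <- -ang }
            if (pos[1] > ny) { pos[1] <- 2 * ny - pos[1]; ang <- -ang }
            if (pos[2] < 1) { pos[2] <- 2 - pos[2]; ang <- pi - ang }
            if (pos[2] > nx) { pos[2] <- 2 * nx - pos[2]; ang <- pi - ang }
            p <- round(pos)
            acc[p[1], p[2]] <- 1
          }
        }
        gauss_blur_nearest(acc, 0.8)
      })
  })
  rng <- range(img)
  if (diff(rng) < .Machine$double.eps) return(matrix(0, ny, nx))
  (img - rng[1]) / diff(rng)
}

#' Generate a three-frame moving-object scene
#'
#' Produces three sequential ground-truth in-focus frames in which a set of
#' rigid objects (Gaussian spots and soft discs) translate with constant
#' per-object velocity: frame k is frame k-1 with each object moved by its
#' velocity vector. Velocities are drawn with uniformly random direction and
#' speed in `[0, max_displacement]` pixels/frame; sub-pixel motion is
#' applied by Fourier translation so displacements below the pixel pitch
#' are representable.
#'
#' @param shape `c(ny, nx)` pixel counts.
#' @param n_objects Number of moving objects.
#' @param max_displacement Maximum per-frame displacement magnitude, pixels.
#' @param seed Integer seed.
#' @return An object of class `os_triplet`: list with `frames` (list of 3
#'   matrices in `[0, 1]`), `velocities` (`n_objects` x 2 matrix, dy/dx
#'   pixels per frame) and `params`.
#' @export
generate_moving_triplet <- function(shape, n_objects = 6, max_displacement = 2,
                                    seed = 1) {
  stopifnot(max_displacement >= 0, n_objects >= 1)
  ny <- shape[1]; nx <- shape[2]
  res <- with_local_seed(seed, {
    ys <- seq_len(ny); xs <- seq_len(nx)
    objs <- vector("list", n_objects)
    vel <- matrix(0, n_objects, 2)
    for (i in seq_len(n_objects)) {
      cy <- stats::runif(1, 0.15 * ny, 0.85 * ny)
      cx <- stats::runif(1, 0.15 * nx, 0.85 * nx)
      amp <- stats::runif(1, 0.5, 1)
      if (stats::runif(1) < 0.5) {
        sg <- stats::runif(1, 2, 5)
        img <- amp * outer(exp(-(ys - cy)^2 / (2 * sg^2)),
                           exp(-(xs - cx)^2 / (2 * sg^2)))
      } else {
        rad <- stats::runif(1, 3, 7)
        d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
        img <- amp / (1 + exp((d - rad) / 0.8))  # soft-edged disc
      }
      objs[[i]] <- img
      ang <- stats::runif(1, 0, 2 * pi)
      spd <- stats::runif(1, 0, max_displacement)
      vel[i, ] <- spd * c(sin(ang), cos(ang))
    }
    frames <- lapply(0:2, function(k) {
      acc <- matrix(0, ny, nx)
      for (i in seq_len(n_objects)) {
        acc <- acc + fourier_translate(objs[[i]], k * vel[i, 1], k * vel[i, 2])
      }
      acc[acc < 0] <- 0
      acc[acc > 1] <- 1
      acc
    })
    list(frames = frames, velocities = vel)
  })
  structure(list(frames = res$frames, velocities = res$velocities,
                 params = list(shape = shape, n_objects = n_objects,
                               max_displacement = max_displacement, seed = seed)),
            class = "os_triplet")
}
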
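# TIFF + JSON-sidecar I/O for raw stacks, YAML run configuration, and the
# command-line surface. Stacks are written as multi-page float32 TIFF with
# an explicit page-order layout; every artefact carries enough sidecar
# metadata to regenerate it bit-exactly.

# Minimal multi-page float32 TIFF writer (little-endian, uncompressed, one
# strip per page). The tiff package reads IEEE-float TIFFs but quantises
# 32-bit *output* to integers, which would break bit-exact round trips, so
# the canonical float32 format is written directly here.
write_float_tiff <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeBin(charToRaw("II"), con)
  w16(42)
  n <- length(pages)
  # per page: pixel data block followed by its IFD
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  pos <- 8L  # first data block starts right after the header
  offsets <- vector("list", n)
  for (i in seq_len(n)) {
    h <- nrow(pages[[i]]); w <- ncol(pages[[i]])
    nbytes <- 4L * h * w
    offsets[[i]] <- c(data = pos, ifd = pos + nbytes)
    pos <- pos + nbytes + ifd_size
  }
  w32(offsets[[1]]["ifd"])
  tag <- function(id, type, count, value) {
    w16(id); w16(type); w32(count)
    if (type == 3 && count == 1) { w16(value); w16(0) } else w32(value)
  }
  for (i in seq_len(n)) {
    p <- pages[[i]]
    h <- nrow(p); w <- ncol(p)
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
    w16(n_tags)
    tag(256, 3, 1, w)             # ImageWidth
    tag(257, 3, 1, h)             # ImageLength
    tag(258, 3, 1, 32)            # BitsPerSample
    tag(259, 3, 1, 1)             # Compression: none
    tag(262, 3, 1, 1)             # Photometric: BlackIsZero
    tag(273, 4, 1, offsets[[i]]["data"])  # StripOffsets
    tag(277, 3, 1, 1)             # SamplesPerPixel
    tag(278, 3, 1, h)             # RowsPerStrip
    tag(279, 4, 1, 4 * h * w)     # StripByteCounts
    tag(339, 3, 1, 3)             # SampleFormat: IEEE float
    w32(if (i < n) offsets[[i + 1]]["ifd"] else 0)
  }
  invisible(path)
}

parse_layout <- function(layout) {
  axes <- trimws(strsplit(layout, ",")[[1]])
  if (!"phase" %in% axes || !all(axes %in% c("z", "phase")) ||
      anyDuplicated(axes)) {
    stop("layout must be a comma-separated list of page axes from slowest ",
         "to fastest, containing 'phase' and optionally 'z' (e.g. \"z,phase\")")
  }
  axes
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a stack as multi-page float32 TIFF with a JSON sidecar
#'
#' Pages are ordered with phase varying fastest (layout `"z,phase"`) and
#' stored as uncompressed IEEE float32, so values round-trip bit-exactly at
#' float32 precision. The sidecar records the layout, pattern, optics,
#' noise model, pixel size and all provenance in `meta` (seeds, generator
#' parameters) — enough to regenerate the stack from scratch.
#'
#' @param stack An [os_stack()].
#' @param path Output TIFF path; the sidecar goes to `paste0(path, ".json")`.
#' @param force Overwrite an existing file (default FALSE: refuse).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, force = FALSE) {
  stopifnot(inherits(stack, "os_stack"))
  if (file.exists(path) && !force) {
    stop("refusing to overwrite existing file ", path, " (use force = TRUE)")
  }
  d <- dim(stack$frames)
  pages <- list()
  for (z in seq_len(d[4])) {
    for (p in 1:3) {
      pages[[length(pages) + 1]] <- stack$frames[, , p, z]
    }
  }
  write_float_tiff(pages, path)
  meta <- list(
    layout = "z,phase", dim = d,
    pixel_size_nm = stack$pixel_size_nm,
    pattern = unclass(stack$pattern),
    optics = unclass(stack$optics),
    noise = unclass(stack$noise),
    meta = stack$meta
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-page TIFF as an OS-SIM stack
#'
#' The page order is never inferred: either an explicit `layout`
#' declaration (axes from slowest to fastest, e.g. `"z,phase"` for
#' phase-fastest pages) or a sidecar written by [write_stack()] must state
#' it. Integer TIFF data (8/16-bit) are promoted to floating point without
#' rescaling; sidecar metadata (scale factor, pattern, optics, noise) is
#' restored when present.
#'
#' @param path TIFF file path.
#' @param layout Page-order declaration; `NULL` to take it from the
#'   sidecar.
#' @return An [os_stack()].
#' @export
read_stack <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("cannot read ", path, ": no such file")
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  if (is.null(layout)) {
    layout <- meta$layout
    if (is.null(layout)) {
      stop("no layout declared and no sidecar found; pass layout= explicitly")
    }
  }
  axes <- parse_layout(layout)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample") %||% 32
  fmt <- attr(pages[[1]], "sample.format") %||% "uint"
  if (bits < 32 && !identical(fmt, "float")) {
    # integer data: promote to floating point without rescaling
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) p * 1.0)
  }
  n <- length(pages)
  if (n %% 3 != 0) {
    stop("page count ", n, " is not a multiple of 3 (three phase frames ",
         "per plane are required)")
  }
  nz <- n %/% 3
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  frames <- array(0, c(ny, nx, 3, nz))
  for (i in seq_len(n)) {
    i0 <- i - 1L
    if (identical(axes, c("z", "phase")) || identical(axes, "phase")) {
      p <- i0 %% 3L + 1L; z <- i0 %/% 3L + 1L
    } else {  # c("phase", "z"): z fastest
      z <- i0 %% nz + 1L; p <- i0 %/% nz + 1L
    }
    frames[, , p, z] <- pages[[i]]
  }
  scale <- meta$scale %||% 1
  pattern <- NULL
  if (!is.null(meta$pattern)) {
    pattern <- do.call(sinusoidal_pattern, meta$pattern[c("frequency",
      "orientation", "modulation", "phase_offsets")])
  }
  optics <- NULL
  if (!is.null(meta$optics)) {
    optics <- optical_config(meta$optics$na, meta$optics$lambda_em_nm,
                             meta$optics$lambda_ex_nm, meta$optics$ri,
                             unlist(meta$optics$voxel_nm))
  }
  noise <- NULL
  if (!is.null(meta$noise) && length(meta$noise)) {
    noise <- noise_model(meta$noise$eta, meta$noise$gaussian_sigma,
                         meta$noise$photon_scale, meta$noise$peak_intensity_norm)
  }
  os_stack(frames * scale, pattern = pattern, optics = optics, noise = noise,
           pixel_size_nm = meta$pixel_size_nm %||% 86,
           meta = if (is.null(meta$meta)) list() else meta$meta)
}

# --- run configuration -----------------------------------------------------

check_keys <- function(block, allowed, name) {
  extra <- setdiff(names(block), allowed)
  if (length(extra)) {
    stop("unknown key(s) in '", name, "' block: ", paste(extra, collapse = ", "))
  }
}

#' Read and validate a YAML run configuration
#'
#' Recognised blocks: `optics` (na, lambda_em_nm, lambda_ex_nm, ri,
#' voxel_nm), `pattern` (frequency — a number or `"optimal"` —,
#' orientation, modulation, phase_offsets), `noise` (eta, gaussian_sigma),
#' `phantom` (kind, shape, n_filaments, thickness_voxels), `reconstruction`
#' (method, alpha), `training` (epochs, batch_size, learning_rate,
#' n_static, n_moving), `evaluation` (eta_grid, n_replicates, mip_slices,
#' n_scenes, max_displacement) and a global `seed`. Unknown keys anywhere
#' are rejected, and each block is validated by constructing the
#' corresponding package object before any computation runs.
#'
#' @param path YAML file path.
#' @return A list with the constructed `optics`, `pattern`, `noise`
#'   objects (where present), the raw validated blocks, and `seed`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys(raw, c("optics", "pattern", "noise", "phantom", "reconstruction",
                    "training", "evaluation", "seed"), "top level")
  out <- list(seed = raw$seed %||% 1)
  if (!is.null(raw$optics)) {
    check_keys(raw$optics, c("na", "lambda_em_nm", "lambda_ex_nm", "ri",
                             "voxel_nm"), "optics")
    out$optics <- do.call(optical_config, raw$optics)
  }
  if (!is.null(raw$pattern)) {
    check_keys(raw$pattern, c("frequency", "orientation", "modulation",
                              "phase_offsets"), "pattern")
    freq <- raw$pattern$frequency %||% "optimal"
    if (identical(freq, "optimal")) {
      if (is.null(out$optics)) stop("pattern frequency 'optimal' needs an optics block")
      freq <- optimal_pattern_frequency(out$optics)
    }
    out$pattern <- sinusoidal_pattern(
      freq, raw$pattern$orientation %||% 0, raw$pattern$modulation %||% 0.9,
      unlist(raw$pattern$phase_offsets) %||% (2 * (0:2) * pi / 3))
  }
  if (!is.null(raw$noise)) {
    check_keys(raw$noise, c("eta", "gaussian_sigma"), "noise")
    out$noise <- noise_model(raw$noise$eta, raw$noise$gaussian_sigma %||% 1)
  }
  if (!is.null(raw$phantom)) {
    check_keys(raw$phantom, c("kind", "shape", "n_filaments",
                              "thickness_voxels"), "phantom")
  }
  if (!is.null(raw$reconstruction)) {
    check_keys(raw$reconstruction, c("method", "alpha"), "reconstruction")
  }
  if (!is.null(raw$training)) {
    check_keys(raw$training, c("epochs", "batch_size", "learning_rate",
                               "n_static", "n_moving"), "training")
  }
  if (!is.null(raw$evaluation)) {
    check_keys(raw$evaluation, c("eta_grid", "n_replicates", "mip_slices",
                                 "n_scenes", "max_displacement"), "evaluation")
  }
  out$blocks <- raw
  out
}

# --- command line ----------------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: ossim <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate phantom --config c.yaml --seed N --out out.tif [--force]",
    "  simulate stack   --config c.yaml --seed N --out out.tif [--force]",
    "  simulate volume  --config c.yaml --seed N --out out.tif [--force]",
    "  simulate phantom also accepts --kind multiscale-noise|blobs|filaments-2d",
    "  reconstruct --method sd|corrected|filtered|widefield [--alpha A]",
    "              [--pattern-freq F] [--layout L] [--force] in.tif out.tif",
    "  train --config c.yaml --seed N --out checkpoint.rds",
    "  evaluate sweep|motion --config c.yaml --seed N --out out.csv",
    "",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  flags <- list()
  pos <- character(0)
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (key %in% c("force")) {
        flags[[key]] <- TRUE
        i <- i + 1
      } else {
        if (i == length(argv)) stop("flag --", key, " needs a value")
        flags[[key]] <- argv[i + 1]
        i <- i + 2
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1
    }
  }
  list(flags = flags, pos = pos)
}

write_image_tiff <- function(img, path, force = FALSE) {
  if (file.exists(path) && !force) {
    stop("refusing to overwrite existing file ", path, " (use force = TRUE)")
  }
  pages <- if (length(dim(img)) == 2) list(img) else
    lapply(seq_len(dim(img)[3]), function(z) img[, , z])
  write_float_tiff(pages, path)
  jsonlite::write_json(list(dim = dim(img)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an image or volume as float32 TIFF
#'
#' Exports a matrix, a `c(ny, nx, nz)` array, or an `os_psf`/`os_phantom`
#' object (their `vol`) as uncompressed multi-page IEEE float32 TIFF with a
#' small JSON sidecar recording the dimensions.
#'
#' @param x Matrix, 3D array, `os_psf` or `os_phantom`.
#' @param path Output path.
#' @param force Overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(x, path, force = FALSE) {
  if (inherits(x, "os_psf") || inherits(x, "os_phantom")) x <- x$vol
  write_image_tiff(x, path, force)
}

cli_simulate <- function(what, flags) {
  cfg <- read_run_config(flags$config %||% stop("--config is required"))
  seed <- as.integer(flags$seed %||% cfg$seed)
  out <- flags$out %||% stop("--out is required")
  force <- isTRUE(flags$force)
  optics <- cfg$optics %||% optical_config(1.2, 600, 488, 1.33, 86)
  pattern <- cfg$pattern %||%
    sinusoidal_pattern(optimal_pattern_frequency(optics), 0.3, 0.9)
  ph_block <- cfg$blocks$phantom %||% list()
  if (what == "phantom") {
    kind <- flags$kind %||% ph_block$kind %||% "filament_mesh"
    if (kind == "filament_mesh") {
      ph <- generate_filament_mesh(unlist(ph_block$shape) %||% c(32, 64, 64),
                                   ph_block$n_filaments %||% 15,
                                   ph_block$thickness_voxels %||% 2,
                                   seed = seed, voxel_nm = optics$voxel_nm[1])
      write_image_tiff(ph$vol, out, force)
    } else {
      img <- generate_texture(unlist(ph_block$shape) %||% c(128, 128),
                              seed = seed, kind = kind)
      write_image_tiff(img, out, force)
    }
    message("wrote phantom (", kind, ", seed ", seed, ") to ", out)
    return(0L)
  }
  if (what == "stack") {
    shp <- unlist(ph_block$shape) %||% c(128, 128)
    shp <- utils::tail(shp, 2)
    in_focus <- generate_texture(shp, derive_seed(seed, "in_focus"),
                                 ph_block$kind %||% "multiscale-noise")
    oof <- generate_texture(shp, derive_seed(seed, "out_focus"), "blobs")
    psf_in <- defocused_psf_plane(optics, c(33, 33), 0)
    psf_out <- defocused_psf_plane(optics, c(33, 33), 1500)
    stack <- simulate_stack(in_focus, psf_in, pattern, out_of_focus = oof,
                            psf_out = psf_out, oof_weight = 0.5,
                            pixel_size_nm = optics$voxel_nm[3], config = optics)
  } else {
    ph <- generate_filament_mesh(unlist(ph_block$shape) %||% c(32, 64, 64),
                                 ph_block$n_filaments %||% 15,
                                 ph_block$thickness_voxels %||% 2,
                                 seed = derive_seed(seed, "phantom"),
                                 voxel_nm = optics$voxel_nm[1])
    stack <- simulate_volume_scan(ph, optics, pattern)
  }
  if (!is.null(cfg$noise)) {
    stack <- add_noise(stack, cfg$noise, derive_seed(seed, "noise"))
  }
  stack$meta$seed <- seed
  write_stack(stack, out, force)
  message("wrote ", what, " (seed ", seed, ") to ", out)
  0L
}

cli_reconstruct <- function(flags, pos) {
  if (length(pos) != 2) stop("reconstruct needs input and output paths")
  method <- flags$method %||% "sd"
  if (!method %in% c("sd", "corrected", "filtered", "widefield")) {
    stop("unknown method: ", method)
  }
  stack <- read_stack(pos[1], layout = flags$layout)
  if (!is.null(flags[["pattern-freq"]]) && is.null(stack$pattern)) {
    stack$pattern <- sinusoidal_pattern(as.numeric(flags[["pattern-freq"]]))
  }
  args <- list(stack = stack, method = method)
  if (!is.null(flags$alpha) && method == "filtered") {
    est <- estimate_pattern_parameters(stack)
    args <- list(stack = stack, method = method,
                 params = hilo_params(as.numeric(flags$alpha),
                                      est$frequency / 2, 0.1 * est$frequency))
  }
  rec <- do.call(reconstruct, args)
  if (!is.null(rec$pattern_estimate)) {
    message("pattern estimate: nu = ", round(rec$pattern_estimate$frequency, 4),
            " cycles/um, phases = ",
            paste(round(rec$pattern_estimate$phases, 3), collapse = ", "))
  }
  img <- rec$image
  if (is.matrix(img)) dim(img) <- c(dim(img), 1)
  write_image_tiff(drop_z(img), pos[2], isTRUE(flags$force))
  message("wrote ", method, " reconstruction to ", pos[2])
  0L
}

cli_train <- function(flags) {
  cfg <- read_run_config(flags$config %||% stop("--config is required"))
  seed <- as.integer(flags$seed %||% cfg$seed)
  out <- flags$out %||% stop("--out is required")
  tr <- cfg$blocks$training %||% list()
  gen <- training_generator_config(shape = c(32, 32))
  ds <- generate_training_set(tr$n_static %||% 24, tr$n_moving %||% 0, gen,
                              seed = derive_seed(seed, "data"))
  model <- build_rcan(rcan_config(n_groups = 1, blocks_per_group = 2,
                                  n_filters = 8, ca_reduction = 4),
                      seed = derive_seed(seed, "init"))
  fit <- train_network(model, ds,
                       train_config(epochs = tr$epochs %||% 20,
                                    batch_size = tr$batch_size %||% 4,
                                    learning_rate = tr$learning_rate %||% 1e-3,
                                    seed = derive_seed(seed, "train")))
  # checkpoint: weights + full config + seeds (runtime artefact)
  saveRDS(list(kind = fit$model$kind, config = fit$model$config,
               weights = lapply(ossim_params(fit), function(p) p$v),
               history = fit$history, seed = seed), out)
  message("trained ", fit$model$kind, " (final loss ",
          format(utils::tail(fit$history$loss, 1), digits = 4),
          "); checkpoint at ", out)
  0L
}

ossim_params <- function(fit) collect_params(fit$model$layers)

cli_evaluate <- function(what, flags) {
  cfg <- read_run_config(flags$config %||% stop("--config is required"))
  seed <- as.integer(flags$seed %||% cfg$seed)
  out <- flags$out %||% stop("--out is required")
  ev <- cfg$blocks$evaluation %||% list()
  optics <- cfg$optics %||% optical_config(1.2, 600, 488, 1.33, 86)
  if (what == "sweep") {
    res <- noise_sweep(eta_grid = unlist(ev$eta_grid) %||% c(2e-5, 1e-4, 5e-4),
                       n_replicates = ev$n_replicates %||% 2,
                       seed = seed, config = optics,
                       shape = unlist(cfg$blocks$phantom$shape) %||% c(60, 96, 96),
                       mip_slices = ev$mip_slices %||% 50)
  } else {
    res <- motion_benchmark(n_scenes = ev$n_scenes %||% 8,
                            max_displacement = ev$max_displacement %||% 2,
                            seed = seed, config = optics)
  }
  utils::write.csv(tibble::as_tibble(res), out, row.names = FALSE)
  message("wrote ", what, " results (seed ", seed, ") to ", out)
  0L
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `reconstruct` and `evaluate` subcommands (see
#' the shipped `inst/cli/ossim.R` wrapper for shell use). Returns the exit
#' code rather than quitting, so the interface is testable in-process:
#' 0 on success, 2 for usage/configuration errors, 1 for runtime failures.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code, invisibly.
#' @export
cli_main <- function(argv) {
  if (length(argv) < 1 || argv[1] %in% c("-h", "--help", "help")) {
    cat(cli_usage())
    return(invisible(if (length(argv) < 1) 2L else 0L))
  }
  sub <- argv[1]
  if (!sub %in% c("simulate", "reconstruct", "train", "evaluate")) {
    cat(cli_usage())
    message("unknown subcommand: ", sub)
    return(invisible(2L))
  }
  rest <- argv[-1]
  code <- tryCatch({
    if (sub == "simulate") {
      what <- rest[1]
      if (is.na(what) || !what %in% c("phantom", "stack", "volume")) {
        message("simulate needs one of: phantom, stack, volume")
        return(invisible(2L))
      }
      pa <- parse_cli_args(rest[-1])
      cli_simulate(what, pa$flags)
    } else if (sub == "reconstruct") {
      pa <- parse_cli_args(rest)
      cli_reconstruct(pa$flags, pa$pos)
    } else if (sub == "train") {
      pa <- parse_cli_args(rest)
      cli_train(pa$flags)
    } else {
      what <- rest[1]
      if (is.na(what) || !what %in% c("sweep", "motion")) {
        message("evaluate needs one of: sweep, motion")
        return(invisible(2L))
      }
      pa <- parse_cli_args(rest[-1])
      cli_evaluate(what, pa$flags)
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    bad_config <- grepl("unknown key|--config|--out|layout|unknown method|unknown subcommand",
                        conditionMessage(e))
    if (bad_config) 2L else 1L
  })
  invisible(as.integer(code))
}
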
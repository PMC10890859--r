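# Learned OS-SIM reconstruction: a residual channel attention network (RCAN)
# for fast reconstruction and a windowed-attention video network (VSR) that
# consumes the three phase frames jointly for motion robustness. Both map 3
# raw frames to 1 sectioned frame and are fully scalable via their configs.

#' RCAN architecture configuration
#'
#' The reference configuration is three groups of ten residual channel
#' attention blocks (RCABs), 96 filters with 3x3 body kernels and a 7x7
#' learnable head; tests and examples use much smaller configurations,
#' which train in minutes on a CPU.
#'
#' @param n_groups Number of residual groups.
#' @param blocks_per_group RCABs per group.
#' @param n_filters Channels throughout the body.
#' @param body_kernel Odd kernel size of body convolutions.
#' @param head_kernel Odd kernel size of the head convolution.
#' @param ca_reduction Channel-attention bottleneck reduction ratio.
#' @param n_in,n_out Input/output frame counts (3 phase frames in, 1
#'   sectioned frame out).
#' @return An object of class `os_rcan_config`.
#' @export
rcan_config <- function(n_groups = 3, blocks_per_group = 10, n_filters = 96,
                        body_kernel = 3, head_kernel = 7, ca_reduction = 16,
                        n_in = 3, n_out = 1) {
  stopifnot(n_groups >= 1, blocks_per_group >= 1, n_filters >= 1)
  if (body_kernel %% 2 == 0 || head_kernel %% 2 == 0) {
    stop("kernel sizes must be odd")
  }
  structure(list(n_groups = n_groups, blocks_per_group = blocks_per_group,
                 n_filters = n_filters, body_kernel = body_kernel,
                 head_kernel = head_kernel, ca_reduction = ca_reduction,
                 n_in = n_in, n_out = n_out),
            class = "os_rcan_config")
}

#' VSR architecture configuration
#'
#' A sequence of windowed channel attention blocks (WCABs): each WCAB is a
#' stack of windowed multi-head self-attention transformer layers (the
#' window partition cyclically shifted on alternate layers) followed by one
#' RCAB for channel attention.
#'
#' @param n_wcabs Number of WCABs.
#' @param swin_per_wcab Attention layers per WCAB.
#' @param window_size Attention window side length (must divide the
#'   processed patch size).
#' @param n_heads Attention heads (must divide `embed_dim`).
#' @param embed_dim Feature width.
#' @param mlp_ratio Width multiplier of the per-layer MLP.
#' @param ca_reduction Channel-attention reduction in the RCABs.
#' @param n_in,n_out Input/output frame counts.
#' @return An object of class `os_vsr_config`.
#' @export
vsr_config <- function(n_wcabs = 5, swin_per_wcab = 2, window_size = 8,
                       n_heads = 4, embed_dim = 48, mlp_ratio = 2,
                       ca_reduction = 16, n_in = 3, n_out = 1) {
  stopifnot(n_wcabs >= 1, swin_per_wcab >= 1, window_size >= 2)
  if (embed_dim %% n_heads != 0) stop("embed_dim must be divisible by n_heads")
  structure(list(n_wcabs = n_wcabs, swin_per_wcab = swin_per_wcab,
                 window_size = window_size, n_heads = n_heads,
                 embed_dim = embed_dim, mlp_ratio = mlp_ratio,
                 ca_reduction = ca_reduction, n_in = n_in, n_out = n_out),
            class = "os_vsr_config")
}

make_rcab <- function(nf, reduction) {
  rd <- max(1L, nf %/% reduction)
  list(conv1 = make_conv_layer(nf, nf, 3),
       conv2 = make_conv_layer(nf, nf, 3),
       ca1 = make_conv_layer(nf, rd, 1),
       ca2 = make_conv_layer(rd, nf, 1))
}

# RCAB: two convolutions, channel attention from globally pooled features
# through a bottleneck (two 1x1 convolutions, sigmoid gate), residual skip.
rcab_forward <- function(x, blk, geom, geom1, use_attention = TRUE) {
  t <- tn_conv2d(tn_relu(tn_conv2d(x, blk$conv1$w, blk$conv1$b, geom)),
                 blk$conv2$w, blk$conv2$b, geom)
  if (use_attention) {
    pooled <- tn_colmeans(t)
    a <- tn_sigmoid(tn_conv2d(tn_relu(tn_conv2d(pooled, blk$ca1$w, blk$ca1$b, geom1)),
                              blk$ca2$w, blk$ca2$b, geom1))
    t <- tn_rowscale(t, a)
  }
  tn_add(x, t)
}

#' Build an RCAN reconstruction model
#'
#' Head convolution with large learnable filters, `n_groups` residual
#' groups of RCABs (each group closed by a convolution and a group skip),
#' a global residual connection, and a reconstruction convolution back to
#' one frame. Output spatial shape equals input spatial shape.
#'
#' @param config An [rcan_config()].
#' @param seed Seed for weight initialisation.
#' @return An object of class `os_model` (kind `"rcan"`).
#' @seealso [train_network()], [reconstruct_ml()], [count_parameters()]
#' @export
build_rcan <- function(config, seed = 1) {
  stopifnot(inherits(config, "os_rcan_config"))
  layers <- with_local_seed(seed, {
    nf <- config$n_filters
    list(
      head = make_conv_layer(config$n_in, nf, config$head_kernel),
      groups = lapply(seq_len(config$n_groups), function(g) {
        list(blocks = lapply(seq_len(config$blocks_per_group), function(b) {
               make_rcab(nf, config$ca_reduction)
             }),
             tail = make_conv_layer(nf, nf, config$body_kernel))
      }),
      recon = make_conv_layer(nf, config$n_out, config$body_kernel)
    )
  })
  structure(list(kind = "rcan", config = config, layers = layers,
                 init_seed = seed),
            class = "os_model")
}

#' Build a VSR (windowed-attention video) reconstruction model
#'
#' The three phase frames are embedded into a feature map, passed through
#' `n_wcabs` windowed channel attention blocks — windowed multi-head
#' self-attention transformer layers whose window partition is cyclically
#' shifted on alternate layers so information crosses window boundaries,
#' each followed by a residual channel attention block — and fused into a
#' single reconstructed frame.
#'
#' @param config A [vsr_config()].
#' @param seed Seed for weight initialisation.
#' @return An object of class `os_model` (kind `"vsr"`).
#' @export
build_vsr <- function(config, seed = 1) {
  stopifnot(inherits(config, "os_vsr_config"))
  layers <- with_local_seed(seed, {
    C <- config$embed_dim
    list(
      embed = make_conv_layer(config$n_in, C, 3),
      wcabs = lapply(seq_len(config$n_wcabs), function(i) {
        list(swin = lapply(seq_len(config$swin_per_wcab), function(l) {
               list(ln1g = nn_param(matrix(1, 1, C)),
                    ln1b = nn_param(matrix(0, 1, C)),
                    qkv = make_linear_layer(C, 3 * C),
                    proj = make_linear_layer(C, C),
                    ln2g = nn_param(matrix(1, 1, C)),
                    ln2b = nn_param(matrix(0, 1, C)),
                    fc1 = make_linear_layer(C, config$mlp_ratio * C),
                    fc2 = make_linear_layer(config$mlp_ratio * C, C),
                    shifted = (l %% 2 == 0))
             }),
             rcab = make_rcab(C, config$ca_reduction))
      }),
      fusion = make_conv_layer(C, config$n_out, 3)
    )
  })
  structure(list(kind = "vsr", config = config, layers = layers,
                 init_seed = seed),
            class = "os_model")
}

#' @export
print.os_model <- function(x, ...) {
  cat("<os_model>", x$kind, "-", format(count_parameters(x), big.mark = ","),
      "trainable parameters\n")
  invisible(x)
}

#' Count trainable parameters of a model
#'
#' @param model An `os_model` or `os_trained_model`.
#' @return Integer total of all weight and bias entries.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "os_trained_model")) model <- model$model
  sum(vapply(collect_params(model$layers), function(p) length(p$v), numeric(1)))
}

perm_cache <- new.env(parent = emptyenv())

get_window_permutation <- function(H, W, ws, shift) {
  key <- paste(H, W, ws, shift, sep = "x")
  p <- perm_cache[[key]]
  if (is.null(p)) {
    p <- window_permutation(H, W, ws, shift)
    perm_cache[[key]] <- p
  }
  p
}

# Forward pass producing the output tensor; x is (H*W) x n_in, column-major
# pixel order.
model_forward <- function(model, x, H, W, use_shift = TRUE) {
  cfg <- model$config
  L <- model$layers
  if (model$kind == "rcan") {
    geom_h <- get_conv_geometry(H, W, cfg$head_kernel)
    geom_b <- get_conv_geometry(H, W, cfg$body_kernel)
    geom_1 <- get_conv_geometry(1, 1, 1)
    h0 <- tn_conv2d(x, L$head$w, L$head$b, geom_h)
    b <- h0
    for (grp in L$groups) {
      gin <- b
      for (blk in grp$blocks) b <- rcab_forward(b, blk, geom_b, geom_1)
      b <- tn_add(gin, tn_conv2d(b, grp$tail$w, grp$tail$b, geom_b))
    }
    return(tn_conv2d(tn_add(b, h0), L$recon$w, L$recon$b, geom_b))
  }
  # vsr
  ws <- cfg$window_size
  if (H %% ws != 0 || W %% ws != 0) {
    stop("window size ", ws, " must divide the patch size; pad the input to ",
         ws * ceiling(H / ws), " x ", ws * ceiling(W / ws))
  }
  geom3 <- get_conv_geometry(H, W, 3)
  geom_1 <- get_conv_geometry(1, 1, 1)
  nwin <- (H %/% ws) * (W %/% ws)
  wt <- ws * ws
  e <- tn_conv2d(x, L$embed$w, L$embed$b, geom3)
  b <- e
  for (wcab in L$wcabs) {
    for (ly in wcab$swin) {
      sh <- if (use_shift && ly$shifted) ws %/% 2 else 0
      perm <- get_window_permutation(H, W, ws, sh)
      xa <- tn_layernorm(b, ly$ln1g, ly$ln1b)
      qkv <- tn_permute_rows(apply_linear(xa, ly$qkv), perm)
      att <- tn_window_attention(qkv, nwin, wt, cfg$n_heads)
      att <- tn_permute_rows(att, order(perm))
      b <- tn_add(b, apply_linear(att, ly$proj))
      xm <- tn_layernorm(b, ly$ln2g, ly$ln2b)
      b <- tn_add(b, apply_linear(tn_gelu(apply_linear(xm, ly$fc1)), ly$fc2))
    }
    b <- rcab_forward(b, wcab$rcab, geom3, geom_1)
  }
  tn_conv2d(tn_add(b, e), L$fusion$w, L$fusion$b, geom3)
}

# --- training --------------------------------------------------------------

#' Training schedule configuration
#'
#' Adam optimisation with an L2-to-L1 loss switch: mean squared error for
#' the first half of the epochs, mean absolute error for the second half
#' (the L1 phase sharpens reconstructions once the bulk intensity mapping
#' has been learned). Epoch count must be even for the half-way switch.
#'
#' @param epochs Total epochs (even).
#' @param batch_size Examples per optimisation step.
#' @param learning_rate Adam learning rate.
#' @param seed Seed controlling shuffling (and any other training
#'   randomness).
#' @return An object of class `os_train_config`.
#' @export
train_config <- function(epochs = 20, batch_size = 4, learning_rate = 1e-4,
                         seed = 1) {
  if (epochs %% 2 != 0) stop("epochs must be even for the half-way loss switch")
  stopifnot(batch_size >= 1, learning_rate > 0)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = seed),
            class = "os_train_config")
}

#' Generate a randomised training set
#'
#' Draws `n_static` static examples and `n_moving` moving-scene examples
#' from the randomised forward simulator (see [make_training_example()]).
#' Moving examples use a three-frame moving scene as the in-focus planes of
#' the phase-stepped acquisition; their supervised target is the sectioned
#' second frame.
#'
#' @param n_static,n_moving Example counts (the reference mix for the video
#'   network is 2000 static / 3000 moving; scale to taste).
#' @param generator A [training_generator_config()]; its `mode` is
#'   overridden per example.
#' @param seed Integer seed; the set is reproducible from it.
#' @return List of `os_training_example`, static examples first, with
#'   attribute `n_static`/`n_moving`.
#' @export
generate_training_set <- function(n_static, n_moving,
                                  generator = training_generator_config(),
                                  seed = 1) {
  gs <- generator; gs$mode <- "static"
  gm <- generator; gm$mode <- "video"
  out <- vector("list", n_static + n_moving)
  for (i in seq_len(n_static)) {
    out[[i]] <- make_training_example(gs, derive_seed(seed, paste0("static", i)))
  }
  for (i in seq_len(n_moving)) {
    out[[n_static + i]] <-
      make_training_example(gm, derive_seed(seed, paste0("moving", i)))
  }
  attr(out, "n_static") <- n_static
  attr(out, "n_moving") <- n_moving
  out
}

# joint 1st/99th percentile normalisation of the three raw frames; the same
# scaling is used at inference time.
normalize_input_frames <- function(frames) {
  q <- stats::quantile(frames, c(0.01, 0.99), names = FALSE)
  if (diff(q) <= 0) q <- range(frames) + c(0, .Machine$double.eps)
  x <- (frames - q[1]) / (q[2] - q[1])
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

prepare_example <- function(ex) {
  frames <- if (inherits(ex$input, "os_stack")) ex$input$frames[, , , 1] else ex$input
  H <- dim(frames)[1]; W <- dim(frames)[2]
  xn <- normalize_input_frames(frames)
  xmat <- matrix(xn, H * W, 3)
  tmat <- matrix(percentile_norm(ex$target), H * W, 1)
  list(x = xmat, t = tmat, H = H, W = W)
}

#' Train a reconstruction model
#'
#' Adam optimisation over the dataset with the [train_config()] schedule:
#' per-epoch mean training loss is recorded, the loss switches from MSE to
#' L1 exactly at the half-way epoch, and parameters are snapshotted each
#' epoch so that a diverging run (non-finite loss) aborts cleanly at the
#' last good state. Fully deterministic for a fixed (model seed, data,
#' config seed) triple.
#'
#' @param model An `os_model` from [build_rcan()] or [build_vsr()]
#'   (modified in place and returned).
#' @param dataset List of training examples ([generate_training_set()] or
#'   `make_training_example()` output).
#' @param config An [train_config()].
#' @return An object of class `os_trained_model`: list with `model`,
#'   `history` (tibble: epoch, loss, loss_fn), `config` and `diverged`.
#' @export
train_network <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "os_model"), length(dataset) >= 1)
  if (length(dataset) < config$batch_size) {
    stop("dataset must contain at least batch_size examples")
  }
  prep <- lapply(dataset, prepare_example)
  params <- collect_params(model$layers)
  state <- adam_state(params)
  tstep <- 0
  n <- length(prep)
  half <- config$epochs %/% 2
  hist_loss <- numeric(0)
  hist_fn <- character(0)
  snapshot <- lapply(params, function(p) p$v)
  diverged <- FALSE
  for (epoch in seq_len(config$epochs)) {
    loss_name <- if (epoch <= half) "mse" else "l1"
    lfun <- if (loss_name == "mse") tn_mse else tn_l1
    ord <- with_local_seed(derive_seed(config$seed, paste0("epoch", epoch)),
                           sample.int(n))
    epoch_losses <- numeric(0)
    for (start in seq(1, n, by = config$batch_size)) {
      ids <- ord[start:min(start + config$batch_size - 1, n)]
      losses <- lapply(ids, function(i) {
        p <- prep[[i]]
        out <- model_forward(model, nn_const(p$x), p$H, p$W)
        lfun(out, p$t)
      })
      loss <- tn_add_scalar_list(losses)
      nn_backward(loss)
      tstep <- tstep + 1
      state <- adam_step(params, state, config$learning_rate, tstep)
      epoch_losses <- c(epoch_losses, loss$v[1, 1])
    }
    m <- mean(epoch_losses)
    hist_loss <- c(hist_loss, m)
    hist_fn <- c(hist_fn, loss_name)
    if (!is.finite(m)) {
      warning("training diverged at epoch ", epoch,
              "; reverting to the last finite checkpoint")
      for (i in seq_along(params)) params[[i]]$v <- snapshot[[i]]
      diverged <- TRUE
      break
    }
    snapshot <- lapply(params, function(p) p$v)
  }
  structure(list(model = model,
                 history = tibble::tibble(epoch = seq_along(hist_loss),
                                          loss = hist_loss, loss_fn = hist_fn),
                 config = config, diverged = diverged),
            class = "os_trained_model")
}

#' @export
print.os_trained_model <- function(x, ...) {
  cat("<os_trained_model>", x$model$kind, "-",
      nrow(x$history), "epochs, final loss",
      format(utils::tail(x$history$loss, 1), digits = 4),
      if (x$diverged) "(DIVERGED)" else "", "\n")
  invisible(x)
}

#' Reconstruct a stack with a trained model
#'
#' Normalises each plane's three raw frames jointly (1st/99th percentile,
#' matching the training-time normalisation), runs the network tile-wise
#' and clips the result at zero. RCAN models use an exact tiling scheme:
#' tiles carry `margin` pixels of real-image context on interior sides and
#' every channel-attention gate is pooled globally over the disjoint tile
#' cores, so the result equals full-frame inference to numerical precision
#' (the margin is widened automatically to the configuration's
#' receptive-field radius). VSR models, whose shifted attention windows
#' genuinely cross tile boundaries, use overlap blending instead: tile
#' weights are zero within `margin` pixels of interior edges and
#' cosine-ramp to one inside, a close approximation. Inputs no larger than
#' one tile are processed in a single pass.
#'
#' @param model An `os_model` or `os_trained_model`.
#' @param stack An [os_stack()] (volumetric stacks are processed
#'   plane-wise) or a `c(ny, nx, 3)` array.
#' @param tile Tile side length (default 64).
#' @param overlap Overlap between neighbouring tiles in pixels (must
#'   exceed `2 * margin`).
#' @param margin Contaminated border width given zero blending weight.
#' @return Matrix (or `c(ny, nx, nz)` array), nonnegative, on the
#'   normalised intensity scale.
#' @export
reconstruct_ml <- function(model, stack, tile = 64, overlap = 32, margin = 12) {
  if (inherits(model, "os_trained_model")) model <- model$model
  frames <- if (inherits(stack, "os_stack")) stack$frames else stack
  if (length(dim(frames)) == 3) dim(frames) <- c(dim(frames), 1L)
  nz <- dim(frames)[4]
  out <- array(0, c(dim(frames)[1], dim(frames)[2], nz))
  for (z in seq_len(nz)) {
    out[, , z] <- ml_reconstruct_plane(model, frames[, , , z], tile, overlap,
                                       margin)
  }
  if (nz == 1) out[, , 1] else out
}

ml_forward_image <- function(model, frames, H, W) {
  x <- matrix(frames, H * W, 3)
  outt <- model_forward(model, nn_const(x), H, W)
  matrix(outt$v, H, W)
}

# plain-value (no gradient) layer helpers for inference
conv_plain <- function(xv, layer, geom) {
  sweep(im2col(xv, geom, ncol(xv)) %*% layer$w$v, 2, layer$b$v[1, ], `+`)
}

# receptive-field radius of an RCAN configuration, in pixels
rcan_receptive_radius <- function(cfg) {
  br <- (cfg$body_kernel - 1) / 2
  (cfg$head_kernel - 1) / 2 +
    cfg$n_groups * (cfg$blocks_per_group * 2 * br + br) + br
}

# Exact tiled RCAN inference: tiles take `margin` pixels of real-image
# context on interior sides (zero padding only at true image borders, as in
# full-frame inference), and every channel-attention gate is computed from
# the global pooled mean assembled over the disjoint tile cores. With
# margin >= the receptive-field radius this reproduces full-frame inference
# to numerical precision while bounding per-pass memory.
rcan_tiled_inference <- function(model, xn, tile, margin) {
  cfg <- model$config
  L <- model$layers
  H <- dim(xn)[1]; W <- dim(xn)[2]
  core <- tile - 2 * margin
  stopifnot(core >= 1)
  core_starts <- function(n) seq(1, n, by = core)
  tiles <- list()
  for (cy in core_starts(H)) {
    for (cx in core_starts(W)) {
      ylo <- max(1, cy - margin); yhi <- min(H, cy + core - 1 + margin)
      xlo <- max(1, cx - margin); xhi <- min(W, cx + core - 1 + margin)
      cyhi <- min(H, cy + core - 1); cxhi <- min(W, cx + core - 1)
      th <- yhi - ylo + 1; tw <- xhi - xlo + 1
      # linear indices of the core within the tile's (column-major) pixels
      cyr <- (cy:cyhi) - ylo + 1
      cxr <- (cx:cxhi) - xlo + 1
      core_idx <- as.vector(outer(cyr, (cxr - 1) * th, `+`))
      tiles[[length(tiles) + 1]] <- list(
        x = matrix(xn[ylo:yhi, xlo:xhi, , drop = FALSE], th * tw, dim(xn)[3]),
        geom = get_conv_geometry(th, tw, cfg$body_kernel),
        geom_head = get_conv_geometry(th, tw, cfg$head_kernel),
        core_idx = core_idx, yr = cy:cyhi, xr = cx:cxhi, th = th)
    }
  }
  npix <- H * W
  h <- lapply(tiles, function(ti) conv_plain(ti$x, L$head, ti$geom_head))
  h0 <- h
  geom1 <- get_conv_geometry(1, 1, 1)
  for (grp in L$groups) {
    gin <- h
    for (blk in grp$blocks) {
      t_list <- lapply(seq_along(tiles), function(i) {
        t1 <- conv_plain(h[[i]], blk$conv1, tiles[[i]]$geom)
        t1[t1 < 0] <- 0
        conv_plain(t1, blk$conv2, tiles[[i]]$geom)
      })
      pooled <- Reduce(`+`, lapply(seq_along(tiles), function(i) {
        colSums(t_list[[i]][tiles[[i]]$core_idx, , drop = FALSE])
      })) / npix
      a1 <- conv_plain(matrix(pooled, 1), blk$ca1, geom1)
      a1[a1 < 0] <- 0
      gate <- 1 / (1 + exp(-conv_plain(a1, blk$ca2, geom1)))
      h <- lapply(seq_along(tiles), function(i) {
        h[[i]] + sweep(t_list[[i]], 2, gate[1, ], `*`)
      })
    }
    h <- lapply(seq_along(tiles), function(i) {
      gin[[i]] + conv_plain(h[[i]], grp$tail, tiles[[i]]$geom)
    })
  }
  out <- matrix(0, H, W)
  for (i in seq_along(tiles)) {
    o <- conv_plain(h[[i]] + h0[[i]], L$recon, tiles[[i]]$geom)
    out[tiles[[i]]$yr, tiles[[i]]$xr] <-
      matrix(o[tiles[[i]]$core_idx, 1], length(tiles[[i]]$yr))
  }
  clip0(out)
}

ml_reconstruct_plane <- function(model, frames, tile, overlap, margin = 12) {
  H <- dim(frames)[1]; W <- dim(frames)[2]
  xn <- normalize_input_frames(frames)
  if (H <= tile && W <= tile) {
    return(clip0(ml_forward_image(model, xn, H, W)))
  }
  if (model$kind == "rcan") {
    m <- max(margin, rcan_receptive_radius(model$config))
    if (tile > 2 * m) {
      return(rcan_tiled_inference(model, xn, tile, m))
    }
    # tile too small to carry the receptive field: fall through to blending
  }
  if (overlap >= tile) stop("overlap must be smaller than tile")
  if (overlap <= 2 * margin) stop("overlap must exceed 2 * margin")
  starts <- function(n) {
    if (n <= tile) return(1L)
    s <- seq(1L, n - tile + 1L, by = tile - overlap)
    if (utils::tail(s, 1) != n - tile + 1L) s <- c(s, n - tile + 1L)
    s
  }
  # 1D profile: zero over the contaminated margin, cosine ramp across the
  # rest of the overlap, flat one in the core; borders at the image edge
  # stay flat (tile and full-frame zero padding coincide there)
  profile <- function(at_lo_edge, at_hi_edge) {
    w <- rep(1, tile)
    ramp <- overlap - 2 * margin
    up <- sin(pi * (seq_len(ramp) - 0.5) / (2 * ramp))^2
    if (!at_lo_edge) w[seq_len(margin + ramp)] <- c(rep(0, margin), up)
    if (!at_hi_edge) w[tile + 1 - seq_len(margin + ramp)] <- c(rep(0, margin), up)
    w
  }
  num <- matrix(0, H, W)
  den <- matrix(0, H, W)
  for (sy in starts(H)) {
    for (sx in starts(W)) {
      ys <- sy:(sy + tile - 1); xs <- sx:(sx + tile - 1)
      wmat <- outer(profile(sy == 1, sy + tile - 1 == H),
                    profile(sx == 1, sx + tile - 1 == W))
      patch <- xn[ys, xs, , drop = FALSE]
      o <- ml_forward_image(model, patch, tile, tile)
      num[ys, xs] <- num[ys, xs] + o * wmat
      den[ys, xs] <- den[ys, xs] + wmat
    }
  }
  clip0(num / pmax(den, 1e-12))
}
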
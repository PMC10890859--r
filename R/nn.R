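# A compact reverse-mode automatic-differentiation engine over matrices,
# sufficient for the reconstruction networks in this package: im2col 2D
# convolutions, channel attention, layer normalisation, windowed multi-head
# self-attention, and the Adam optimiser. Feature maps are stored as
# (H*W) x C matrices with column-major pixel order. The graph is rebuilt on
# every forward pass; parameters are persistent environments whose values
# the optimiser updates in place.

nn_counter <- new.env(parent = emptyenv())
nn_counter$id <- 0L

nn_tensor <- function(v, parents = list(), bwfun = NULL, is_param = FALSE) {
  if (is.null(dim(v))) v <- matrix(v, 1)
  nn_counter$id <- nn_counter$id + 1L
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$parents <- parents
  e$bwfun <- bwfun
  e$grad <- NULL
  e$id <- nn_counter$id
  e$is_param <- is_param
  class(e) <- "nn_tensor"
  e
}

nn_param <- function(v) nn_tensor(v, is_param = TRUE)
nn_const <- function(v) nn_tensor(v)

# Reverse-mode sweep from a scalar loss tensor.
nn_backward <- function(loss) {
  order <- list()
  seen <- new.env(parent = emptyenv())
  visit <- function(t) {
    key <- as.character(t$id)
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    for (p in t$parents) visit(p)
    order[[length(order) + 1L]] <<- t
  }
  visit(loss)
  for (t in order) t$grad <- NULL
  loss$grad <- matrix(1, 1, 1)
  for (i in rev(seq_along(order))) {
    t <- order[[i]]
    if (is.null(t$bwfun) || is.null(t$grad)) next
    gs <- t$bwfun(t$grad)
    for (j in seq_along(t$parents)) {
      p <- t$parents[[j]]
      if (is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(loss)
}

tn_matmul <- function(a, b) {
  nn_tensor(a$v %*% b$v, list(a, b), function(g) {
    list(g %*% t(b$v), t(a$v) %*% g)
  })
}

# elementwise add; `b` may be a 1 x C row bias broadcast over rows
tn_add <- function(a, b) {
  bcast <- nrow(b$v) == 1L && nrow(a$v) > 1L
  v <- if (bcast) sweep(a$v, 2, b$v[1, ], `+`) else a$v + b$v
  nn_tensor(v, list(a, b), function(g) {
    list(g, if (bcast) matrix(colSums(g), 1) else g)
  })
}

tn_sub <- function(a, b) {
  nn_tensor(a$v - b$v, list(a, b), function(g) list(g, -g))
}

tn_scale <- function(a, s) {
  nn_tensor(a$v * s, list(a), function(g) list(g * s))
}

tn_hadamard <- function(a, b) {
  nn_tensor(a$v * b$v, list(a, b), function(g) list(g * b$v, g * a$v))
}

# scale each column c of `a` ((T x C)) by s[1, c] ((1 x C) tensor)
tn_rowscale <- function(a, s) {
  nn_tensor(sweep(a$v, 2, s$v[1, ], `*`), list(a, s), function(g) {
    list(sweep(g, 2, s$v[1, ], `*`), matrix(colSums(g * a$v), 1))
  })
}

tn_relu <- function(a) {
  m <- a$v > 0
  nn_tensor(a$v * m, list(a), function(g) list(g * m))
}

tn_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  nn_tensor(s, list(a), function(g) list(g * s * (1 - s)))
}

tn_gelu <- function(a) {
  ph <- stats::pnorm(a$v)
  nn_tensor(a$v * ph, list(a), function(g) {
    list(g * (ph + a$v * stats::dnorm(a$v)))
  })
}

# column means -> 1 x C (global average pooling over pixels)
tn_colmeans <- function(a) {
  n <- nrow(a$v)
  nn_tensor(matrix(colMeans(a$v), 1), list(a), function(g) {
    list(matrix(g[1, ], nrow = n, ncol = ncol(a$v), byrow = TRUE) / n)
  })
}

tn_permute_rows <- function(a, perm) {
  nn_tensor(a$v[perm, , drop = FALSE], list(a), function(g) {
    gp <- matrix(0, nrow(a$v), ncol(a$v))
    gp[perm, ] <- g
    list(gp)
  })
}

tn_mse <- function(pred, target_v) {
  d <- pred$v - target_v
  nn_tensor(matrix(mean(d^2)), list(pred), function(g) {
    list(g[1, 1] * 2 * d / length(d))
  })
}

tn_l1 <- function(pred, target_v) {
  d <- pred$v - target_v
  nn_tensor(matrix(mean(abs(d))), list(pred), function(g) {
    list(g[1, 1] * sign(d) / length(d))
  })
}

tn_add_scalar_list <- function(ts) {
  # mean of scalar loss tensors (batch reduction)
  n <- length(ts)
  v <- mean(vapply(ts, function(t) t$v[1, 1], numeric(1)))
  nn_tensor(matrix(v), ts, function(g) rep(list(g / n), n))
}

# --- convolution -----------------------------------------------------------

# im2col gather indices for a H x W image and odd K x K kernel with zero
# padding; out-of-bounds pixels point at the sentinel row H*W + 1.
conv_geometry <- function(H, W, K) {
  r <- (K - 1) / 2
  hw <- H * W
  rows <- rep(seq_len(H), W)
  cols <- rep(seq_len(W), each = H)
  idx <- matrix(0L, hw, K * K)
  k <- 0L
  for (dc in -r:r) {
    for (dr in -r:r) {
      k <- k + 1L
      rr <- rows + dr
      cc <- cols + dc
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      lin <- rr + (cc - 1L) * H
      lin[!ok] <- hw + 1L
      idx[, k] <- lin
    }
  }
  list(idx = idx, H = H, W = W, K = K, K2 = K * K, hw = hw)
}

geometry_cache <- new.env(parent = emptyenv())

get_conv_geometry <- function(H, W, K) {
  key <- paste(H, W, K, sep = "x")
  g <- geometry_cache[[key]]
  if (is.null(g)) {
    g <- conv_geometry(H, W, K)
    geometry_cache[[key]] <- g
  }
  g
}

im2col <- function(xv, geom, cin) {
  xp <- rbind(xv, matrix(0, 1, cin))  # sentinel zero row for padding
  out <- matrix(0, geom$hw, geom$K2 * cin)
  for (k in seq_len(geom$K2)) {
    out[, (k - 1L) * cin + seq_len(cin)] <- xp[geom$idx[, k], , drop = FALSE]
  }
  out
}

# Same-size 2D convolution (zero padding), weights (K2*Cin) x Cout plus a
# 1 x Cout bias.
tn_conv2d <- function(x, w, b, geom) {
  cin <- ncol(x$v)
  xcol <- im2col(x$v, geom, cin)
  v <- sweep(xcol %*% w$v, 2, b$v[1, ], `+`)
  nn_tensor(v, list(x, w, b), function(g) {
    dW <- t(xcol) %*% g
    db <- matrix(colSums(g), 1)
    dXcol <- g %*% t(w$v)
    dx <- matrix(0, geom$hw, cin)
    for (k in seq_len(geom$K2)) {
      ik <- geom$idx[, k]
      valid <- ik <= geom$hw
      blk <- dXcol[valid, (k - 1L) * cin + seq_len(cin), drop = FALSE]
      dx[ik[valid], ] <- dx[ik[valid], ] + blk
    }
    list(dx, dW, db)
  })
}

# --- layer normalisation ---------------------------------------------------

tn_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x$v)
  xc <- x$v - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  v <- sweep(sweep(xhat, 2, gamma$v[1, ], `*`), 2, beta$v[1, ], `+`)
  nn_tensor(v, list(x, gamma, beta), function(g) {
    C <- ncol(x$v)
    dgamma <- matrix(colSums(g * xhat), 1)
    dbeta <- matrix(colSums(g), 1)
    gx <- sweep(g, 2, gamma$v[1, ], `*`)
    # d/dx of row-wise standardisation
    t1 <- gx
    t2 <- rowMeans(gx)
    t3 <- rowMeans(gx * xhat)
    dx <- inv * (t1 - t2 - xhat * t3)
    list(dx, dgamma, dbeta)
  })
}

# --- windowed multi-head self-attention ------------------------------------

# Input `qkv` is (T x 3C) with rows already window-contiguous (T = nwin*wt,
# wt tokens per window). Computes softmax(Q K' / sqrt(dh)) V per window and
# head; returns (T x C). Row-stochastic attention by construction.
tn_window_attention <- function(qkv, nwin, wt, nheads) {
  C <- ncol(qkv$v) / 3
  dh <- C / nheads
  stopifnot(dh == round(dh))
  scale <- 1 / sqrt(dh)
  out <- matrix(0, nrow(qkv$v), C)
  attn <- vector("list", nwin * nheads)
  for (wi in seq_len(nwin)) {
    rows <- (wi - 1L) * wt + seq_len(wt)
    for (h in seq_len(nheads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      q <- qkv$v[rows, cols, drop = FALSE]
      k <- qkv$v[rows, C + cols, drop = FALSE]
      v <- qkv$v[rows, 2 * C + cols, drop = FALSE]
      s <- (q %*% t(k)) * scale
      s <- s - apply(s, 1, max)
      a <- exp(s)
      a <- a / rowSums(a)
      attn[[(wi - 1L) * nheads + h]] <- a
      out[rows, cols] <- a %*% v
    }
  }
  res <- nn_tensor(out, list(qkv), function(g) {
    dqkv <- matrix(0, nrow(qkv$v), 3 * C)
    for (wi in seq_len(nwin)) {
      rows <- (wi - 1L) * wt + seq_len(wt)
      for (h in seq_len(nheads)) {
        cols <- (h - 1L) * dh + seq_len(dh)
        a <- attn[[(wi - 1L) * nheads + h]]
        q <- qkv$v[rows, cols, drop = FALSE]
        k <- qkv$v[rows, C + cols, drop = FALSE]
        v <- qkv$v[rows, 2 * C + cols, drop = FALSE]
        go <- g[rows, cols, drop = FALSE]
        dv <- t(a) %*% go
        da <- go %*% t(v)
        ds <- a * (da - rowSums(da * a))  # softmax backward
        dq <- (ds %*% k) * scale
        dk <- (t(ds) %*% q) * scale
        dqkv[rows, cols] <- dqkv[rows, cols] + dq
        dqkv[rows, C + cols] <- dqkv[rows, C + cols] + dk
        dqkv[rows, 2 * C + cols] <- dqkv[rows, 2 * C + cols] + dv
      }
    }
    list(dqkv)
  })
  attr(res, "attention") <- attn
  res
}

# Permutation grouping pixels of an H x W image (column-major rows) into
# ws x ws windows, after an optional cyclic shift of the partition grid.
window_permutation <- function(H, W, ws, shift = 0) {
  rows <- rep(seq_len(H), W)
  cols <- rep(seq_len(W), each = H)
  rs <- ((rows - 1 + shift) %% H)
  cs <- ((cols - 1 + shift) %% W)
  win <- (rs %/% ws) + (cs %/% ws) * (H %/% ws)
  within <- (rs %% ws) + (cs %% ws) * ws
  order(win * ws * ws + within)
}

# --- parameter initialisation and Adam -------------------------------------

he_init <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

make_conv_layer <- function(cin, cout, K) {
  list(w = nn_param(he_init(K * K * cin, cout, K * K * cin)),
       b = nn_param(matrix(0, 1, cout)), K = K)
}

make_linear_layer <- function(cin, cout) {
  list(w = nn_param(matrix(stats::rnorm(cin * cout, 0, sqrt(1 / cin)), cin, cout)),
       b = nn_param(matrix(0, 1, cout)))
}

apply_linear <- function(x, layer) tn_add(tn_matmul(x, layer$w), layer$b)

collect_params <- function(obj) {
  if (inherits(obj, "nn_tensor")) {
    if (obj$is_param) return(list(obj)) else return(list())
  }
  if (is.list(obj)) return(do.call(c, lapply(obj, collect_params)))
  list()
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = array(0, dim(p$v)), v = array(0, dim(p$v))))
}

adam_step <- function(params, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * p$grad
    st$v <- beta2 * st$v + (1 - beta2) * p$grad^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    p$v <- p$v - lr * mhat / (sqrt(vhat) + eps)
    state[[i]] <- st
  }
  state
}
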
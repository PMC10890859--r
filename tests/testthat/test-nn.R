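# The reverse-mode autodiff engine behind the reconstruction networks:
# every analytic gradient is checked against central finite differences.

num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("conv2d gradients match finite differences", {
  set.seed(1)
  geom <- ossim:::get_conv_geometry(5, 4, 3)
  x0 <- matrix(rnorm(20 * 2), 20, 2)
  w0 <- matrix(rnorm(18 * 3) * 0.3, 18, 3)
  b0 <- matrix(rnorm(3), 1, 3)
  tgt <- matrix(0.3, 20, 3)
  loss_of <- function(xv, wv, bv) {
    out <- ossim:::tn_relu(ossim:::tn_conv2d(ossim:::nn_const(xv),
      ossim:::nn_param(wv), ossim:::nn_param(bv), geom))
    ossim:::tn_mse(out, tgt)$v[1, 1]
  }
  x <- ossim:::nn_const(x0); w <- ossim:::nn_param(w0); b <- ossim:::nn_param(b0)
  l <- ossim:::tn_mse(ossim:::tn_relu(ossim:::tn_conv2d(x, w, b, geom)), tgt)
  ossim:::nn_backward(l)
  expect_lt(max(abs(x$grad - num_grad(function(v) loss_of(v, w0, b0), x0))), 1e-7)
  expect_lt(max(abs(w$grad - num_grad(function(v) loss_of(x0, v, b0), w0))), 1e-7)
  expect_lt(max(abs(b$grad - num_grad(function(v) loss_of(x0, w0, v), b0))), 1e-7)
})

test_that("layer-norm gradients match finite differences", {
  set.seed(2)
  x0 <- matrix(rnorm(12), 4, 3)
  g0 <- matrix(runif(3) + 0.5, 1, 3)
  b0 <- matrix(rnorm(3), 1, 3)
  tgt <- matrix(0.1, 4, 3)
  f <- function(xv, gv, bv) {
    ossim:::tn_mse(ossim:::tn_layernorm(ossim:::nn_const(xv),
      ossim:::nn_param(gv), ossim:::nn_param(bv)), tgt)$v[1, 1]
  }
  x <- ossim:::nn_const(x0); g <- ossim:::nn_param(g0); b <- ossim:::nn_param(b0)
  l <- ossim:::tn_mse(ossim:::tn_layernorm(x, g, b), tgt)
  ossim:::nn_backward(l)
  expect_lt(max(abs(x$grad - num_grad(function(v) f(v, g0, b0), x0))), 1e-7)
  expect_lt(max(abs(g$grad - num_grad(function(v) f(x0, v, b0), g0))), 1e-7)
  expect_lt(max(abs(b$grad - num_grad(function(v) f(x0, g0, v), b0))), 1e-7)
})

test_that("windowed attention: row-stochastic weights and exact gradients", {
  set.seed(3)
  qkv0 <- matrix(rnorm(8 * 12) * 0.5, 8, 12)  # 2 windows x 4 tokens, C = 4
  att <- ossim:::tn_window_attention(ossim:::nn_const(qkv0), 2, 4, 2)
  for (a in attr(att, "attention")) {
    expect_equal(rowSums(a), rep(1, nrow(a)), tolerance = 1e-12)
    expect_true(all(a >= 0))
  }
  tgt <- matrix(0.2, 8, 4)
  f <- function(qv) {
    ossim:::tn_mse(ossim:::tn_window_attention(ossim:::nn_const(qv), 2, 4, 2),
                   tgt)$v[1, 1]
  }
  q <- ossim:::nn_const(qkv0)
  l <- ossim:::tn_mse(ossim:::tn_window_attention(q, 2, 4, 2), tgt)
  ossim:::nn_backward(l)
  expect_lt(max(abs(q$grad - num_grad(f, qkv0))), 1e-7)
})

test_that("channel-attention path (pool, sigmoid, rescale) backpropagates", {
  set.seed(4)
  x0 <- matrix(rnorm(20), 5, 4)
  tgt <- matrix(0, 5, 4)
  f <- function(xv) {
    x <- ossim:::nn_const(xv)
    a <- ossim:::tn_sigmoid(ossim:::tn_colmeans(x))
    ossim:::tn_mse(ossim:::tn_rowscale(x, a), tgt)$v[1, 1]
  }
  x <- ossim:::nn_const(x0)
  a <- ossim:::tn_sigmoid(ossim:::tn_colmeans(x))
  l <- ossim:::tn_mse(ossim:::tn_rowscale(x, a), tgt)
  ossim:::nn_backward(l)
  expect_lt(max(abs(x$grad - num_grad(f, x0))), 1e-7)
})

test_that("gelu and row-permutation backpropagate through an L1 loss", {
  set.seed(5)
  x0 <- matrix(rnorm(12), 6, 2)
  perm <- sample(6)
  tgt <- matrix(0.1, 6, 2)
  f <- function(xv) {
    ossim:::tn_l1(ossim:::tn_gelu(ossim:::tn_permute_rows(
      ossim:::nn_const(xv), perm)), tgt)$v[1, 1]
  }
  x <- ossim:::nn_const(x0)
  l <- ossim:::tn_l1(ossim:::tn_gelu(ossim:::tn_permute_rows(x, perm)), tgt)
  ossim:::nn_backward(l)
  expect_lt(max(abs(x$grad - num_grad(f, x0))), 1e-7)
})

test_that("Adam drives a convex quadratic toward its minimum", {
  p <- ossim:::nn_param(matrix(c(5, -3), 1, 2))
  state <- ossim:::adam_state(list(p))
  tgt <- matrix(c(1, 2), 1, 2)
  for (t in 1:600) {
    l <- ossim:::tn_mse(p, tgt)
    ossim:::nn_backward(l)
    state <- ossim:::adam_step(list(p), state, 0.05, t)
  }
  expect_lt(max(abs(p$v - tgt)), 0.02)
})
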
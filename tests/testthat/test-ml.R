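# Network architectures, training-set generation, training schedule and
# tiled inference.

test_that("RCAN parameter count matches the independent closed form", {
  # reference configuration: 3 groups x 10 RCABs x 96 filters, 7x7 head,
  # channel-attention bottleneck 96/16 = 6
  nf <- 96; rd <- 6
  rcab <- 2 * ((9 * nf + 1) * nf) + (nf + 1) * rd + (rd + 1) * nf
  expected <- (7 * 7 * 3 + 1) * nf +                    # head, 3 frames in
    3 * (10 * rcab + (9 * nf + 1) * nf) +               # groups + tail convs
    (9 * nf + 1) * 1                                    # reconstruction conv
  expect_identical(count_parameters(build_rcan(rcan_config())), expected)
  # and for a tiny configuration with a different bottleneck
  nf <- 8; rd <- 2
  rcab <- 2 * ((9 * nf + 1) * nf) + (nf + 1) * rd + (rd + 1) * nf
  expected_tiny <- (7 * 7 * 3 + 1) * nf + 1 * (2 * rcab + (9 * nf + 1) * nf) +
    (9 * nf + 1) * 1
  expect_identical(count_parameters(tiny_rcan()), expected_tiny)
})

test_that("models map 3 finite frames to 1 finite frame of the same shape", {
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  for (model in list(tiny_rcan(2), tiny_vsr(3))) {
    out <- reconstruct_ml(model, x)
    expect_identical(dim(out), c(32L, 32L))
    expect_true(all(is.finite(out)))
    expect_true(all(out >= 0))
  }
  # three identical frames are a valid input too
  xs <- array(rep(runif(32 * 32), 3), c(32, 32, 3))
  expect_true(all(is.finite(reconstruct_ml(tiny_vsr(3), xs))))
})

test_that("kernel parity and window divisibility are enforced", {
  expect_error(rcan_config(body_kernel = 4), "odd")
  expect_error(vsr_config(embed_dim = 10, n_heads = 4), "divisible")
  m <- tiny_vsr()
  x <- array(runif(20 * 20 * 3), c(20, 20, 3))
  expect_error(reconstruct_ml(m, x, tile = 64), "pad the input to 24 x 24")
})

test_that("shifted window partitions change attention connectivity", {
  m <- tiny_vsr(7)
  x <- matrix(runif(32 * 32 * 3), 32 * 32, 3)
  out_shift <- ossim:::model_forward(m, ossim:::nn_const(x), 32, 32,
                                     use_shift = TRUE)
  out_plain <- ossim:::model_forward(m, ossim:::nn_const(x), 32, 32,
                                     use_shift = FALSE)
  expect_gt(max(abs(out_shift$v - out_plain$v)), 1e-8)
})

test_that("disabling channel attention reduces an RCAB to a plain residual block", {
  set.seed(8)
  blk <- ossim:::make_rcab(4, 2)
  H <- 6; W <- 5
  x0 <- matrix(rnorm(H * W * 4), H * W, 4)
  geom <- ossim:::get_conv_geometry(H, W, 3)
  geom1 <- ossim:::get_conv_geometry(1, 1, 1)
  with_att <- ossim:::rcab_forward(ossim:::nn_const(x0), blk, geom, geom1)
  no_att <- ossim:::rcab_forward(ossim:::nn_const(x0), blk, geom, geom1,
                                 use_attention = FALSE)
  expect_gt(max(abs(with_att$v - no_att$v)), 1e-8)
  # independent direct-convolution reference (plain loops, zero padding)
  conv_ref <- function(img, wmat, bias) {
    cin <- dim(img)[3]; cout <- ncol(wmat)
    out <- array(0, c(H, W, cout))
    for (co in seq_len(cout)) {
      acc <- matrix(bias[co], H, W)
      k <- 0
      for (dc in -1:1) for (dr in -1:1) {
        k <- k + 1
        for (ci in seq_len(cin)) {
          w <- wmat[(k - 1) * cin + ci, co]
          for (r in 1:H) for (cl in 1:W) {
            rr <- r + dr; cc <- cl + dc
            if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
              acc[r, cl] <- acc[r, cl] + w * img[rr, cc, ci]
            }
          }
        }
      }
      out[, , co] <- acc
    }
    out
  }
  ximg <- array(x0, c(H, W, 4))
  t1 <- conv_ref(ximg, blk$conv1$w$v, blk$conv1$b$v[1, ])
  t1[t1 < 0] <- 0
  t2 <- conv_ref(t1, blk$conv2$w$v, blk$conv2$b$v[1, ])
  # NOTE: conv_ref indexes kernel offsets in the same (dr fast, dc slow)
  # order as the engine's im2col layout
  expect_equal(no_att$v, matrix(ximg + t2, H * W, 4), tolerance = 1e-10)
})

test_that("training sets have exact composition and are reproducible", {
  gen <- training_generator_config(shape = c(24, 24), psf_size = 17)
  ds1 <- generate_training_set(2, 3, gen, seed = 4)
  ds2 <- generate_training_set(2, 3, gen, seed = 4)
  expect_length(ds1, 5)
  expect_identical(attr(ds1, "n_static"), 2)
  expect_identical(attr(ds1, "n_moving"), 3)
  expect_identical(vapply(ds1, function(e) e$mode, character(1)),
                   c("static", "static", "video", "video", "video"))
  for (i in 1:5) {
    expect_identical(ds1[[i]]$input$frames, ds2[[i]]$input$frames)
    expect_identical(ds1[[i]]$target, ds2[[i]]$target)
  }
})

test_that("the loss switches from MSE to L1 exactly at the half-way epoch", {
  gen <- training_generator_config(shape = c(24, 24), psf_size = 17)
  ds <- generate_training_set(4, 0, gen, seed = 5)
  fit <- train_network(tiny_rcan(1), ds,
                       train_config(epochs = 6, batch_size = 2,
                                    learning_rate = 1e-3, seed = 1))
  expect_identical(fit$history$loss_fn, c(rep("mse", 3), rep("l1", 3)))
  expect_error(train_config(epochs = 7), "even")
})

test_that("training is deterministic for fixed seeds", {
  gen <- training_generator_config(shape = c(24, 24), psf_size = 17)
  ds <- generate_training_set(4, 0, gen, seed = 6)
  f1 <- train_network(tiny_rcan(3), ds,
                      train_config(epochs = 4, batch_size = 2,
                                   learning_rate = 1e-3, seed = 9))
  f2 <- train_network(tiny_rcan(3), ds,
                      train_config(epochs = 4, batch_size = 2,
                                   learning_rate = 1e-3, seed = 9))
  expect_identical(f1$history$loss, f2$history$loss)
})

test_that("tiled and full-frame inference agree away from numerical noise", {
  m <- tiny_rcan(5)
  x <- array(runif(128 * 128 * 3), c(128, 128, 3))
  full <- ossim:::ml_reconstruct_plane(m, x, tile = 256, overlap = 32)
  tiled <- ossim:::ml_reconstruct_plane(m, x, tile = 64, overlap = 32)
  rel_rms <- sqrt(mean((tiled - full)^2)) / sqrt(mean(full^2))
  expect_lt(rel_rms, 1e-4)
})

test_that("an all-zero stack reconstructs to (near) zero", {
  m <- tiny_rcan(6)
  out <- reconstruct_ml(m, array(0, c(32, 32, 3)))
  expect_lt(max(out), 1e-8)
})

test_that("tidy/glance expose the training history", {
  gen <- training_generator_config(shape = c(24, 24), psf_size = 17)
  ds <- generate_training_set(4, 0, gen, seed = 7)
  fit <- train_network(tiny_rcan(2), ds,
                       train_config(epochs = 2, batch_size = 2,
                                    learning_rate = 1e-3, seed = 3))
  expect_identical(nrow(generics::tidy(fit)), 2L)
  g <- generics::glance(fit)
  expect_identical(g$kind, "rcan")
  expect_false(g$diverged)
})
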
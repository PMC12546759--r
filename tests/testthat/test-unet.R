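# Noise-predictor building blocks: time-embedding initialization, skip
# concatenation, attention contracts, shape/determinism/conditioning of the
# full net, and finite-difference agreement of the hand-written backward.

test_that("time embedding table follows the sinusoidal initialization", {
  tb <- init_time_embedding(100L, 64L)
  expect_equal(dim(tb), c(100L, 64L))
  # row for t = 0: sin half all 0, cos half all 1
  expect_equal(tb[1, 1:32], rep(0, 32))
  expect_equal(tb[1, 33:64], rep(1, 32))
  # t = 1, i = 0: first entry sin(1)
  expect_equal(tb[2, 1], sin(1))
  # frequency ladder: f_i = exp(-10 i / (d/2 - 1))
  f <- exp(-10 * (0:31) / 31)
  expect_equal(tb[3, 1:32], sin(2 * f))
  expect_true(all(tb >= -1 & tb <= 1))
  expect_error(init_time_embedding(10L, 7L), "even")
})

test_that("skip concatenation stacks channels and checks lengths", {
  a <- array(1, c(8, 32, 2)); b <- array(2, c(8, 32, 2))
  out <- skip_concat(a, b)
  expect_equal(dim(out), c(16L, 32L, 2L))
  expect_true(all(out[1:8, , ] == 1) && all(out[9:16, , ] == 2))
  out2 <- skip_concat(array(0, c(4, 16, 1)), array(0, c(12, 16, 1)))
  expect_equal(dim(out2), c(16L, 16L, 1L))
  expect_error(skip_concat(array(0, c(8, 32, 1)), array(0, c(8, 16, 1))),
               "mismatch")
})

test_that("functional attention satisfies the softmax-singleton contracts", {
  tokens <- matrix(rnorm(4 * 6), 4, 6)
  cond <- rnorm(4)
  # single memory token: every output token receives cond (residually)
  out <- cross_attention(tokens, cond)
  expect_equal(out, tokens + matrix(cond, 4, 6))
  out_nores <- cross_attention(tokens, cond, residual = FALSE)
  expect_equal(out_nores, matrix(cond, 4, 6))
  expect_equal(dim(out), dim(tokens))

  # self-attention: shape preserved; singleton gives x + value(x)
  one <- matrix(rnorm(4), 4, 1)
  expect_equal(self_attention(one), one + one)
  x <- matrix(rnorm(4 * 5), 4, 5)
  expect_equal(dim(self_attention(x)), dim(x))

  # permutation equivariance (no positional signal)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(self_attention(x)[, perm], self_attention(x[, perm]),
               tolerance = 1e-12)
})

test_that("the U-Net preserves shape, is deterministic, and feels the condition", {
  cfg <- unet_config(latent_ch = 4L, latent_len = 32L, channels = c(8, 12, 16),
                     kernel_size = 7L, time_dim = 8L, cond_dim = 11L,
                     T_steps = 20L)
  m <- unet_init(cfg, seed = 1)
  z <- matrix(rnorm(4 * 32), 4, 32)
  cond <- rnorm(11)
  y1 <- unet_forward(m, z, 5L, cond)
  expect_equal(dim(y1), c(4L, 32L))
  expect_true(all(is.finite(y1)))
  expect_identical(y1, unet_forward(m, z, 5L, cond))

  cond2 <- rnorm(11)
  expect_false(identical(y1, unet_forward(m, z, 5L, cond2)))
  expect_false(identical(y1, unet_forward(m, z, 6L, cond)))
  expect_error(unet_forward(m, z, 5L, rnorm(7)), "cond_dim")
  expect_error(unet_forward(m, z, 25L, cond), "range")

  # condition locality: zeroing the cross-attention value projections makes
  # the output exactly independent of the condition
  m$mid_xattn$Wv$value[] <- 0
  for (i in seq_along(m$up_xattn))
    if (!is.null(m$up_xattn[[i]])) m$up_xattn[[i]]$Wv$value[] <- 0
  expect_identical(unet_forward(m, z, 5L, cond),
                   unet_forward(m, z, 5L, cond2))
})

test_that("hand-written U-Net backward matches finite differences; all groups train", {
  set.seed(2)
  cfg <- unet_config(latent_ch = 2L, latent_len = 16L, channels = c(6, 8, 10),
                     kernel_size = 5L, time_dim = 8L, cond_dim = 9L,
                     T_steps = 20L)
  m <- unet_init(cfg, seed = 2)
  B <- 2L
  z <- array(rnorm(2 * 16 * B), c(2, 16, B))
  tb <- c(3L, 20L)
  cond <- matrix(rnorm(9 * B), 9, B)
  y <- unet_forward(m, z, tb, cond)
  cardiodiff:::nn_zero_grads(m$params)
  dz <- cardiodiff:::unet_backward(m, cos(y))
  lossf <- function() sum(sin(unet_forward(m, z, tb, cond)))

  h <- 1e-5
  set.seed(3)
  # input gradient at random positions
  for (trial in 1:5) {
    i <- sample(length(z), 1)
    z1 <- z; z1[i] <- z1[i] + h; z2 <- z; z2[i] <- z2[i] - h
    num <- (sum(sin(unet_forward(m, z1, tb, cond))) -
              sum(sin(unet_forward(m, z2, tb, cond)))) / (2 * h)
    expect_lt(abs(num - dz[i]) / max(1e-6, abs(num)), 1e-4)
  }
  # one random coordinate of every parameter group
  for (p in m$params) {
    i <- sample(length(p$value), 1)
    v0 <- p$value[i]
    p$value[i] <- v0 + h; f1 <- lossf()
    p$value[i] <- v0 - h; f2 <- lossf()
    p$value[i] <- v0
    num <- (f1 - f2) / (2 * h)
    expect_lt(abs(num - p$grad[i]), max(1e-4, 1e-4 * abs(num)))
  }
  # gradient flow: a scalar loss reaches every group (time table included:
  # its used rows must be nonzero)
  n_nonzero <- sum(vapply(m$params, function(p) any(p$grad != 0), logical(1)))
  expect_equal(n_nonzero, length(m$params))
})
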
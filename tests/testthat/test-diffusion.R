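# DDPM scheduler: schedule construction, forward/reverse formulas and the
# ancestral sampling chain, checked against independent scalar oracles.

test_that("linear schedule hits its endpoints and matches a product-loop oracle", {
  s <- make_linear_schedule()
  expect_equal(s$beta[1], 0.00085)
  expect_equal(s$beta[1000], 0.0120)
  expect_equal(s$T, 1000L)
  # independent brute-force cumulative product
  ab <- numeric(s$T)
  acc <- 1
  for (t in seq_len(s$T)) { acc <- acc * (1 - s$beta[t]); ab[t] <- acc }
  expect_lt(max(abs(ab - s$alpha_bar)), 1e-12)
  expect_true(all(diff(s$beta) >= 0))
  expect_true(all(diff(s$alpha_bar) < 0))

  s1 <- make_linear_schedule(0.1, 0.2, 1)
  expect_equal(s1$beta, 0.1)
  expect_error(make_linear_schedule(0.5, 0.1, 10), "beta")
})

test_that("forward diffusion matches its closed-form branches and marginal", {
  s <- make_linear_schedule(T_steps = 100L)
  z0 <- matrix(rnorm(8), 2, 4)
  t <- 40L
  expect_equal(forward_diffuse(z0, t, 0 * z0, s), sqrt(s$alpha_bar[t]) * z0)
  eps <- matrix(rnorm(8), 2, 4)
  expect_equal(forward_diffuse(0 * z0, t, eps, s), sqrt(1 - s$alpha_bar[t]) * eps)
  expect_error(forward_diffuse(z0, 101L, eps, s), "range")

  # Monte-Carlo marginal: var(z_t - sqrt(ab) z0) = 1 - ab within 3 MC sigma
  set.seed(1)
  n <- 10000L
  draws <- vapply(seq_len(n), function(i) {
    forward_diffuse(1.7, t, rnorm(1), s) - sqrt(s$alpha_bar[t]) * 1.7
  }, 0)
  v <- var(draws)
  target <- 1 - s$alpha_bar[t]
  mc_sd <- target * sqrt(2 / (n - 1))
  expect_lt(abs(v - target), 3 * mc_sd)
})

test_that("training loss equals an elementwise summation oracle", {
  expect_equal(training_loss(1:4, 1:4), 0)
  expect_equal(training_loss(rep(0, 5), rep(1, 5)), 1)
  set.seed(3)
  a <- array(rnorm(24), c(2, 3, 4)); b <- array(rnorm(24), c(2, 3, 4))
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_lt(abs(training_loss(a, b) - acc / length(a)), 1e-12)
  expect_error(training_loss(1:3, 1:4), "mismatch")
})

test_that("predict_z0 inverts the forward map at every step", {
  s <- make_linear_schedule(T_steps = 1000L)
  set.seed(4)
  z0 <- matrix(rnorm(12), 3, 4)
  for (t in c(1L, 2L, 17L, 500L, 999L, 1000L)) {
    eps <- matrix(rnorm(12), 3, 4)
    zt <- forward_diffuse(z0, t, eps, s)
    expect_lt(max(abs(predict_z0(zt, eps, t, s) - z0)), 1e-6)
  }
  t <- 100L
  zt <- matrix(rnorm(12), 3, 4)
  expect_equal(predict_z0(zt, 0 * zt, t, s), zt / sqrt(s$alpha_bar[t]))
})

test_that("posterior parameters match a scalar recomputation and vanish at t = 1", {
  s <- make_linear_schedule(T_steps = 50L)
  set.seed(5)
  zt <- matrix(rnorm(6), 2, 3)
  eh <- matrix(rnorm(6), 2, 3)

  pp1 <- posterior_params(zt, eh, 1L, s)
  expect_equal(pp1$var, 0)

  expect_equal(posterior_params(0 * zt, 0 * zt, 10L, s)$mean, 0 * zt)

  # independent scalar-loop oracle for Eq-style mean/variance
  t <- 23L
  a <- s$alpha[t]; ab <- s$alpha_bar[t]; abp <- s$alpha_bar[t - 1]
  mu_o <- zt
  for (i in seq_along(zt)) {
    z0h <- (zt[i] - sqrt(1 - ab) * eh[i]) / sqrt(ab)
    mu_o[i] <- (sqrt(a) * (1 - abp) * zt[i] + sqrt(abp) * (1 - a) * z0h) / (1 - ab)
  }
  v_o <- (1 - a) * (1 - abp) / (1 - ab)
  pp <- posterior_params(zt, eh, t, s)
  expect_lt(max(abs(pp$mean - mu_o)), 1e-10)
  expect_lt(abs(pp$var - v_o), 1e-10)
  # sigma_t^2 in (0, beta_t] for t >= 2
  for (t in 2:50) {
    v <- posterior_params(zt, eh, t, s)$var
    expect_gt(v, 0)
    expect_lte(v, s$beta[t])
  }
})

test_that("sampling steps are deterministic where the variance vanishes", {
  s <- make_linear_schedule(T_steps = 10L)
  zt <- matrix(rnorm(4), 2, 2)
  eh <- matrix(rnorm(4), 2, 2)
  noise <- matrix(rnorm(4), 2, 2)
  expect_equal(sample_step(zt, eh, 1L, s, noise),
               posterior_params(zt, eh, 1L, s)$mean)
  expect_equal(sample_step(zt, eh, 5L, s, 0 * noise),
               posterior_params(zt, eh, 5L, s)$mean)
})

test_that("the sampling chain is seed-reproducible and matches a manual unroll", {
  s <- make_linear_schedule(T_steps = 2L)
  pred0 <- function(z, t, cond) 0 * z
  out1 <- sample_loop(pred0, NULL, s, c(2, 3), seed = 9)
  out2 <- sample_loop(pred0, NULL, s, c(2, 3), seed = 9)
  expect_identical(out1, out2)

  # manual unroll with the same RNG stream
  set.seed(9)
  z <- array(rnorm(6), c(2, 3))
  for (t in 2:1) {
    pp <- posterior_params(z, 0 * z, t, s)
    nz <- array(rnorm(6), c(2, 3))
    z <- pp$mean + sqrt(pp$var) * nz
  }
  expect_equal(out1, z, tolerance = 1e-12)

  # single-step closed form: T = 1, predictor 0 -> z1 / sqrt(alpha_1)
  s1 <- make_linear_schedule(0.04, 0.04, 1L)
  out <- sample_loop(pred0, NULL, s1, c(2, 2), seed = 3)
  set.seed(3)
  z1 <- array(rnorm(4), c(2, 2))
  expect_equal(out, z1 / sqrt(1 - 0.04), tolerance = 1e-12)
})

test_that("a predictor trained on a Gaussian toy recovers its mean", {
  # oracle predictor for data ~ N(m, s2): eps_hat(z_t) has the closed form
  # (z_t - sqrt(ab) m) * w with w chosen from the Gaussian posterior.
  # The schedule must reach abar_T ~ 0 so the N(0, I) start of ancestral
  # sampling matches the terminal forward marginal.
  s <- make_linear_schedule(0.05, 0.4, T_steps = 30L)
  m_true <- 2.5; s2_true <- 0.25
  pred <- function(z, t, cond) {
    ab <- s$alpha_bar[t]
    sqrt(1 - ab) * (z - sqrt(ab) * m_true) / (ab * s2_true + 1 - ab)
  }
  draws <- vapply(1:400, function(i) sample_loop(pred, NULL, s, c(1, 1), seed = i), 0)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - m_true), 3 * se + 0.05)
})
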
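# DDPM scheduler: linear beta schedule, forward noising, noise-prediction
# loss, posterior of the reverse chain, and ancestral sampling. Step indices
# run t = 1..T with the convention alpha_bar_0 := 1, under which the final
# (t = 1) reverse step has exactly zero variance.

#' Linear noise schedule
#'
#' beta_t interpolates linearly from `beta_start` (t = 1) to `beta_end`
#' (t = T); `alpha_t = 1 - beta_t` and `alpha_bar_t` is the running product.
#' Defaults follow the model's training configuration: T = 1000 steps over
#' [0.00085, 0.0120]. `kind = "scaled_linear"` interpolates in sqrt(beta)
#' instead (a spacing in common use with the same printed endpoints).
#'
#' @param beta_start,beta_end endpoints, 0 < start <= end < 1.
#' @param T_steps number of diffusion steps (>= 1).
#' @param kind "linear" (in beta) or "scaled_linear" (in sqrt(beta)).
#' @return a `noise_schedule` list: T, beta, alpha, alpha_bar.
#' @export
make_linear_schedule <- function(beta_start = 0.00085, beta_end = 0.0120,
                                 T_steps = 1000L,
                                 kind = c("linear", "scaled_linear")) {
  kind <- match.arg(kind)
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1))
    stop("require 0 < beta_start <= beta_end < 1")
  if (T_steps < 1) stop("T_steps must be >= 1")
  T_steps <- as.integer(T_steps)
  if (T_steps == 1L) {
    beta <- beta_start
  } else if (kind == "linear") {
    beta <- seq(beta_start, beta_end, length.out = T_steps)
  } else {
    beta <- seq(sqrt(beta_start), sqrt(beta_end), length.out = T_steps)^2
  }
  alpha <- 1 - beta
  structure(list(T = T_steps, beta = beta, alpha = alpha,
                 alpha_bar = cumprod(alpha), kind = kind),
            class = "noise_schedule")
}

# alpha_bar_{t-1} with the alpha_bar_0 := 1 convention
.abar_prev <- function(sched, t) if (t == 1L) 1 else sched$alpha_bar[t - 1L]

.check_t <- function(sched, t) {
  if (length(t) != 1L || t < 1L || t > sched$T) stop("t out of range 1..T")
  as.integer(t)
}

#' Forward diffusion marginal
#'
#' `z_t = sqrt(alpha_bar_t) z0 + sqrt(1 - alpha_bar_t) eps`.
#'
#' @param z0 latent (any numeric array). @param t step in 1..T.
#' @param eps standard-normal draw, same shape as `z0`.
#' @param sched a [make_linear_schedule()] schedule.
#' @return noised latent of the same shape.
#' @export
forward_diffuse <- function(z0, t, eps, sched) {
  t <- .check_t(sched, t)
  if (length(z0) != length(eps)) stop("z0/eps shape mismatch")
  ab <- sched$alpha_bar[t]
  sqrt(ab) * z0 + sqrt(1 - ab) * eps
}

#' Noise-prediction training loss
#'
#' Squared L2 distance between the true and predicted noise with
#' mean-per-element reduction (so the loss scale is independent of the
#' latent size).
#'
#' @param eps,eps_hat equal-shaped numeric arrays.
#' @return non-negative scalar.
#' @export
training_loss <- function(eps, eps_hat) {
  if (length(eps) != length(eps_hat)) stop("shape mismatch")
  mean((eps - eps_hat)^2)
}

#' Reconstruct z0 from a noisy latent and predicted noise
#'
#' `z0_hat = (z_t - sqrt(1 - alpha_bar_t) eps_hat) / sqrt(alpha_bar_t)` —
#' the algebraic inversion of [forward_diffuse()].
#'
#' @param z_t noisy latent. @param eps_hat predicted noise. @param t step.
#' @param sched schedule.
#' @return estimate of the clean latent.
#' @export
predict_z0 <- function(z_t, eps_hat, t, sched) {
  t <- .check_t(sched, t)
  ab <- sched$alpha_bar[t]
  (z_t - sqrt(1 - ab) * eps_hat) / sqrt(ab)
}

#' Reverse-step posterior parameters
#'
#' Mean `mu_q = [sqrt(alpha_t)(1 - abar_{t-1}) z_t +
#' sqrt(abar_{t-1})(1 - alpha_t) z0_hat] / (1 - abar_t)` and variance
#' `sigma_t^2 = (1 - alpha_t)(1 - abar_{t-1}) / (1 - abar_t)`, with
#' `abar_0 := 1` so the t = 1 step is deterministic.
#'
#' @param z_t noisy latent. @param eps_hat predicted noise. @param t step.
#' @param sched schedule.
#' @return list(mean, var): posterior mean (latent shape) and scalar variance.
#' @export
posterior_params <- function(z_t, eps_hat, t, sched) {
  t <- .check_t(sched, t)
  a <- sched$alpha[t]
  ab <- sched$alpha_bar[t]
  abp <- .abar_prev(sched, t)
  z0h <- predict_z0(z_t, eps_hat, t, sched)
  mu <- (sqrt(a) * (1 - abp) * z_t + sqrt(abp) * (1 - a) * z0h) / (1 - ab)
  v <- (1 - a) * (1 - abp) / (1 - ab)
  list(mean = mu, var = v)
}

#' One ancestral sampling step
#'
#' Draws `z_{t-1} = mu_q + sigma_t * noise`; at t = 1 the variance is zero
#' and the return is exactly the posterior mean.
#'
#' @param z_t current latent. @param eps_hat predicted noise. @param t step.
#' @param sched schedule. @param noise standard-normal draw (latent shape).
#' @return the denoised latent `z_{t-1}`.
#' @export
sample_step <- function(z_t, eps_hat, t, sched, noise) {
  pp <- posterior_params(z_t, eps_hat, t, sched)
  pp$mean + sqrt(pp$var) * noise
}

#' Full ancestral sampling chain
#'
#' Starts from `z_T ~ N(0, I)` and applies [sample_step()] for t = T..1
#' using `predictor(z_t, t, cond)` as the noise prediction. Deterministic
#' given `seed`.
#'
#' @param predictor function (z_t, t, cond) -> latent-shaped array.
#' @param cond condition vector passed through to the predictor (may be NULL).
#' @param sched schedule.
#' @param latent_dim integer vector, the latent shape (e.g. c(4, 128)).
#' @param seed integer seed.
#' @return the final denoised latent.
#' @export
sample_loop <- function(predictor, cond, sched, latent_dim, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  z <- array(stats::rnorm(prod(latent_dim)), dim = latent_dim)
  for (t in seq(sched$T, 1L)) {
    eps_hat <- predictor(z, t, cond)
    if (length(eps_hat) != length(z)) stop("predictor returned wrong shape")
    noise <- array(stats::rnorm(prod(latent_dim)), dim = latent_dim)
    z <- sample_step(z, eps_hat, t, sched, noise)
  }
  z
}
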
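# Convolutional variational autoencoder: a strided 1D conv encoder halves
# the length log2(L/latent_len) times while mapping 12 channels to the
# latent channel count; the decoder mirrors it with nearest-neighbour
# upsampling + convolution. Trained on reconstruction MSE plus KL to N(0, I)
# under a monotonic linear annealing of the KL weight.

#' KL-annealing schedule
#'
#' The KL coefficient starts at 0 and increases linearly with epoch,
#' reaching `lambda_max` at `ramp_epochs` and staying there.
#'
#' @param lambda_max final KL weight (>= 0).
#' @param ramp_epochs epochs over which the weight ramps (>= 1).
#' @return an `anneal_schedule` list.
#' @export
anneal_schedule <- function(lambda_max = 2e-5, ramp_epochs = 10L) {
  stopifnot(lambda_max >= 0, ramp_epochs >= 1)
  structure(list(lambda_max = lambda_max, ramp_epochs = as.integer(ramp_epochs)),
            class = "anneal_schedule")
}

#' KL weight at a given epoch
#'
#' `lambda(e) = lambda_max * min(1, e / ramp_epochs)`; 0 at epoch 0,
#' non-decreasing, constant at `lambda_max` beyond the ramp.
#'
#' @param epoch non-negative integer. @param sched an [anneal_schedule()].
#' @return the KL coefficient.
#' @export
lambda_at <- function(epoch, sched) {
  sched$lambda_max * min(1, epoch / sched$ramp_epochs)
}

#' KL divergence of a diagonal Gaussian posterior to N(0, I)
#'
#' Closed form `-1/2 * sum(1 + log_var - mu^2 - exp(log_var))`; non-negative,
#' and zero iff mu = 0 and log_var = 0 everywhere.
#'
#' @param mu,log_var equal-shaped arrays (posterior mean and log-variance).
#' @return scalar >= 0.
#' @export
kl_divergence <- function(mu, log_var) {
  if (length(mu) != length(log_var)) stop("mu/log_var shape mismatch")
  -0.5 * sum(1 + log_var - mu^2 - exp(log_var))
}

#' Reparameterization draw
#'
#' `z = mu + exp(log_var / 2) * eps` with `eps ~ N(0, I)`.
#'
#' @param mu,log_var posterior parameters. @param eps standard-normal draw
#'   of the same shape.
#' @return latent sample.
#' @export
reparameterize <- function(mu, log_var, eps) {
  if (length(mu) != length(eps)) stop("eps shape mismatch")
  mu + exp(log_var / 2) * eps
}

#' VAE training loss
#'
#' Reconstruction MSE (mean over every entry) plus `lam` times the KL
#' divergence of the posterior.
#'
#' @param signal,reconstruction equal-shaped arrays.
#' @param mu,log_var posterior parameters.
#' @param lam non-negative KL weight.
#' @return scalar loss.
#' @export
vae_loss <- function(signal, reconstruction, mu, log_var, lam) {
  if (lam < 0) stop("lam must be non-negative")
  if (length(signal) != length(reconstruction)) stop("shape mismatch")
  mean((signal - reconstruction)^2) + lam * kl_divergence(mu, log_var)
}

## ---- model ------------------------------------------------------------

#' Initialize a VAE
#'
#' @param in_ch input channels (12 leads).
#' @param L input length (must be latent_len * 2^k for integer k).
#' @param latent_ch,latent_len latent shape (default 4 x 128).
#' @param widths conv channel widths from full length down to the latent
#'   stage (length k + 1); default a linear ramp 24..64.
#' @param seed integer seed for parameter initialization.
#' @return a `vae` model object.
#' @export
vae_init <- function(in_ch = 12L, L = 1024L, latent_ch = 4L,
                     latent_len = 128L, widths = NULL, seed = 1) {
  nh <- log2(L / latent_len)
  if (nh != round(nh) || nh < 1) stop("L / latent_len must be a power of 2")
  nh <- as.integer(nh)
  if (is.null(widths)) widths <- round(seq(24, 64, length.out = nh + 1))
  stopifnot(length(widths) == nh + 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  enc <- list(layer_conv1d(in_ch, widths[1], 7L), layer_silu())
  for (i in seq_len(nh)) {
    enc <- c(enc, list(layer_conv1d(widths[i], widths[i + 1], 7L, stride = 2L),
                       layer_silu()))
  }
  mu_head <- layer_conv1d(widths[nh + 1], latent_ch, 3L)
  lv_head <- layer_conv1d(widths[nh + 1], latent_ch, 3L)
  # start with a small posterior sd (sigma ~ exp(-3)) so the
  # reparameterization noise does not drown the latent signal early on
  lv_head$W$value <- lv_head$W$value * 0.1
  lv_head$b$value[] <- -6

  dec <- list(layer_conv1d(latent_ch, widths[nh + 1], 3L), layer_silu())
  for (i in rev(seq_len(nh))) {
    dec <- c(dec, list(layer_upsample2(),
                       layer_conv1d(widths[i + 1], widths[i], 7L),
                       layer_silu()))
  }
  dec <- c(dec, list(layer_conv1d(widths[1], in_ch, 7L)))

  model <- list(enc = enc, mu_head = mu_head, lv_head = lv_head, dec = dec,
                in_ch = in_ch, L = as.integer(L),
                latent_ch = as.integer(latent_ch),
                latent_len = as.integer(latent_len))
  model$params <- c(nn_collect_params(enc), mu_head$params, lv_head$params,
                    nn_collect_params(dec))
  class(model) <- "vae"
  model
}

.as_batch <- function(x, ch, L) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  d <- dim(x)
  if (length(d) != 3L || d[1] != ch || d[2] != L)
    stop(sprintf("expected %d x %d [x B] input, got %s", ch, L,
                 paste(d, collapse = " x ")))
  x
}

run_fwd <- function(layers, x) {
  for (ly in layers) x <- ly$fwd(x)
  x
}
run_bwd <- function(layers, dy) {
  for (ly in rev(layers)) dy <- ly$bwd(dy)
  dy
}

#' Encode signals to the Gaussian posterior
#'
#' @param model a [vae_init()] model.
#' @param x 12 x L matrix or [12, L, B] array of normalized signals.
#' @return list(mu, log_var), each [latent_ch, latent_len (, B)]; matrices
#'   for single-signal input. log-variance is clamped to [-10, 10].
#' @export
vae_encode <- function(model, x) {
  single <- is.matrix(x)
  x <- .as_batch(x, model$in_ch, model$L)
  h <- run_fwd(model$enc, x)
  mu <- model$mu_head$fwd(h)
  lv <- pmin(pmax(model$lv_head$fwd(h), -10), 10)
  if (single) {
    mu <- array(mu, dim = dim(mu)[1:2]); lv <- array(lv, dim = dim(lv)[1:2])
  }
  list(mu = mu, log_var = lv)
}

#' Decode latents to signal space
#'
#' @param model a [vae_init()] model.
#' @param z [latent_ch x latent_len] matrix or [.., B] array.
#' @return 12 x L matrix (or [12, L, B] array) of reconstructed signals.
#' @export
vae_decode <- function(model, z) {
  single <- is.matrix(z)
  z <- .as_batch(z, model$latent_ch, model$latent_len)
  y <- run_fwd(model$dec, z)
  if (single) y <- array(y, dim = dim(y)[1:2])
  y
}

#' Train the VAE
#'
#' Minimizes reconstruction MSE + lambda(epoch) * KL with Adam, where
#' lambda follows the monotonic linear annealing schedule. The KL term is
#' averaged over the batch (sum over latent dimensions per sample).
#'
#' @param x [12, L, N] array of normalized signals.
#' @param model optional pre-initialized [vae_init()] model.
#' @param epochs,batch_size,lr optimizer settings.
#' @param anneal an [anneal_schedule()].
#' @param seed integer seed (initialization, shuffling, reparameterization).
#' @param verbose print per-epoch losses.
#' @param ... passed to [vae_init()] when `model` is NULL.
#' @return list: `model`, `history` (per-epoch mean loss, mse, kl).
#' @export
train_vae <- function(x, model = NULL, epochs = 10L, batch_size = 32L,
                      lr = 5e-4, anneal = anneal_schedule(), seed = 1,
                      verbose = FALSE, ...) {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  if (is.null(model))
    model <- vae_init(in_ch = d[1], L = d[2], seed = seed, ...)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed) + 1L)
  N <- d[3]
  step <- 0L
  hist <- data.frame(epoch = integer(), loss = numeric(), mse = numeric(),
                     kl = numeric())
  for (ep in seq_len(epochs)) {
    lam <- lambda_at(ep - 1L, anneal)
    perm <- sample.int(N)
    ep_loss <- ep_mse <- ep_kl <- 0; nb <- 0L
    for (start in seq(1L, N, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, N)]
      xb <- x[, , idx, drop = FALSE]
      B <- length(idx)

      h <- run_fwd(model$enc, xb)
      mu <- model$mu_head$fwd(h)
      lv <- pmin(pmax(model$lv_head$fwd(h), -10), 10)
      eps <- array(stats::rnorm(length(mu)), dim = dim(mu))
      z <- mu + exp(lv / 2) * eps
      rec <- run_fwd(model$dec, z)

      mse <- mean((xb - rec)^2)
      kl <- kl_divergence(mu, lv) / B
      loss <- mse + lam * kl

      nn_zero_grads(model$params)
      drec <- 2 * (rec - xb) / length(rec)
      dz <- run_bwd(model$dec, drec)
      dmu <- dz + (lam / B) * mu
      dlv <- dz * eps * 0.5 * exp(lv / 2) + (lam / B) * 0.5 * (exp(lv) - 1)
      dh <- model$mu_head$bwd(dmu) + model$lv_head$bwd(dlv)
      run_bwd(model$enc, dh)
      step <- step + 1L
      nn_adam_step(model$params, lr, step)

      ep_loss <- ep_loss + loss; ep_mse <- ep_mse + mse; ep_kl <- ep_kl + kl
      nb <- nb + 1L
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / nb,
                                   mse = ep_mse / nb, kl = ep_kl / nb))
    if (verbose)
      message(sprintf("epoch %d: loss %.5f (mse %.5f, kl %.3f, lambda %.2g)",
                      ep, ep_loss / nb, ep_mse / nb, ep_kl / nb, lam))
  }
  list(model = model, history = hist)
}
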
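# Conditional 1D U-Net noise predictor. Down-sampling stages enrich the
# channel dimension while halving the length; up-sampling stages mirror
# them, with skip connections concatenated channel-wise at matching
# resolutions (In(U_i) = Concat(Out(U_{i-1}), Out(D_i))). The time step is
# fetched from a trainable embedding table (sinusoidally initialized),
# linearly projected to each stage's width and broadcast-added along the
# length axis. The condition embedding enters only through cross-attention
# (bottleneck and the coarsest up stage); self-attention at the bottleneck
# captures global structure along the latent length.

#' Initialize the trainable time-embedding table
#'
#' Row r (1-based) is initialized for time value t = r - 1 as
#' `[sin(t * f_i) | cos(t * f_i)]`, i = 0..d/2-1, with geometric frequencies
#' `f_i = exp(-10 * i / (d/2 - 1))` (so f_0 = 1 and the ladder spans a factor
#' e^-10). The table is a trainable parameter thereafter.
#'
#' @param T_steps number of rows (diffusion steps).
#' @param d even embedding length >= 4 (default 64).
#' @return numeric matrix [T_steps x d], entries in [-1, 1].
#' @export
init_time_embedding <- function(T_steps, d = 64L) {
  if (d %% 2 != 0 || d < 4) stop("embedding length d must be even and >= 4")
  half <- d %/% 2
  f <- exp(-10 * (0:(half - 1)) / (half - 1))
  tt <- 0:(T_steps - 1)
  cbind(sin(outer(tt, f)), cos(outer(tt, f)))
}

#' Channel-wise skip concatenation
#'
#' Concatenates an up-path activation with the down-path activation of the
#' same resolution along the channel axis.
#'
#' @param up_prev,down_same arrays [C1, L, B] and [C2, L, B] with equal
#'   length and batch.
#' @return array [C1 + C2, L, B].
#' @export
skip_concat <- function(up_prev, down_same) {
  d1 <- dim(up_prev); d2 <- dim(down_same)
  if (is.matrix(up_prev)) { d1 <- c(d1, 1L); dim(up_prev) <- d1 }
  if (is.matrix(down_same)) { d2 <- c(d2, 1L); dim(down_same) <- d2 }
  if (!all(d1[-1] == d2[-1])) stop("length/batch mismatch in skip connection")
  out <- array(0, dim = c(d1[1] + d2[1], d1[2], d1[3]))
  out[seq_len(d1[1]), , ] <- up_prev
  out[d1[1] + seq_len(d2[1]), , ] <- down_same
  out
}

#' Configure the U-Net noise predictor
#'
#' @param latent_ch,latent_len shape of the latent the net denoises.
#' @param channels channel width per resolution stage; its length sets the
#'   number of stages (default the 7-stage schedule).
#' @param kernel_size odd convolution kernel (default 7).
#' @param time_dim even time-embedding length (default 64).
#' @param cond_dim length of the condition embedding vector.
#' @param T_steps diffusion steps (rows of the time table).
#' @return a `unet_config` list.
#' @export
unet_config <- function(latent_ch = 4L, latent_len = 128L,
                        channels = c(32, 64, 96, 128, 160, 192, 224),
                        kernel_size = 7L, time_dim = 64L, cond_dim = 67L,
                        T_steps = 1000L) {
  stopifnot(kernel_size %% 2 == 1, time_dim %% 2 == 0)
  S <- length(channels)
  if (latent_len %% 2^(S - 1) != 0)
    stop("latent_len must be divisible by 2^(stages-1)")
  structure(list(latent_ch = as.integer(latent_ch),
                 latent_len = as.integer(latent_len),
                 channels = as.integer(channels),
                 kernel_size = as.integer(kernel_size),
                 time_dim = as.integer(time_dim),
                 cond_dim = as.integer(cond_dim),
                 T_steps = as.integer(T_steps)),
            class = "unet_config")
}

#' Initialize the U-Net
#'
#' @param cfg a [unet_config()].
#' @param seed integer seed for parameter initialization.
#' @return a `unet` model object.
#' @export
unet_init <- function(cfg, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  S <- length(cfg$channels)
  ch <- cfg$channels; k <- cfg$kernel_size
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  m$time_table <- nn_param(init_time_embedding(cfg$T_steps, cfg$time_dim))

  m$stem <- layer_conv1d(cfg$latent_ch, ch[1], k)
  m$down_t <- m$down_conv <- m$down_act <- m$down_ln <- vector("list", S - 1)
  m$down_pool <- vector("list", S - 1)
  for (i in seq_len(S - 1)) {
    m$down_t[[i]] <- layer_dense(cfg$time_dim, ch[i])
    m$down_conv[[i]] <- layer_conv1d(ch[i], ch[i], k)
    m$down_act[[i]] <- layer_silu()
    m$down_ln[[i]] <- layer_lnorm(ch[i])
    m$down_pool[[i]] <- layer_conv1d(ch[i], ch[i + 1], k, stride = 2L)
  }
  m$mid_t <- layer_dense(cfg$time_dim, ch[S])
  m$mid_sattn <- layer_self_attn(ch[S])
  m$mid_xattn <- layer_cross_attn(ch[S], cfg$cond_dim)
  m$mid_conv <- layer_conv1d(ch[S], ch[S], k)
  m$mid_act <- layer_silu()
  m$mid_ln <- layer_lnorm(ch[S])

  m$up_us <- m$up_conv1 <- m$up_conv2 <- m$up_t <- m$up_act <- m$up_ln <-
    vector("list", S - 1)
  m$up_xattn <- vector("list", S - 1)
  for (i in seq_len(S - 1)) {   # i indexes the target (finer) stage
    m$up_us[[i]] <- layer_upsample2()
    m$up_conv1[[i]] <- layer_conv1d(ch[i + 1], ch[i], k)
    m$up_conv2[[i]] <- layer_conv1d(2L * ch[i], ch[i], k)
    m$up_t[[i]] <- layer_dense(cfg$time_dim, ch[i])
    m$up_act[[i]] <- layer_silu()
    m$up_ln[[i]] <- layer_lnorm(ch[i])
    if (i == S - 1)   # coarsest up stage carries cross-attention
      m$up_xattn[[i]] <- layer_cross_attn(ch[i], cfg$cond_dim)
  }
  m$head <- layer_conv1d(ch[1], cfg$latent_ch, k)
  m$head$W$value <- m$head$W$value * 0.05   # near-zero initial prediction

  grab <- function(ls) nn_collect_params(Filter(Negate(is.null), ls))
  m$params <- c(list(m$time_table), m$stem$params,
                grab(m$down_t), grab(m$down_conv), grab(m$down_ln),
                grab(m$down_pool),
                m$mid_t$params, m$mid_sattn$params, m$mid_xattn$params,
                m$mid_conv$params, m$mid_ln$params,
                grab(m$up_us), grab(m$up_conv1), grab(m$up_conv2),
                grab(m$up_t), grab(m$up_ln), grab(m$up_xattn),
                m$head$params)
  class(m) <- "unet"
  m
}

# broadcast-add a (C x B) matrix along the length axis of [C, L, B]
.badd <- function(x, add) {
  d <- dim(x)
  x + aperm(array(add, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
}

#' U-Net forward pass
#'
#' Predicts the noise for a batch of noisy latents at (possibly different)
#' time steps under a shared layout: output shape equals input shape.
#'
#' @param model a [unet_init()] model.
#' @param z [latent_ch, latent_len] matrix or [.., B] array.
#' @param t integer step(s) in 1..T (length 1 or B).
#' @param cond condition matrix [cond_dim x B] (or vector for B = 1).
#' @return predicted noise, same shape as `z`.
#' @export
unet_forward <- function(model, z, t, cond) {
  single <- is.matrix(z)
  z <- .as_batch(z, model$cfg$latent_ch, model$cfg$latent_len)
  B <- dim(z)[3]
  if (is.null(dim(cond))) cond <- matrix(cond, ncol = B)
  if (nrow(cond) != model$cfg$cond_dim)
    stop(sprintf("condition length %d != configured cond_dim %d",
                 nrow(cond), model$cfg$cond_dim))
  t <- as.integer(rep_len(t, B))
  if (any(t < 1L | t > model$cfg$T_steps)) stop("t out of range 1..T")
  S <- length(model$cfg$channels)
  m <- model
  m$t_batch <- t
  temb <- t(m$time_table$value[t, , drop = FALSE])   # d x B

  h <- m$stem$fwd(z)
  skips <- vector("list", S - 1)
  for (i in seq_len(S - 1)) {
    h <- .badd(h, m$down_t[[i]]$fwd(temb))
    h <- m$down_ln[[i]]$fwd(m$down_act[[i]]$fwd(m$down_conv[[i]]$fwd(h)))
    skips[[i]] <- h
    h <- m$down_pool[[i]]$fwd(h)
  }
  h <- .badd(h, m$mid_t$fwd(temb))
  h <- m$mid_sattn$fwd(h)
  h <- m$mid_xattn$fwd(h, cond)
  h <- m$mid_ln$fwd(m$mid_act$fwd(m$mid_conv$fwd(h)))
  for (i in rev(seq_len(S - 1))) {
    h <- m$up_conv1[[i]]$fwd(m$up_us[[i]]$fwd(h))
    h <- m$up_conv2[[i]]$fwd(skip_concat(h, skips[[i]]))
    h <- .badd(h, m$up_t[[i]]$fwd(temb))
    h <- m$up_act[[i]]$fwd(h)
    if (!is.null(m$up_xattn[[i]])) h <- m$up_xattn[[i]]$fwd(h, cond)
    h <- m$up_ln[[i]]$fwd(h)
  }
  out <- m$head$fwd(h)
  if (single) out <- array(out, dim = dim(out)[1:2])
  out
}

# backward companion of unet_forward; accumulates parameter gradients and
# scatters the time-embedding gradient into the table rows used by the batch
unet_backward <- function(model, dy) {
  m <- model
  S <- length(m$cfg$channels)
  if (is.matrix(dy)) dy <- array(dy, dim = c(dim(dy), 1L))
  B <- dim(dy)[3]
  dtemb <- matrix(0, m$cfg$time_dim, B)
  sum_len <- function(g) apply(g, c(1, 3), sum)  # collapse broadcast add

  dh <- m$head$bwd(dy)
  dskips <- vector("list", S - 1)
  for (i in seq_len(S - 1)) {
    dh <- m$up_ln[[i]]$bwd(dh)
    if (!is.null(m$up_xattn[[i]])) dh <- m$up_xattn[[i]]$bwd(dh)$dx
    dh <- m$up_act[[i]]$bwd(dh)
    dtemb <- dtemb + m$up_t[[i]]$bwd(sum_len(dh))
    dcat <- m$up_conv2[[i]]$bwd(dh)
    ci <- m$cfg$channels[i]
    dskips[[i]] <- dcat[ci + seq_len(ci), , , drop = FALSE]
    dh <- m$up_us[[i]]$bwd(m$up_conv1[[i]]$bwd(dcat[seq_len(ci), , , drop = FALSE]))
  }
  dh <- m$mid_ln$bwd(dh)
  dh <- m$mid_act$bwd(dh)
  dh <- m$mid_conv$bwd(dh)
  dh <- m$mid_xattn$bwd(dh)$dx
  dh <- m$mid_sattn$bwd(dh)
  dtemb <- dtemb + m$mid_t$bwd(sum_len(dh))
  for (i in rev(seq_len(S - 1))) {
    dh <- m$down_pool[[i]]$bwd(dh)
    dh <- dh + dskips[[i]]
    dh <- m$down_conv[[i]]$bwd(m$down_act[[i]]$bwd(m$down_ln[[i]]$bwd(dh)))
    dtemb <- dtemb + m$down_t[[i]]$bwd(sum_len(dh))
  }
  dz <- m$stem$bwd(dh)
  acc <- rowsum(t(dtemb), group = m$t_batch)
  rows <- as.integer(rownames(acc))
  m$time_table$grad[rows, ] <- m$time_table$grad[rows, , drop = FALSE] + acc
  dz
}
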
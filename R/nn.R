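# Minimal neural-network kernel: 1D conv / dense / layernorm / attention
# layers with explicit forward+backward and an Adam optimizer.
#
# Tensor layout is [channels, length, batch] (column-major friendly).
# Each layer is an environment holding its parameters and a one-deep
# forward cache; the usage contract is strictly fwd() then bwd() once,
# single-threaded. Parameters are environments with $value / $grad and
# Adam moments so layers can share them by reference.

nn_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- value * 0    # keeps the value's shape (vector vs matrix)
  p$m <- p$grad
  p$v <- p$grad
  p
}

nn_zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

#' @keywords internal
nn_adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (p in params) {
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    p$value <- p$value - lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
  }
  invisible(NULL)
}

# He-style fan-in initialization
nn_init_w <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

## ---- 1D convolution (im2col) ------------------------------------------

# x: [C_in, L, B]; weight W: [C_out, C_in*k]; zero padding `pad` each side,
# stride `s`. Output [C_out, L_out, B].
layer_conv1d <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  ly <- new.env(parent = emptyenv())
  ly$W <- nn_param(nn_init_w(out_ch, in_ch * k, in_ch * k))
  ly$b <- nn_param(numeric(out_ch))
  ly$in_ch <- in_ch; ly$out_ch <- out_ch
  ly$k <- as.integer(k); ly$stride <- as.integer(stride); ly$pad <- as.integer(pad)
  ly$params <- list(ly$W, ly$b)

  ly$fwd <- function(x) {
    d <- dim(x)
    stopifnot(length(d) == 3L, d[1] == in_ch)
    L <- d[2]; B <- d[3]
    Lp <- L + 2L * ly$pad
    Lout <- (Lp - ly$k) %/% ly$stride + 1L
    xp <- array(0, dim = c(in_ch, Lp, B))
    xp[, (ly$pad + 1L):(ly$pad + L), ] <- x
    pos0 <- seq.int(1L, by = ly$stride, length.out = Lout)
    # per-tap matmul: y = sum_j W_j x[., pos0+j-1, .] avoids materializing
    # the full im2col matrix (memory traffic dominates at these sizes)
    Y <- matrix(ly$b$value, out_ch, Lout * B)
    for (j in seq_len(ly$k)) {
      Xj <- xp[, pos0 + (j - 1L), , drop = FALSE]
      dim(Xj) <- c(in_ch, Lout * B)
      Y <- Y + ly$W$value[, (j - 1L) * in_ch + seq_len(in_ch), drop = FALSE] %*% Xj
    }
    ly$xp <- xp
    ly$dims <- c(L = L, B = B, Lp = Lp, Lout = Lout)
    array(Y, dim = c(out_ch, Lout, B))
  }

  ly$bwd <- function(dy) {
    dm <- ly$dims
    L <- dm[["L"]]; B <- dm[["B"]]; Lp <- dm[["Lp"]]; Lout <- dm[["Lout"]]
    dY <- matrix(dy, nrow = out_ch)
    ly$b$grad <- ly$b$grad + rowSums(dY)
    dxp <- array(0, dim = c(in_ch, Lp, B))
    pos0 <- seq.int(1L, by = ly$stride, length.out = Lout)
    for (j in seq_len(ly$k)) {
      cols <- (j - 1L) * in_ch + seq_len(in_ch)
      pj <- pos0 + (j - 1L)
      Xj <- ly$xp[, pj, , drop = FALSE]
      dim(Xj) <- c(in_ch, Lout * B)
      ly$W$grad[, cols] <- ly$W$grad[, cols, drop = FALSE] + tcrossprod(dY, Xj)
      dXj <- crossprod(ly$W$value[, cols, drop = FALSE], dY)
      dim(dXj) <- c(in_ch, Lout, B)
      dxp[, pj, ] <- dxp[, pj, , drop = FALSE] + dXj
    }
    dxp[, (ly$pad + 1L):(ly$pad + L), , drop = FALSE]
  }
  ly
}

## ---- dense ------------------------------------------------------------

# x: [in, B] matrix
layer_dense <- function(in_dim, out_dim) {
  ly <- new.env(parent = emptyenv())
  ly$W <- nn_param(nn_init_w(out_dim, in_dim, in_dim))
  ly$b <- nn_param(numeric(out_dim))
  ly$params <- list(ly$W, ly$b)
  ly$fwd <- function(x) {
    ly$x <- x
    ly$W$value %*% x + ly$b$value
  }
  ly$bwd <- function(dy) {
    ly$W$grad <- ly$W$grad + dy %*% t(ly$x)
    ly$b$grad <- ly$b$grad + rowSums(dy)
    crossprod(ly$W$value, dy)
  }
  ly
}

## ---- activations ------------------------------------------------------

layer_silu <- function() {
  ly <- new.env(parent = emptyenv())
  ly$params <- list()
  ly$fwd <- function(x) {
    s <- 1 / (1 + exp(-x))
    ly$x <- x; ly$s <- s
    x * s
  }
  ly$bwd <- function(dy) dy * (ly$s + ly$x * ly$s * (1 - ly$s))
  ly
}

## ---- layer norm over channels -----------------------------------------

# Normalizes over the channel axis independently at each (position, batch).
layer_lnorm <- function(ch, eps = 1e-5) {
  ly <- new.env(parent = emptyenv())
  ly$g <- nn_param(rep(1, ch))
  ly$beta <- nn_param(numeric(ch))
  ly$params <- list(ly$g, ly$beta)
  ly$fwd <- function(x) {
    d <- dim(x)
    xm <- matrix(x, nrow = d[1])
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    va <- colMeans(xc^2)
    istd <- 1 / sqrt(va + eps)
    xh <- sweep(xc, 2, istd, `*`)
    ly$xh <- xh; ly$istd <- istd; ly$d <- d
    array(ly$g$value * xh + ly$beta$value, dim = d)
  }
  ly$bwd <- function(dy) {
    d <- ly$d
    dym <- matrix(dy, nrow = d[1])
    ly$g$grad <- ly$g$grad + rowSums(dym * ly$xh)
    ly$beta$grad <- ly$beta$grad + rowSums(dym)
    dxh <- dym * ly$g$value
    n <- d[1]
    # standard layernorm backward over the channel axis
    dx <- sweep(dxh - matrix(colMeans(dxh), n, ncol(dxh), byrow = TRUE) -
                  ly$xh * matrix(colMeans(dxh * ly$xh), n, ncol(dxh), byrow = TRUE),
                2, ly$istd, `*`)
    array(dx, dim = d)
  }
  ly
}

## ---- linear-interpolation upsampling x2 --------------------------------

# y[2i-1] = x[i]; y[2i] = (x[i] + x[i+1])/2 (last pair repeats the edge).
# Linear interpolation avoids the blocking harmonics of nearest-neighbour
# upsampling, which otherwise imprint a periodic artifact on decoded signals.
layer_upsample2 <- function() {
  ly <- new.env(parent = emptyenv())
  ly$params <- list()
  ly$fwd <- function(x) {
    d <- dim(x)
    ly$d <- d
    L <- d[2]
    nxt <- c(seq_len(L)[-1], L)
    y <- array(0, dim = c(d[1], 2L * L, d[3]))
    y[, seq(1L, 2L * L, by = 2L), ] <- x
    y[, seq(2L, 2L * L, by = 2L), ] <- (x + x[, nxt, , drop = FALSE]) / 2
    y
  }
  ly$bwd <- function(dy) {
    d <- ly$d
    L <- d[2]
    dodd <- dy[, seq(1L, 2L * L, by = 2L), , drop = FALSE]
    dev <- dy[, seq(2L, 2L * L, by = 2L), , drop = FALSE] / 2
    dx <- dodd + dev
    # scatter the x[i+1] half back (edge repeats onto the last sample)
    dx[, 2:L, ] <- dx[, 2:L, , drop = FALSE] + dev[, 1:(L - 1), , drop = FALSE]
    dx[, L, ] <- dx[, L, , drop = FALSE] + dev[, L, , drop = FALSE]
    dx
  }
  ly
}

## ---- self-attention over the length axis ------------------------------

# Residual scaled-dot-product self-attention; tokens are positions,
# features are channels. x: [C, L, B].
layer_self_attn <- function(ch) {
  ly <- new.env(parent = emptyenv())
  ly$Wq <- nn_param(nn_init_w(ch, ch, ch))
  ly$Wk <- nn_param(nn_init_w(ch, ch, ch))
  ly$Wv <- nn_param(nn_init_w(ch, ch, ch))
  ly$Wo <- nn_param(nn_init_w(ch, ch, ch) * 0.1)  # small: near-identity residual start
  ly$params <- list(ly$Wq, ly$Wk, ly$Wv, ly$Wo)
  ly$fwd <- function(x) {
    d <- dim(x); B <- d[3]
    ly$x <- x; ly$cache <- vector("list", B)
    y <- x
    sc <- 1 / sqrt(d[1])
    for (b in seq_len(B)) {
      X <- x[, , b, drop = FALSE]; dim(X) <- d[1:2]
      Q <- ly$Wq$value %*% X; K <- ly$Wk$value %*% X; V <- ly$Wv$value %*% X
      S <- crossprod(Q, K) * sc                # L x L, rows = queries
      A <- exp(S - apply(S, 1, max))
      A <- A / rowSums(A)
      O <- V %*% t(A)                          # C x L
      y[, , b] <- x[, , b] + ly$Wo$value %*% O
      ly$cache[[b]] <- list(X = X, Q = Q, K = K, V = V, A = A, O = O)
    }
    y
  }
  ly$bwd <- function(dy) {
    d <- dim(ly$x); B <- d[3]
    dx <- dy
    sc <- 1 / sqrt(d[1])
    for (b in seq_len(B)) {
      cb <- ly$cache[[b]]
      dyb <- dy[, , b, drop = FALSE]; dim(dyb) <- d[1:2]
      ly$Wo$grad <- ly$Wo$grad + dyb %*% t(cb$O)
      dO <- crossprod(ly$Wo$value, dyb)        # C x L
      dV <- dO %*% cb$A
      dA <- crossprod(cb$V, dO)                # L x L (keys x queries) -> careful
      dA <- t(dA)                              # rows = queries
      dS <- cb$A * (dA - rowSums(dA * cb$A)) * sc
      dQ <- cb$K %*% t(dS)
      dK <- cb$Q %*% dS
      ly$Wq$grad <- ly$Wq$grad + dQ %*% t(cb$X)
      ly$Wk$grad <- ly$Wk$grad + dK %*% t(cb$X)
      ly$Wv$grad <- ly$Wv$grad + dV %*% t(cb$X)
      dX <- crossprod(ly$Wq$value, dQ) + crossprod(ly$Wk$value, dK) +
        crossprod(ly$Wv$value, dV)
      dx[, , b] <- dx[, , b] + dX
    }
    dx
  }
  ly
}

## ---- cross-attention on a single condition token -----------------------

# The condition is one token, so the softmax over keys is identically 1 and
# the query/key projections are mathematically inert; only the value path is
# live. Residual: y = x + Wo %*% (Wv %*% c), broadcast along length.
layer_cross_attn <- function(ch, cond_dim) {
  ly <- new.env(parent = emptyenv())
  ly$Wv <- nn_param(nn_init_w(ch, cond_dim, cond_dim))
  ly$Wo <- nn_param(nn_init_w(ch, ch, ch) * 0.1)
  ly$params <- list(ly$Wv, ly$Wo)
  ly$fwd <- function(x, cond) {
    d <- dim(x)
    ly$d <- d; ly$cond <- cond
    ly$V <- ly$Wv$value %*% cond               # ch x B
    add <- ly$Wo$value %*% ly$V                # ch x B
    y <- x
    for (b in seq_len(d[3])) y[, , b] <- y[, , b] + add[, b]
    y
  }
  ly$bwd <- function(dy) {
    d <- ly$d
    dadd <- apply(dy, c(1, 3), sum)            # ch x B
    if (is.null(dim(dadd))) dadd <- matrix(dadd, nrow = d[1])
    ly$Wo$grad <- ly$Wo$grad + dadd %*% t(ly$V)
    dV <- crossprod(ly$Wo$value, dadd)
    ly$Wv$grad <- ly$Wv$grad + dV %*% t(ly$cond)
    dcond <- crossprod(ly$Wv$value, dV)
    list(dx = dy, dcond = dcond)
  }
  ly
}

nn_collect_params <- function(layers) {
  out <- list()
  for (ly in layers) out <- c(out, ly$params)
  out
}

## ---- functional attention ops (contract-level, no parameters) ----------

#' Scaled dot-product cross-attention
#'
#' Pure functional cross-attention used as the reference form of the
#' attention contract: queries come from the latent token sequence, keys and
#' values from the condition memory. With a single condition token the
#' softmax over keys is identically one and every output token receives the
#' same value vector, added residually.
#'
#' @param tokens numeric matrix, features x n_tokens (queries).
#' @param memory numeric matrix, features x n_memory (keys/values); a vector
#'   is treated as a single memory token.
#' @param residual logical; add the input tokens to the attention output.
#' @return matrix of the same shape as `tokens`.
#' @export
cross_attention <- function(tokens, memory, residual = TRUE) {
  if (is.null(dim(memory))) memory <- matrix(memory, ncol = 1)
  stopifnot(nrow(tokens) == nrow(memory))
  sc <- 1 / sqrt(nrow(tokens))
  S <- crossprod(tokens, memory) * sc          # n_tokens x n_memory
  A <- exp(S - apply(S, 1, max))
  A <- A / rowSums(A)
  out <- memory %*% t(A)                       # features x n_tokens
  if (residual) out + tokens else out
}

#' Scaled dot-product self-attention
#'
#' Functional residual self-attention along the token axis with identity
#' projections; permutation-equivariant since no positional signal is added.
#'
#' @param tokens numeric matrix, features x n_tokens.
#' @return matrix of the same shape as `tokens`.
#' @export
self_attention <- function(tokens) {
  cross_attention(tokens, tokens, residual = TRUE)
}
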
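# shared helpers: finite-difference gradient checker and small fixtures

num_grad <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + h; x2[i] <- x2[i] - h
    g[i] <- (f(x1) - f(x2)) / (2 * h)
  }
  g
}

rel_err <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(b)))

# small bank of smooth band-limited test signals [12, L, N]
smooth_signals <- function(N, L = 128L, seed = 1) {
  set.seed(seed)
  x <- array(0, dim = c(12, L, N))
  tt <- seq_len(L) / L
  for (i in seq_len(N)) {
    f <- sample(2:6, 1)
    base <- sin(2 * pi * f * tt) + 0.3 * cos(2 * pi * (f + 1) * tt)
    x[, , i] <- outer(runif(12, 0.5, 1.5), base)
  }
  x
}
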
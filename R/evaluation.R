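# Three-level evaluation of generated ECGs against real ones:
#   signal level    — Frechet distance between Gaussian moment-matches of
#                     encoder representations, plus k-NN manifold
#                     precision / recall / F1 (k = 3 by default);
#   feature level   — mean absolute error between the conditioning heart
#                     rate and the rate detected on the generated waveform;
#   diagnostic level— CLIP-style cosine alignment between text and signal
#                     representations in a jointly trained space.

#' Frechet distance between two representation sets
#'
#' `FID = ||mu_r - mu_g||^2 + Tr(S_r + S_g - 2 (S_r S_g)^{1/2})` on the
#' moment-matched Gaussians of the two sets. The matrix square root is
#' computed via the symmetric form S_r^{1/2} S_g S_r^{1/2} (eigenvalues
#' clamped at zero), which keeps the trace real; the result is clipped at 0.
#'
#' @param real,gen numeric matrices, N x D (rows are representations), equal
#'   D and N >= 2 each.
#' @return non-negative scalar; symmetric in its arguments.
#' @export
fid <- function(real, gen) {
  real <- as.matrix(real); gen <- as.matrix(gen)
  if (ncol(real) != ncol(gen)) stop("representation dimension mismatch")
  if (nrow(real) < 2 || nrow(gen) < 2) stop("need N >= 2 per set")
  mr <- colMeans(real); mg <- colMeans(gen)
  Sr <- stats::cov(real); Sg <- stats::cov(gen)
  er <- eigen(Sr, symmetric = TRUE)
  Sr2 <- er$vectors %*% (sqrt(pmax(er$values, 0)) * t(er$vectors))
  M <- Sr2 %*% Sg %*% Sr2
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  val <- sum((mr - mg)^2) + sum(diag(Sr)) + sum(diag(Sg)) -
    2 * sum(sqrt(pmax(ev, 0)))
  max(val, 0)
}

#' Manifold radius of a representation point
#'
#' Euclidean distance from `e_prime` (a member of `set`) to its k-th nearest
#' other point in `set`; one exact self-match is excluded so duplicated
#' points keep a zero radius at k = 1.
#'
#' @param e_prime numeric vector, a point of `set`.
#' @param set numeric matrix N x D with at least k + 1 points.
#' @param k neighbour order (default 3).
#' @return the k-NN radius.
#' @export
manifold_radius <- function(e_prime, set, k = 3L) {
  set <- as.matrix(set)
  if (nrow(set) < k + 1) stop("set must contain at least k + 1 points")
  d <- sqrt(colSums((t(set) - e_prime)^2))
  self <- which(d == 0)
  if (length(self)) d <- d[-self[1]]   # drop one self-match
  sort(d, partial = k)[k]
}

#' Hypersphere coverage indicator
#'
#' 1 iff `e` lies inside the manifold of `set`: the union of hyperspheres
#' centred at each member with its k-NN radius (boundary inclusive).
#'
#' @param e numeric vector. @param set matrix N x D. @param k neighbour order.
#' @return 0 or 1.
#' @export
covered <- function(e, set, k = 3L) {
  set <- as.matrix(set)
  radii <- vapply(seq_len(nrow(set)),
                  function(i) manifold_radius(set[i, ], set, k), 0)
  d <- sqrt(colSums((t(set) - e)^2))
  as.integer(any(d <= radii))
}

# k-NN radii for all points of a set (self excluded), vectorized
.knn_radii <- function(set, k) {
  D2 <- as.matrix(stats::dist(set))
  diag(D2) <- Inf
  apply(D2, 1, function(r) sort(r, partial = k)[k])
}

#' Manifold precision, recall and F1
#'
#' Precision: fraction of generated points inside the real manifold.
#' Recall: fraction of real points inside the generated manifold.
#' F1: harmonic mean (0 when precision + recall = 0). High precision with
#' low recall is the mode-collapse signature.
#'
#' @param real,gen matrices N x D, each with at least k + 1 points.
#' @param k neighbour order (default 3).
#' @return named numeric vector (precision, recall, f1).
#' @export
precision_recall_f1 <- function(real, gen, k = 3L) {
  real <- as.matrix(real); gen <- as.matrix(gen)
  if (ncol(real) != ncol(gen)) stop("representation dimension mismatch")
  if (nrow(real) < k + 1 || nrow(gen) < k + 1)
    stop("each set must contain at least k + 1 points")
  rr <- .knn_radii(real, k)
  rg <- .knn_radii(gen, k)
  cross <- .cross_dist(gen, real)             # |G| x |X|
  precision <- mean(apply(cross <= matrix(rr, nrow(gen), nrow(real),
                                          byrow = TRUE), 1, any))
  recall <- mean(apply(t(cross) <= matrix(rg, nrow(real), nrow(gen),
                                          byrow = TRUE), 1, any))
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

.cross_dist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Heart-rate mean absolute error
#'
#' Mean of |hr_ref - hr_gen| over paired lists: the conditioning heart rate
#' versus the rate detected on the corresponding generated waveform.
#'
#' @param hr_ref,hr_gen equal-length numeric vectors (bpm); pairs where the
#'   detected rate is NA are dropped (all-NA gives NA).
#' @return bpm >= 0.
#' @export
heart_rate_mae <- function(hr_ref, hr_gen) {
  if (length(hr_ref) != length(hr_gen) || !length(hr_ref))
    stop("hr_ref and hr_gen must be equal-length, non-empty")
  ok <- !is.na(hr_ref) & !is.na(hr_gen)
  if (!any(ok)) return(NA_real_)
  mean(abs(hr_ref[ok] - hr_gen[ok]))
}

#' CLIP-style alignment score
#'
#' Cosine similarity between a text representation and a signal
#' representation in the shared space.
#'
#' @param r_text,r_signal equal-length nonzero numeric vectors.
#' @return value in [-1, 1].
#' @export
clip_score <- function(r_text, r_signal) {
  if (length(r_text) != length(r_signal)) stop("dimension mismatch")
  nt <- sqrt(sum(r_text^2)); ns <- sqrt(sum(r_signal^2))
  if (nt == 0 || ns == 0) stop("zero vector has no direction")
  sum(r_text * r_signal) / (nt * ns)
}

## ---- pluggable encoders ------------------------------------------------

#' Seeded random-projection signal encoder
#'
#' Deterministic stand-in for a pretrained ECG representation network:
#' projects the flattened 12-lead signal through a fixed seeded Gaussian
#' matrix (scaled by 1/sqrt(input dim)). Useful wherever the evaluation
#' contract only needs a fixed deterministic encoder.
#'
#' @param dim representation length. @param in_dim flattened signal length
#'   (12 * 1024 by default). @param seed integer seed.
#' @return a `signal_encoder` list with `dim` and `encode(signal)`.
#' @export
make_projection_encoder <- function(dim = 48L, in_dim = 12L * 1024L, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  W <- matrix(stats::rnorm(dim * in_dim, sd = 1 / sqrt(in_dim)), dim, in_dim)
  structure(list(dim = as.integer(dim),
                 encode = function(signal) as.numeric(W %*% as.vector(signal))),
            class = "signal_encoder")
}

#' Represent a collection of signals
#'
#' @param signals [12, L, N] array, list of matrices, or list of
#'   [ecg_record]s.
#' @param encoder a `signal_encoder`.
#' @return N x dim matrix of representations.
#' @export
represent_signals <- function(signals, encoder) {
  if (is.array(signals) && length(dim(signals)) == 3L) {
    signals <- lapply(seq_len(dim(signals)[3]), function(i) signals[, , i])
  } else if (is.list(signals)) {
    signals <- lapply(signals, function(s) if (inherits(s, "ecg_record")) s$signal else s)
  }
  t(vapply(signals, encoder$encode, numeric(encoder$dim)))
}

## ---- text-signal alignment model ---------------------------------------

#' Train a text-signal alignment model
#'
#' Jointly trains a small 1D CNN signal encoder and a 2-layer perceptron
#' text projector with a symmetric InfoNCE objective (temperature 0.07)
#' over in-batch pairs, so that matched (text embedding, signal) pairs score
#' a higher cosine than mismatched ones. Deterministic given `seed`.
#'
#' @param text matrix [text_dim x N] of text embeddings.
#' @param signals [12, L, N] array of (normalized) signals.
#' @param dim shared representation length (default 32).
#' @param steps training steps (default 150). @param lr Adam rate.
#' @param temperature InfoNCE temperature.
#' @param seed integer seed.
#' @return an `alignment_model` with `encode_signal(sig)`, `project_text(v)`.
#' @export
train_alignment_model <- function(text, signals, dim = 32L, steps = 150L,
                                  lr = 2e-3, temperature = 0.07, seed = 1) {
  stopifnot(length(dim(signals)) == 3L, ncol(text) == dim(signals)[3])
  N <- ncol(text)
  if (N < 2) stop("need at least 2 distinct pairs")
  if (max(apply(text, 1, stats::sd)) == 0)
    stop("degenerate data: all text embeddings identical")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  L <- dim(signals)[2]
  sc1 <- layer_conv1d(12L, 16L, 7L, stride = 4L)
  sa1 <- layer_silu()
  sc2 <- layer_conv1d(16L, 32L, 7L, stride = 4L)
  sa2 <- layer_silu()
  sd1 <- layer_dense(32L, dim)
  tp1 <- layer_dense(nrow(text), 64L)
  ta1 <- layer_silu()
  tp2 <- layer_dense(64L, dim)
  params <- c(sc1$params, sc2$params, sd1$params,
              tp1$params, ta1$params, tp2$params)

  enc_sig_fwd <- function(xb) {
    h <- sa2$fwd(sc2$fwd(sa1$fwd(sc1$fwd(xb))))
    pooled <- apply(h, c(1, 3), mean)          # C x B global mean pool
    list(out = sd1$fwd(pooled), h_len = dim(h)[2])
  }
  batch_size <- min(32L, N)
  for (step in seq_len(steps)) {
    idx <- sample.int(N, batch_size)
    xb <- signals[, , idx, drop = FALSE]
    tb <- text[, idx, drop = FALSE]
    B <- length(idx)

    es <- enc_sig_fwd(xb)
    S <- es$out                                 # dim x B
    Tx <- tp2$fwd(ta1$fwd(tp1$fwd(tb)))
    ns <- sqrt(colSums(S^2)) + 1e-12
    nt <- sqrt(colSums(Tx^2)) + 1e-12
    U <- sweep(S, 2, ns, `/`); V <- sweep(Tx, 2, nt, `/`)
    logits <- crossprod(U, V) / temperature     # B x B (rows signal)
    P <- exp(logits - apply(logits, 1, max)); P <- P / rowSums(P)
    Q <- exp(sweep(logits, 2, apply(logits, 2, max))); Q <- sweep(Q, 2, colSums(Q), `/`)
    I <- diag(B)
    dlogits <- ((P - I) + (Q - I)) / (2 * B) / temperature
    dU <- V %*% t(dlogits)
    dV <- U %*% dlogits
    dS <- sweep(dU - sweep(U, 2, colSums(dU * U), `*`), 2, ns, `/`)
    dT <- sweep(dV - sweep(V, 2, colSums(dV * V), `*`), 2, nt, `/`)

    nn_zero_grads(params)
    tp1$bwd(ta1$bwd(tp2$bwd(dT)))
    dpool <- sd1$bwd(dS)                        # C x B
    dh <- aperm(array(dpool / es$h_len, dim = c(32L, B, es$h_len)), c(1, 3, 2))
    sc1$bwd(sa1$bwd(sc2$bwd(sa2$bwd(dh))))
    nn_adam_step(params, lr, step)
  }
  structure(list(
    dim = as.integer(dim),
    encode_signal = function(sig) {
      xb <- if (is.matrix(sig)) array(sig, dim = c(dim(sig), 1L)) else sig
      as.numeric(enc_sig_fwd(xb)$out)
    },
    project_text = function(v) as.numeric(tp2$fwd(ta1$fwd(tp1$fwd(matrix(v, ncol = 1)))))
  ), class = "alignment_model")
}

#' Assemble the three-level metrics report
#'
#' Signal level: FID and manifold precision/recall/F1 on encoder
#' representations. Feature level: heart-rate MAE between the conditioning
#' rates and rates detected on the generated waveforms. Diagnostic level:
#' mean CLIP-style cosine over pairs (NA when no alignment model is given).
#'
#' @param real,generated lists of [ecg_record]s (equal-length pairing for the
#'   feature/diagnostic levels).
#' @param encoder a `signal_encoder` for the signal-level metrics.
#' @param k manifold neighbour order (default 3).
#' @param hr_ref conditioning heart rates; default taken from `real`.
#' @param alignment optional `alignment_model`.
#' @param text optional matrix [text_dim x N] of per-pair text embeddings
#'   (required for the diagnostic level).
#' @return a `metrics_report` list: fid, precision, recall, f1, hr_mae,
#'   clip_score.
#' @export
evaluate_three_level <- function(real, generated, encoder, k = 3L,
                                 hr_ref = NULL, alignment = NULL,
                                 text = NULL) {
  R <- represent_signals(real, encoder)
  G <- represent_signals(generated, encoder)
  prf <- precision_recall_f1(R, G, k)
  if (is.null(hr_ref))
    hr_ref <- vapply(real, `[[`, 0, "heart_rate")
  hr_gen <- vapply(generated, heart_rate_from_waveform, 0)
  clip <- NA_real_
  if (!is.null(alignment) && !is.null(text)) {
    clip <- mean(vapply(seq_along(generated), function(i) {
      clip_score(alignment$project_text(text[, i]),
                 alignment$encode_signal(generated[[i]]$signal))
    }, 0))
  }
  rep <- list(fid = fid(R, G),
              precision = unname(prf["precision"]),
              recall = unname(prf["recall"]),
              f1 = unname(prf["f1"]),
              hr_mae = heart_rate_mae(hr_ref, hr_gen),
              clip_score = clip)
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Three-level evaluation\n")
  cat(sprintf("  signal:     FID = %.4f | precision = %.3f  recall = %.3f  F1 = %.3f\n",
              x$fid, x$precision, x$recall, x$f1))
  cat(sprintf("  feature:    heart-rate MAE = %s bpm\n",
              ifelse(is.na(x$hr_mae), "NA", format(round(x$hr_mae, 2)))))
  cat(sprintf("  diagnostic: CLIP score = %s\n",
              ifelse(is.na(x$clip_score), "NA", format(round(x$clip_score, 3)))))
  invisible(x)
}
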
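# Evaluation metrics against brute-force oracles: FID closed forms,
# manifold precision/recall, heart-rate MAE, CLIP score, alignment training.

brute_radius <- function(i, set, k) {
  d <- sqrt(rowSums((set - matrix(set[i, ], nrow(set), ncol(set),
                                  byrow = TRUE))^2))
  sort(d[-i])[k]
}

brute_prf <- function(real, gen, k) {
  rr <- vapply(seq_len(nrow(real)), brute_radius, 0, set = real, k = k)
  rg <- vapply(seq_len(nrow(gen)), brute_radius, 0, set = gen, k = k)
  cov_g <- vapply(seq_len(nrow(gen)), function(i) {
    d <- sqrt(rowSums((real - matrix(gen[i, ], nrow(real), ncol(real),
                                     byrow = TRUE))^2))
    any(d <= rr)
  }, logical(1))
  cov_x <- vapply(seq_len(nrow(real)), function(i) {
    d <- sqrt(rowSums((gen - matrix(real[i, ], nrow(gen), ncol(gen),
                                    byrow = TRUE))^2))
    any(d <= rg)
  }, logical(1))
  p <- mean(cov_g); r <- mean(cov_x)
  c(p, r, if (p + r == 0) 0 else 2 * p * r / (p + r))
}

test_that("manifold radius matches brute-force sorted distances", {
  set <- matrix(c(0, 1, 2, 3, 10), ncol = 1)
  expect_equal(manifold_radius(0, set, k = 3), 3)
  expect_equal(manifold_radius(10, set, k = 3), 9)
  dup <- matrix(c(1, 1, 2, 5), ncol = 1)
  expect_equal(manifold_radius(1, dup, k = 1), 0)
  expect_error(manifold_radius(0, set, k = 5), "at least")
})

test_that("coverage is boundary-inclusive and rejects far points", {
  set <- matrix(c(0, 1, 2, 3, 10), ncol = 1)
  expect_equal(covered(2, set, k = 3), 1L)            # member, distance 0
  expect_equal(covered(1000, set, k = 3), 0L)
  # exact boundary: radius of point 0 at k=1 is 1; a point at distance 1
  cl <- matrix(c(0, 1, 2, 3), ncol = 1)
  r0 <- manifold_radius(0, cl, k = 1)
  expect_equal(covered(-r0, cl, k = 1), 1L)
})

test_that("vectorized precision/recall equals the O(N^2) brute force exactly", {
  set.seed(10)
  real <- matrix(rnorm(200 * 8), 200, 8)
  gen <- matrix(rnorm(200 * 8, mean = 0.3), 200, 8)
  fast <- precision_recall_f1(real, gen, k = 3)
  slow <- brute_prf(real, gen, k = 3)
  expect_identical(unname(fast), slow)

  same <- matrix(rnorm(10 * 3), 10, 3)
  expect_equal(unname(precision_recall_f1(same, same, k = 3)), c(1, 1, 1))

  far <- same + 1e4
  expect_equal(unname(precision_recall_f1(same, far, k = 3)), c(0, 0, 0))
})

test_that("mode collapse shows as precision far above recall", {
  set.seed(11)
  real <- matrix(rnorm(150 * 4, sd = 2), 150, 4)
  collapsed <- matrix(rnorm(150 * 4, sd = 0.01), 150, 4)  # one tight cluster
  prf <- precision_recall_f1(real, collapsed, k = 3)
  expect_gt(prf["precision"], prf["recall"] + 0.5)
})

test_that("enlarging the generated set cannot decrease recall", {
  set.seed(12)
  real <- matrix(rnorm(60 * 3), 60, 3)
  gen <- matrix(rnorm(30 * 3), 30, 3)
  bigger <- rbind(gen, matrix(rnorm(30 * 3), 30, 3))
  r1 <- precision_recall_f1(real, gen, k = 3)["recall"]
  r2 <- precision_recall_f1(real, bigger, k = 3)["recall"]
  expect_gte(r2, r1)
})

test_that("FID matches closed forms and is symmetric", {
  set.seed(13)
  A <- matrix(rnorm(500 * 2), 500, 2)
  expect_lt(fid(A, A), 1e-6)

  # shifted Gaussian: FID -> ||mu||^2 = 25
  n <- 1e5
  X <- matrix(rnorm(n * 2), n, 2)
  G <- cbind(rnorm(n, 3), rnorm(n, 4))
  expect_equal(fid(X, G), 25, tolerance = 0.05 * 25)

  # 1-D scale mismatch: FID -> (sigma_r - sigma_g)^2 = 1
  X1 <- matrix(rnorm(n), ncol = 1)
  G1 <- matrix(rnorm(n, sd = 2), ncol = 1)
  expect_equal(fid(X1, G1), 1, tolerance = 0.05)

  B <- matrix(rnorm(300 * 2, 1), 300, 2)
  expect_lt(abs(fid(A, B) - fid(B, A)), 1e-8)
  expect_gte(fid(A, B), 0)
  expect_error(fid(A, matrix(0, 10, 3)), "mismatch")
  expect_error(fid(A[1, , drop = FALSE], A), "N >= 2")
})

test_that("heart-rate MAE is the mean absolute pairwise error", {
  expect_equal(heart_rate_mae(c(60, 80), c(60, 80)), 0)
  expect_equal(heart_rate_mae(c(60, 80), c(65, 75)), 5)
  expect_equal(heart_rate_mae(100, 90), 10)
  expect_error(heart_rate_mae(1:3, 1:2), "equal-length")
  # bounded by the max pairwise error
  set.seed(14)
  a <- runif(20, 40, 160); b <- runif(20, 40, 160)
  expect_lte(heart_rate_mae(a, b), max(abs(a - b)))
  expect_gte(heart_rate_mae(a, b), 0)
})

test_that("CLIP score hits the cosine boundary values and scale invariance", {
  v <- c(1, 2, 3)
  expect_equal(clip_score(v, v), 1)
  expect_equal(clip_score(c(1, 0), c(0, 1)), 0)
  expect_equal(clip_score(v, -v), -1)
  expect_equal(clip_score(5 * v, 0.1 * v), 1)
  expect_error(clip_score(v, 0 * v), "zero")
  w <- c(-2, 1, 0.5)
  expect_equal(clip_score(3 * v, w), clip_score(v, w))
})

test_that("alignment training separates matched from mismatched pairs", {
  # reports deterministically encode the beat rate; embeddings via hashing
  set.seed(15)
  n <- 48
  hrs <- runif(n, 40, 160)
  emb <- make_hash_embedder(32L, seed = 2L)
  text <- vapply(hrs, function(h) {
    emb$embed(build_prompt(if (h < 60) "sinus bradycardia"
                           else if (h <= 100) "sinus rhythm"
                           else "sinus tachycardia"))
  }, numeric(32))
  L <- 256L
  sigs <- array(0, dim = c(12, L, n))
  tt <- seq_len(L) / 25.6
  for (i in seq_len(n)) {
    base <- rowSums(vapply(seq(0.2, 10, by = 60 / hrs[i]), function(b)
      exp(-0.5 * ((tt - b) / 0.05)^2), numeric(L)))
    sigs[, , i] <- outer(runif(12, 0.5, 1.5), base) + rnorm(12 * L, 0, 0.02)
  }
  am <- train_alignment_model(text, sigs, dim = 16L, steps = 120L, seed = 3)
  # determinism
  am2 <- train_alignment_model(text, sigs, dim = 16L, steps = 120L, seed = 3)
  expect_identical(am$encode_signal(sigs[, , 1]), am2$encode_signal(sigs[, , 1]))

  cos_pair <- function(model, i, j) {
    clip_score(model$project_text(text[, i]), model$encode_signal(sigs[, , j]))
  }
  matched <- mean(vapply(seq_len(n), function(i) cos_pair(am, i, i), 0))
  set.seed(16)
  perm <- sample(n)
  mismatched <- mean(vapply(seq_len(n), function(i) cos_pair(am, i, perm[i]), 0))
  expect_gt(matched, mismatched)

  expect_error(train_alignment_model(text[, 1, drop = FALSE],
                                     sigs[, , 1, drop = FALSE]), "at least 2")
})

test_that("the three-level report is internally consistent on a self-evaluation", {
  ds0 <- synth_dataset(12, seed = 17)
  ds <- preprocess_records(ds0$records)
  enc <- make_projection_encoder(16L, in_dim = 12L * 1024L, seed = 4)
  rep <- evaluate_three_level(ds$records, ds$records, enc, k = 3)
  expect_lt(rep$fid, 1e-6)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$f1, 1)
  expect_lt(rep$hr_mae, 2.5)    # detector error only
  expect_true(is.na(rep$clip_score))
  expect_true(rep$precision >= 0 && rep$precision <= 1)
})
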
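test_that("oversampling balances per-epoch class counts", {
  set.seed(1)
  idx <- oversample_indices(c(0, 0, 0, 0, 1))
  expect_length(idx, 8)
  lab <- c(0, 0, 0, 0, 1)[idx]
  expect_equal(sum(lab == 0), 4)
  expect_equal(sum(lab == 1), 4)
  expect_true(all(idx[lab == 1] == 5))
  ## the clinical training cohort ratio: 59 negative / 16 positive -> 59:59
  lab2 <- rep(c(0, 1), c(59, 16))
  idx2 <- oversample_indices(lab2)
  expect_equal(as.vector(table(lab2[idx2])), c(59L, 59L))
  ## balanced input: a permutation of the original indices
  idx3 <- oversample_indices(rep(0:1, 5))
  expect_setequal(idx3, 1:10)
  expect_error(oversample_indices(rep(1, 4)), "both classes")
})

test_that("reverse weighting is inverse to class frequency, mean-normalized", {
  w <- reverse_weights(c(59, 16))
  expect_equal(w[1] / w[2], 16 / 59)
  expect_equal(mean(w), 1)
  expect_gt(w[2], w[1])   # tail class gets the higher weight
  expect_equal(reverse_weights(c(7, 7)), c(1, 1))
  expect_error(reverse_weights(c(5, 0)), "positive")
})

test_that("cosine similarity matrix matches a double-loop oracle", {
  set.seed(2)
  G <- matrix(rnorm(40), 4, 10)
  S <- cosine_similarity_matrix(G)
  ref <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    ref[i, j] <- sum(G[i, ] * G[j, ]) /
      (sqrt(sum(G[i, ]^2)) * sqrt(sum(G[j, ]^2)))
  expect_equal(S, ref, tolerance = 1e-6)
  expect_equal(S, t(S))
  expect_equal(diag(S), rep(1, 4))
  expect_true(all(S >= -1 & S <= 1))
  ## exact special values
  G2 <- rbind(c(1, 0), c(1, 0), c(0, 2))
  S2 <- cosine_similarity_matrix(G2)
  expect_equal(S2[1, 2], 1)
  expect_equal(S2[1, 3], 0)
  ## zero gradients get similarity 0, never penalized
  S3 <- cosine_similarity_matrix(rbind(c(0, 0), c(1, 1)))
  expect_equal(S3[1, 2], 0)
  expect_equal(diag(S3), c(0, 1))
})

test_that("penalty factors implement the thresholded shrink rule", {
  ## duplicated pair forces lambda on both
  Sdup <- cosine_similarity_matrix(rbind(c(1, 2), c(1, 2), c(-2, 1)))
  f <- penalty_factors(Sdup, epsilon = 0.9, lambda = 0.5)
  expect_equal(f, c(0.5, 0.5, 1))
  ## mutually orthogonal batch untouched
  f0 <- penalty_factors(cosine_similarity_matrix(diag(4)), 0.9, 0.5)
  expect_equal(f0, rep(1, 4))
  expect_error(penalty_factors(Sdup, epsilon = 1.5), "epsilon")
  expect_error(penalty_factors(Sdup, epsilon = 0.9, lambda = 0), "lambda")
})

test_that("penalty factors match an any-pair-exceeds-threshold oracle", {
  set.seed(3)
  for (rep in 1:20) {
    G <- matrix(rnorm(6 * 5), 6, 5)
    if (rep %% 3 == 0) G[2, ] <- G[1, ] * runif(1, 0.5, 2)   # plant duplicates
    S <- cosine_similarity_matrix(G)
    eps <- runif(1, 0.3, 0.95)
    f <- penalty_factors(S, eps, 0.5)
    ref <- sapply(1:6, function(i) {
      hit <- any(sapply(setdiff(1:6, i), function(j) S[i, j] > eps))
      if (hit) 0.5 else 1
    })
    expect_equal(f, ref)
  }
})

test_that("penalty factors are monotone in epsilon", {
  set.seed(4)
  G <- matrix(rnorm(8 * 6), 8, 6)
  G[3, ] <- G[7, ] + rnorm(6, sd = 0.05)
  S <- cosine_similarity_matrix(G)
  eps_grid <- seq(0.1, 0.95, by = 0.05)
  n_pen <- sapply(eps_grid, function(e) sum(penalty_factors(S, e, 0.5) < 1))
  expect_true(all(diff(n_pen) <= 0))
})

test_that("penalized aggregation scales and reduces to the plain mean", {
  set.seed(5)
  G <- matrix(rnorm(4 * 7), 4, 7)
  ## all factors one: exactly the unpenalized mean gradient
  expect_identical(apply_gradient_penalty(G, rep(1, 4)), colMeans(G))
  ## two identical samples at lambda 0.5: aggregate is half the plain one
  G2 <- rbind(G[1, ], G[1, ])
  f2 <- penalty_factors(cosine_similarity_matrix(G2), 0.9, 0.5)
  expect_equal(apply_gradient_penalty(G2, f2),
               0.5 * apply_gradient_penalty(G2, rep(1, 2)))
  ## random batch vs per-sample loop oracle
  f <- c(0.5, 1, 0.7, 1)
  ref <- Reduce(`+`, lapply(1:4, function(i) f[i] * G[i, ])) / 4
  expect_equal(apply_gradient_penalty(G, f), ref, tolerance = 1e-12)
})

test_that("shrinking non-negatively aligned gradients cannot grow the aggregate", {
  set.seed(6)
  base <- rnorm(10)
  G <- t(sapply(1:5, function(i) base * runif(1, 0.8, 1.2) + rnorm(10, sd = 0.01)))
  S <- cosine_similarity_matrix(G)
  f <- penalty_factors(S, 0.9, 0.5)
  expect_true(any(f < 1))
  plain <- apply_gradient_penalty(G, rep(1, 5))
  pen <- apply_gradient_penalty(G, f)
  expect_lte(sqrt(sum(pen^2)), sqrt(sum(plain^2)))
})

test_that("per-sample network gradients drive the penalty as in training", {
  m <- tiny_model(seed = 15)
  x <- tiny_images(4, seed = 8)
  x[, 2] <- x[, 1]                       # an oversampled duplicate
  y <- c(1L, 1L, 0L, 0L)
  fw <- rtn_forward(m, x, train = TRUE, keep = TRUE)
  probs <- restransnet:::softmax_rows(fw$logits)
  dlog <- probs
  dlog[cbind(1:4, y + 1L)] <- dlog[cbind(1:4, y + 1L)] - 1
  G <- per_sample_gradients(m, fw$cache, dlog, scope = "full")
  S <- cosine_similarity_matrix(G)
  expect_gt(S[1, 2], 0.999)              # duplicates have identical gradients
  f <- penalty_factors(S, 0.9, 0.5)
  expect_equal(f[1:2], c(0.5, 0.5))
  ## the head_last scope preserves the duplicate-similarity structure
  Ghl <- per_sample_gradients(m, fw$cache, dlog, scope = "head_last")
  expect_gt(cosine_similarity_matrix(Ghl)[1, 2], 0.999)
})
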
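## Shared fixtures, built in code. The tiny architecture keeps unit tests
## fast; the demo fit (memoized across test files) provides a weakly trained
## model for tests that need learned weights.

tiny_config <- function(n_blocks = 2L, d = 8L, heads = 2L)
  rtn_model_config(img_size = 16L, channels = c(2L, 3L, 4L),
                   n_blocks = n_blocks, d = d, heads = heads,
                   patch_grid = 2L, mlp_ratio = 2L)

tiny_model <- function(seed = 1L, ...) rtn_build(tiny_config(...), seed = seed)

tiny_images <- function(B, seed = 1L, size = 16L) {
  set.seed(seed)
  matrix(runif(size * size * B), size * size, B)
}

## a ramp image where pixel (r, c) = r + 1000 * c, for index-arithmetic checks
ramp_image <- function(n = 512L)
  outer(seq_len(n), seq_len(n), function(r, c) r + 1000 * c)

.fixture_env <- new.env(parent = emptyenv())

## weakly trained full-resolution model on a separable synthetic cohort,
## computed once per test session
demo_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    co <- generate_synthetic_cohort(n_patients = 60, images_per_patient = 1,
                                    effect_size = 3, survival_link = NULL,
                                    seed = 402)
    .fixture_env$fit <- restransnet(
      co,
      config = rtn_train_config(epochs = 8, batch_size = 24, seed = 402),
      model_config = rtn_model_config(n_blocks = 2L, d = 32L))
    .fixture_env$cohort <- co
  }
  .fixture_env$fit
}

demo_cohort <- function() {
  demo_fit()
  .fixture_env$cohort
}

## scalar reference implementation of one pre-norm transformer block
## (independent of the package's vectorized path)
loop_transformer_block <- function(X, w, heads) {
  d <- ncol(X); n <- nrow(X); dk <- d / heads
  ln <- function(v, g, b) {
    m <- mean(v); s <- sqrt(max(mean(v^2) - m^2, 0) + 1e-5)
    ((v - m) / s) * g + b
  }
  Xn <- t(sapply(seq_len(n), function(i) ln(X[i, ], w$ln1_g, w$ln1_b)))
  lin <- function(M, W, b) {
    out <- matrix(0, nrow(M), ncol(W))
    for (i in seq_len(nrow(M))) for (j in seq_len(ncol(W)))
      out[i, j] <- sum(M[i, ] * W[, j]) + b[j]
    out
  }
  Q <- lin(Xn, w$Wq, w$bq); K <- lin(Xn, w$Wk, w$bk); V <- lin(Xn, w$Wv, w$bv)
  AO <- matrix(0, n, d)
  for (h in seq_len(heads)) {
    ci <- ((h - 1) * dk + 1):(h * dk)
    for (i in seq_len(n)) {
      s <- numeric(n)
      for (j in seq_len(n)) s[j] <- sum(Q[i, ci] * K[j, ci]) / sqrt(dk)
      a <- exp(s - max(s)); a <- a / sum(a)
      for (cc in ci) AO[i, cc] <- sum(a * V[, cc])
    }
  }
  Z <- lin(AO, w$Wo, w$bo) + X
  Zn <- t(sapply(seq_len(n), function(i) ln(Z[i, ], w$ln2_g, w$ln2_b)))
  H1 <- lin(Zn, w$W1, w$b1)
  Hg <- H1 * pnorm(H1)
  lin(Hg, w$W2, w$b2) + Z
}
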
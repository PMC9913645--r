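test_that("backbone produces the expected 64-channel 16x16 feature map", {
  m <- rtn_build(rtn_model_config(n_blocks = 1L, d = 16L), seed = 1)
  img <- matrix(runif(128 * 128), 128, 128)
  fm <- conv_backbone(m, img)
  expect_equal(dim(fm), c(64L, 16L, 16L))
  expect_true(all(is.finite(fm)))
})

test_that("zeroed residual branch reduces a block to its projection path", {
  m <- tiny_model(seed = 2)
  ## zero the residual branch of block 1: output = ReLU(BN(proj(x)))
  m$params$bb1_conv2_W[] <- 0
  x <- tiny_images(3, seed = 4)
  rb <- restransnet:::res_block_fwd(x, m$params, m$state, 1L, m$plans, 3L,
                                    train = FALSE, keep = FALSE)
  pl <- m$plans$cp_1
  proj <- restransnet:::conv_fwd(x, m$params$bb1_proj_W, pl)
  ref <- pmax(proj, 0)  # eval-mode BN with fresh state (rm=0, rv=1) ~ identity
  expect_equal(restransnet:::cpp_tall2pbc(rb$tall, 2L, pl$P, 3L),
               unclass(ref), tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("attention handles degenerate cases exactly", {
  set.seed(5)
  V <- matrix(rnorm(8), 1, 8)
  ## single token: softmax of a scalar is 1, output == V
  out <- attention(matrix(rnorm(8), 1, 8), matrix(rnorm(8), 1, 8), V)
  expect_equal(out$out, V)
  ## identical key rows: uniform attention, output is the mean of V rows
  K <- matrix(rep(rnorm(4), each = 3), 3, 4)
  V3 <- matrix(rnorm(12), 3, 4)
  out2 <- attention(matrix(rnorm(4), 1, 4), K, V3)
  expect_equal(as.vector(out2$out), colMeans(V3), tolerance = 1e-12)
  expect_equal(rowSums(out2$A), 1)
  expect_error(attention(matrix(0, 1, 3), matrix(0, 1, 4), V3), "shapes")
})

test_that("attention matches a loop-based softmax-weighted sum oracle", {
  set.seed(6)
  for (rep in 1:5) {
    Q <- matrix(rnorm(12), 3, 4); K <- matrix(rnorm(12), 3, 4)
    V <- matrix(rnorm(12), 3, 4)
    got <- attention(Q, K, V)$out
    ref <- matrix(0, 3, 4)
    for (i in 1:3) {
      s <- sapply(1:3, function(j) sum(Q[i, ] * K[j, ]) / sqrt(4))
      a <- exp(s) / sum(exp(s))
      for (cc in 1:4) ref[i, cc] <- sum(a * V[, cc])
    }
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("transformer block matches the scalar loop oracle on a 3-token instance", {
  set.seed(7)
  d <- 4L
  w <- list(ln1_g = runif(d, 0.5, 1.5), ln1_b = rnorm(d),
            Wq = matrix(rnorm(16), d, d), bq = rnorm(d),
            Wk = matrix(rnorm(16), d, d), bk = rnorm(d),
            Wv = matrix(rnorm(16), d, d), bv = rnorm(d),
            Wo = matrix(rnorm(16), d, d), bo = rnorm(d),
            ln2_g = runif(d, 0.5, 1.5), ln2_b = rnorm(d),
            W1 = matrix(rnorm(d * 8), d, 8), b1 = rnorm(8),
            W2 = matrix(rnorm(8 * d), 8, d), b2 = rnorm(d))
  X <- matrix(rnorm(3 * d), 3, d)
  got <- transformer_block(X, w, heads = 1L)$Y
  ref <- loop_transformer_block(X, w, heads = 1L)
  expect_equal(got, ref, tolerance = 1e-5)
})

test_that("zeroed MSA and MLP output weights make each block the identity", {
  m <- tiny_model(seed = 8)
  for (j in 1:2) {
    m$params[[paste0("t", j, "_Wo")]][] <- 0
    m$params[[paste0("t", j, "_bo")]][] <- 0
    m$params[[paste0("t", j, "_W2")]][] <- 0
    m$params[[paste0("t", j, "_b2")]][] <- 0
  }
  X <- matrix(rnorm(5 * 8), 5, 8)
  w <- restransnet:::tf_weights(m$params, 1)
  out <- transformer_block(X, w, heads = 2L)
  expect_identical(out$Y, X + 0)  # exact residual identity
})

test_that("shapes are conserved through the transformer stack", {
  m <- tiny_model(seed = 9)
  X <- matrix(rnorm(10 * 8), 10, 8)
  for (j in 1:2) {
    X2 <- transformer_block(X, restransnet:::tf_weights(m$params, j), heads = 2L)$Y
    expect_equal(dim(X2), dim(X))
    X <- X2
  }
})

test_that("patch embedding yields the expected sequence geometry", {
  cfg <- tiny_config()   # 16x16 input -> 2x2 map? map = 16/8 = 2, grid 2 -> 4 patches
  expect_equal(cfg$n_patches, 4L)
  m <- tiny_model(seed = 10)
  fw <- rtn_forward(m, tiny_images(2, seed = 1), train = FALSE, keep = TRUE)
  expect_equal(dim(fw$cache$pm), c(cfg$channels[3] * cfg$patch_side^2,
                                   cfg$n_patches * 2L))
  expect_equal(fw$cache$cr, c(1L, cfg$n_patches + 2L))
  ## degenerate grid: one patch -> sequence length 2 with class token
  cfg1 <- rtn_model_config(img_size = 16L, channels = c(2L, 3L, 4L),
                           n_blocks = 1L, d = 8L, heads = 2L, patch_grid = 1L,
                           mlp_ratio = 2L)
  m1 <- rtn_build(cfg1, seed = 1)
  fw1 <- rtn_forward(m1, tiny_images(1), train = FALSE, keep = TRUE)
  expect_equal(nrow(fw1$cache$tf[[1]]$X), 2L)
})

test_that("with zero position embeddings the class logits are patch-permutation invariant", {
  m <- tiny_model(seed = 11)
  m$params$pos[] <- 0
  x <- tiny_images(1, seed = 3)
  base <- rtn_forward(m, x, train = FALSE)$logits
  ## permute patches by permuting the gather index blocks
  set.seed(4)
  pdim <- 4L   # C * patch_side^2 = 4 * 1
  perm <- sample(4)
  blocks <- split(m$pidx, rep(seq_len(4), each = pdim))
  m$pidx <- unlist(blocks[perm], use.names = FALSE)
  permuted <- rtn_forward(m, x, train = FALSE)$logits
  expect_equal(base, permuted, tolerance = 1e-10)
})

test_that("with learned position embeddings patch order changes the logits", {
  m <- tiny_model(seed = 12)
  x <- tiny_images(1, seed = 3)
  base <- rtn_forward(m, x, train = FALSE)$logits
  set.seed(5)
  pdim <- 4L
  perm <- c(2, 1, 4, 3)
  blocks <- split(m$pidx, rep(seq_len(4), each = pdim))
  m$pidx <- unlist(blocks[perm], use.names = FALSE)
  permuted <- rtn_forward(m, x, train = FALSE)$logits
  expect_gt(max(abs(base - permuted)), 1e-8)
})

test_that("forward pass is normalized, deterministic, and batch-invariant in eval mode", {
  m <- tiny_model(seed = 13)
  x <- tiny_images(4, seed = 6)
  fw <- rtn_forward(m, x, train = FALSE)
  expect_equal(dim(fw$logits), c(4L, 2L))
  p <- restransnet:::softmax_rows(fw$logits)
  expect_equal(rowSums(p), rep(1, 4))
  ## identical images in one batch -> identical logits
  x2 <- cbind(x[, 1], x[, 1])
  fw2 <- rtn_forward(m, x2, train = FALSE)
  expect_equal(fw2$logits[1, ], fw2$logits[2, ])
  ## per-sample output independent of batch composition (no BN batch stats)
  single <- rtn_forward(m, x[, 3, drop = FALSE], train = FALSE)$logits
  expect_equal(unname(fw$logits[3, ]), unname(as.vector(single)), tolerance = 1e-12)
})

test_that("cross-entropy loss matches its closed forms", {
  expect_equal(ce_loss(1 - 1e-12, 1), 0, tolerance = 1e-6)
  expect_equal(ce_loss(0.5, 1), log(2))
  expect_equal(ce_loss(c(0.9, 0.2), c(1, 0), reduction = "sum"),
               -(log(0.9) + log(0.8)))
  expect_equal(ce_loss(c(0.9, 0.2), c(1, 0)), -(log(0.9) + log(0.8)) / 2)
  ## per-class weights scale the per-sample terms
  expect_equal(ce_loss(c(0.9, 0.2), c(1, 0), class_weights = c(1, 2),
                       reduction = "sum"),
               -(2 * log(0.9) + log(0.8)))
  expect_error(ce_loss(0.5, 2), "0/1")
  ## clamping keeps impossible predictions finite
  expect_true(is.finite(ce_loss(0, 1)))
})

test_that("checkpoints round-trip with identical predictions", {
  m <- tiny_model(seed = 14)
  x <- tiny_images(3, seed = 7)
  path <- tempfile(fileext = ".rds")
  rtn_save(m, path)
  m2 <- rtn_load(path)
  expect_equal(rtn_predict(m, x), rtn_predict(m2, x))
  unlink(path)
})
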
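## The hybrid residual-CNN / transformer network: construction, forward pass,
## and hand-written backpropagation.
##
## Architecture: three ResNet-style residual blocks (channels 16 -> 32 -> 64,
## each stride 2, two 3x3 convs + batch norm with a 1x1 projection shortcut),
## a learned linear patch embedding over the final feature map with a class
## token and position embeddings, a stack of pre-norm transformer blocks
## (multi-head self-attention + GELU MLP, residual connections), a final
## layer norm, and a two-layer ReLU classifier reading only the class token.

#' Architecture hyper-parameters
#'
#' @param img_size Input side length; must be divisible by 8 (three stride-2
#'   stages). The clinical patch size is 128.
#' @param channels Output channels of the three residual blocks.
#' @param n_blocks Number of transformer blocks (12 in the full model).
#' @param d Embedding dimension.
#' @param heads Attention heads; `d` must be divisible by `heads`.
#' @param patch_grid Patch grid side over the final feature map (grid^2
#'   patches); the feature map side must be divisible by it.
#' @param mlp_ratio Hidden width of the transformer MLP as a multiple of `d`.
#' @param head_hidden Classifier hidden width (default `d / 2`).
#' @return List of class `"rtn_model_config"`.
#' @export
rtn_model_config <- function(img_size = 128L, channels = c(16L, 32L, 64L),
                             n_blocks = 12L, d = 64L, heads = 4L,
                             patch_grid = 4L, mlp_ratio = 4L,
                             head_hidden = NULL) {
  if (img_size %% 8 != 0) stop("img_size must be divisible by 8")
  map <- img_size %/% 8L
  if (map %% patch_grid != 0) stop("feature map side ", map,
                                   " not divisible by patch_grid ", patch_grid)
  if (d %% heads != 0) stop("d must be divisible by heads")
  if (length(channels) != 3) stop("exactly three residual blocks are used")
  if (is.null(head_hidden)) head_hidden <- max(2L, d %/% 2L)
  structure(list(img_size = as.integer(img_size), channels = as.integer(channels),
                 n_blocks = as.integer(n_blocks), d = as.integer(d),
                 heads = as.integer(heads), patch_grid = as.integer(patch_grid),
                 mlp_ratio = as.integer(mlp_ratio),
                 head_hidden = as.integer(head_hidden),
                 map = as.integer(map),
                 n_patches = as.integer(patch_grid^2),
                 patch_side = as.integer(map %/% patch_grid)),
            class = "rtn_model_config")
}

tf_param_names <- c("ln1_g", "ln1_b", "Wq", "bq", "Wk", "bk", "Wv", "bv",
                    "Wo", "bo", "ln2_g", "ln2_b", "W1", "b1", "W2", "b2")

tf_weights <- function(p, j) {
  w <- lapply(tf_param_names, function(nm) p[[paste0("t", j, "_", nm)]])
  names(w) <- tf_param_names
  w
}

## patch gather permutation: feature (C,H,W) tall layout -> per-patch blocks,
## patches ordered column-major over the grid, elements channel-fastest
build_pidx <- function(C, H, g, ps) {
  idx <- integer(0)
  for (pc in seq_len(g)) for (pr in seq_len(g)) {
    w_rng <- ((pc - 1L) * ps + 1L):(pc * ps)
    r_rng <- ((pr - 1L) * ps + 1L):(pr * ps)
    for (w in w_rng) for (r in r_rng)
      idx <- c(idx, ((w - 1L) * H + (r - 1L)) * C + seq_len(C))
  }
  idx
}

#' Build an untrained network
#'
#' Seeded initialization: Kaiming-normal for convolution weights and the
#' classifier's ReLU layer, truncated normal (sd 0.02) for transformer and
#' embedding weights and the class/position tokens; zero linear biases;
#' batch-norm gains 1. Convolutions carry no bias (batch norm follows every
#' conv and absorbs it).
#'
#' @param config An [rtn_model_config()].
#' @param seed Integer seed for the weight initialization.
#' @return List of class `"rtn_model"` with `params`, `state` (batch-norm
#'   running statistics), `config`, and precomputed convolution/patch plans.
#' @export
rtn_build <- function(config = rtn_model_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  ch <- cfg$channels
  cin <- c(1L, ch[1], ch[2])
  p <- list(); st <- list(); plans <- list()
  H <- cfg$img_size
  for (i in 1:3) {
    pre <- paste0("bb", i, "_")
    plans[[paste0("c1_", i)]] <- conv_plan(cin[i], H, H, 3L, 2L, 1L)
    plans[[paste0("c2_", i)]] <- conv_plan(ch[i], H %/% 2L, H %/% 2L, 3L, 1L, 1L)
    plans[[paste0("cp_", i)]] <- conv_plan(cin[i], H, H, 1L, 2L, 0L)
    ## conv weights are (fan_in x C_out); biases are absorbed by batch norm
    p[[paste0(pre, "conv1_W")]] <- t(kaiming(ch[i], cin[i] * 9L))
    p[[paste0(pre, "conv2_W")]] <- t(kaiming(ch[i], ch[i] * 9L))
    p[[paste0(pre, "proj_W")]] <- t(kaiming(ch[i], cin[i]))
    for (bn in c("bn1", "bn2", "bnp")) {
      p[[paste0(pre, bn, "_g")]] <- rep(1, ch[i])
      p[[paste0(pre, bn, "_b")]] <- numeric(ch[i])
      st[[paste0(pre, bn, "_rm")]] <- numeric(ch[i])
      st[[paste0(pre, bn, "_rv")]] <- rep(1, ch[i])
    }
    H <- H %/% 2L
  }
  d <- cfg$d; n <- cfg$n_patches
  pdim <- ch[3] * cfg$patch_side^2
  p$embed_W <- matrix(trunc_normal(d * pdim), d, pdim)
  p$embed_b <- numeric(d)
  p$cls <- trunc_normal(d)
  p$pos <- matrix(trunc_normal((n + 1L) * d), n + 1L, d)
  hd <- cfg$mlp_ratio * d
  for (j in seq_len(cfg$n_blocks)) {
    pre <- paste0("t", j, "_")
    p[[paste0(pre, "ln1_g")]] <- rep(1, d); p[[paste0(pre, "ln1_b")]] <- numeric(d)
    for (nm in c("Wq", "Wk", "Wv", "Wo"))
      p[[paste0(pre, nm)]] <- matrix(trunc_normal(d * d), d, d)
    for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(pre, nm)]] <- numeric(d)
    p[[paste0(pre, "ln2_g")]] <- rep(1, d); p[[paste0(pre, "ln2_b")]] <- numeric(d)
    p[[paste0(pre, "W1")]] <- matrix(trunc_normal(d * hd), d, hd)
    p[[paste0(pre, "b1")]] <- numeric(hd)
    p[[paste0(pre, "W2")]] <- matrix(trunc_normal(hd * d), hd, d)
    p[[paste0(pre, "b2")]] <- numeric(d)
  }
  p$lnf_g <- rep(1, d); p$lnf_b <- numeric(d)
  p$head_W1 <- t(kaiming(cfg$head_hidden, d))   # ReLU layer: Kaiming fan-in
  p$head_b1 <- numeric(cfg$head_hidden)
  p$head_W2 <- matrix(trunc_normal(cfg$head_hidden * 2L), cfg$head_hidden, 2L)
  p$head_b2 <- numeric(2L)
  structure(list(params = p, state = st, config = cfg, plans = plans,
                 pidx = build_pidx(ch[3], cfg$map, cfg$patch_grid, cfg$patch_side),
                 seed = seed),
            class = "rtn_model")
}

#' @export
print.rtn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Hybrid residual-CNN/transformer network (%dx%d input)\n",
              cfg$img_size, cfg$img_size))
  cat(sprintf("  backbone channels %s; %d transformer blocks, d=%d, %d heads, %d patches\n",
              paste(cfg$channels, collapse = "/"), cfg$n_blocks, cfg$d,
              cfg$heads, cfg$n_patches))
  cat(sprintf("  parameters: %s\n",
              format(sum(vapply(x$params, length, 1L)), big.mark = ",")))
  invisible(x)
}

## coerce input to a tall (H*W) x B matrix
as_image_batch <- function(x, size) {
  if (inherits(x, "rtn_cohort")) x <- x$images
  if (is.array(x) && length(dim(x)) == 3) {
    stopifnot(dim(x)[1] == size, dim(x)[2] == size)
    return(matrix(x, size * size, dim(x)[3]))
  }
  if (is.matrix(x)) {
    if (nrow(x) == size && ncol(x) == size) return(matrix(as.numeric(x), size * size, 1L))
    if (nrow(x) == size * size) return(x)
  }
  stop("expected a ", size, "x", size, " image, an array (", size, ",", size,
       ",B), or a (", size * size, " x B) matrix")
}

res_block_fwd <- function(x, p, st, i, plans, B, train, keep,
                          momentum = 0.1, eps = 1e-5) {
  pre <- paste0("bb", i, "_")
  pl1 <- plans[[paste0("c1_", i)]]; pl2 <- plans[[paste0("c2_", i)]]
  plp <- plans[[paste0("cp_", i)]]
  newstate <- list()
  run_bn <- function(a, bn, relu) {
    g <- p[[paste0(pre, bn, "_g")]]; be <- p[[paste0(pre, bn, "_b")]]
    if (train) {
      stt <- cpp_colstats(a); m <- stt[1, ]; v <- stt[2, ]
      newstate[[paste0(pre, bn, "_rm")]] <<-
        (1 - momentum) * st[[paste0(pre, bn, "_rm")]] + momentum * m
      newstate[[paste0(pre, bn, "_rv")]] <<-
        (1 - momentum) * st[[paste0(pre, bn, "_rv")]] + momentum * v
    } else {
      m <- st[[paste0(pre, bn, "_rm")]]; v <- st[[paste0(pre, bn, "_rv")]]
    }
    istd <- 1 / sqrt(v + eps)
    out <- cpp_bn_fwd(a, g, be, m, istd, relu)
    list(y = out$y, xhat = out$xhat, istd = istd)
  }
  a1 <- conv_fwd(x, p[[paste0(pre, "conv1_W")]], pl1)
  b1 <- run_bn(a1, "bn1", TRUE)
  r1 <- cpp_pbc2tall(b1$y, pl2$C, pl1$P, B)
  a2 <- conv_fwd(r1, p[[paste0(pre, "conv2_W")]], pl2)
  b2 <- run_bn(a2, "bn2", FALSE)
  ap <- conv_fwd(x, p[[paste0(pre, "proj_W")]], plp)
  bp_ <- run_bn(ap, "bnp", FALSE)
  s <- b2$y + bp_$y
  outT <- s * (s > 0)
  cache <- NULL
  if (keep) cache <- list(x = x, r1 = r1, xhat1 = b1$xhat, y1 = b1$y,
                          istd1 = b1$istd, xhat2 = b2$xhat,
                          istd2 = b2$istd, xhatp = bp_$xhat,
                          istdp = bp_$istd, outT = outT)
  list(tall = cpp_pbc2tall(outT, pl2$C, pl1$P, B), cache = cache,
       newstate = newstate)
}

## dpbc: gradient at the block output in pbc layout; returns dx in pbc layout
## over the block's input grid (dx = NULL for the first block, whose input
## is the image itself)
res_block_bwd <- function(dpbc, cache, p, i, plans, B) {
  want_dx <- i > 1L
  pre <- paste0("bb", i, "_")
  pl1 <- plans[[paste0("c1_", i)]]; pl2 <- plans[[paste0("c2_", i)]]
  plp <- plans[[paste0("cp_", i)]]
  ds <- dpbc * (cache$outT > 0)
  g2 <- cpp_bn_bwd(ds, cache$xhat2, NULL, p[[paste0(pre, "bn2_g")]], cache$istd2)
  cb2 <- conv_bwd(cache$r1, p[[paste0(pre, "conv2_W")]], g2$dx, pl2)
  g1 <- cpp_bn_bwd(cb2$dx, cache$xhat1, cache$y1, p[[paste0(pre, "bn1_g")]],
                   cache$istd1)
  cb1 <- conv_bwd(cache$x, p[[paste0(pre, "conv1_W")]], g1$dx, pl1, want_dx)
  gp <- cpp_bn_bwd(ds, cache$xhatp, NULL, p[[paste0(pre, "bnp_g")]], cache$istdp)
  cbp <- conv_bwd(cache$x, p[[paste0(pre, "proj_W")]], gp$dx, plp, want_dx)
  grads <- list(cb1$dW, g1$dg, g1$db, cb2$dW, g2$dg, g2$db,
                cbp$dW, gp$dg, gp$db)
  names(grads) <- paste0(pre, c("conv1_W", "bn1_g", "bn1_b",
                                "conv2_W", "bn2_g", "bn2_b",
                                "proj_W", "bnp_g", "bnp_b"))
  list(dx = if (want_dx) cb1$dx + cbp$dx else NULL, grads = grads)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, the attention function applied within each
#' head; the `1/sqrt(d_k)` scaling keeps the softmax inputs (and hence the
#' gradients) in a stable range. Rows of the attention matrix sum to one.
#'
#' @param Q,K,V Numeric matrices: queries (n_q x d_k), keys and values
#'   (n_k x d_k and n_k x d_v).
#' @return List with `out` (n_q x d_v) and the attention matrix `A`.
#' @export
attention <- function(Q, K, V) {
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V)) stop("non-conforming shapes")
  A <- softmax_rows(tcrossprod(Q, K) / sqrt(ncol(K)))
  list(out = A %*% V, A = A)
}

tf_block_fwd <- function(X, w, heads, B, nt, keep) {
  d <- ncol(X)
  dk <- d %/% heads
  ln1 <- ln_fwd(X, w$ln1_g, w$ln1_b)
  Q <- addb(ln1$y %*% w$Wq, w$bq)
  K <- addb(ln1$y %*% w$Wk, w$bk)
  V <- addb(ln1$y %*% w$Wv, w$bv)
  AO <- matrix(0, nrow(X), d)
  A <- vector("list", B)
  for (i in seq_len(B)) {
    ri <- ((i - 1L) * nt + 1L):(i * nt)
    Ai <- vector("list", heads)
    for (h in seq_len(heads)) {
      ci <- ((h - 1L) * dk + 1L):(h * dk)
      at <- attention(Q[ri, ci, drop = FALSE], K[ri, ci, drop = FALSE],
                      V[ri, ci, drop = FALSE])
      AO[ri, ci] <- at$out
      Ai[[h]] <- at$A
    }
    A[[i]] <- Ai
  }
  Z <- addb(AO %*% w$Wo, w$bo) + X
  ln2 <- ln_fwd(Z, w$ln2_g, w$ln2_b)
  H1 <- addb(ln2$y %*% w$W1, w$b1)
  Hg <- gelu(H1)
  Y <- addb(Hg %*% w$W2, w$b2) + Z
  cache <- NULL
  if (keep) cache <- list(X = X, ln1 = ln1[c("xhat", "istd", "g")],
                          Xn = ln1$y, Q = Q, K = K, V = V, A = A, AO = AO,
                          Z = Z, ln2 = ln2[c("xhat", "istd", "g")],
                          Zn = ln2$y, H1 = H1, Hg = Hg)
  list(Y = Y, A = A, cache = cache)
}

tf_block_bwd <- function(dY, tc, w, heads, B, nt) {
  d <- ncol(dY)
  dk <- d %/% heads
  ## MLP branch
  dHg <- dY %*% t(w$W2)
  dH1 <- dHg * gelu_grad(tc$H1)
  dZn <- dH1 %*% t(w$W1)
  lb2 <- ln_bwd(dZn, tc$ln2)
  dZ <- dY + lb2$dx
  ## attention branch
  dAO <- dZ %*% t(w$Wo)
  dQ <- matrix(0, nrow(dY), d); dK <- dQ; dV <- dQ
  for (i in seq_len(B)) {
    ri <- ((i - 1L) * nt + 1L):(i * nt)
    for (h in seq_len(heads)) {
      ci <- ((h - 1L) * dk + 1L):(h * dk)
      A <- tc$A[[i]][[h]]
      dAOi <- dAO[ri, ci, drop = FALSE]
      Vi <- tc$V[ri, ci, drop = FALSE]
      dA <- tcrossprod(dAOi, Vi)
      dV[ri, ci] <- crossprod(A, dAOi)
      dS <- A * (dA - rowSums(dA * A))
      dS <- dS / sqrt(dk)
      dQ[ri, ci] <- dS %*% tc$K[ri, ci, drop = FALSE]
      dK[ri, ci] <- crossprod(dS, tc$Q[ri, ci, drop = FALSE])
    }
  }
  dXn <- dQ %*% t(w$Wq) + dK %*% t(w$Wk) + dV %*% t(w$Wv)
  lb1 <- ln_bwd(dXn, tc$ln1)
  dX <- dZ + lb1$dx
  grads <- list(ln1_g = lb1$dg, ln1_b = lb1$db,
                Wq = crossprod(tc$Xn, dQ), bq = colSums(dQ),
                Wk = crossprod(tc$Xn, dK), bk = colSums(dK),
                Wv = crossprod(tc$Xn, dV), bv = colSums(dV),
                Wo = crossprod(tc$AO, dZ), bo = colSums(dZ),
                ln2_g = lb2$dg, ln2_b = lb2$db,
                W1 = crossprod(tc$Zn, dH1), b1 = colSums(dH1),
                W2 = crossprod(tc$Hg, dY), b2 = colSums(dY))
  list(dX = dX, grads = grads)
}

#' Apply one transformer block to a token sequence
#'
#' Pre-norm residual block: `Z = MSA(LN(X)) + X`, then
#' `Y = MLP(LN(Z)) + Z`, where the MLP is two linear layers with a GELU
#' activation between them. Class token and position embeddings are expected
#' to be merged into `X` already (done once at patch-embedding time).
#'
#' @param X Token sequence (n_tokens x d).
#' @param weights Named list with `ln1_g, ln1_b, Wq, bq, Wk, bk, Wv, bv, Wo,
#'   bo, ln2_g, ln2_b, W1, b1, W2, b2` (see [rtn_build()]; obtainable for
#'   block `j` of a model via `restransnet:::tf_weights(model$params, j)`).
#' @param heads Number of attention heads.
#' @return List with `Y` (output sequence, same shape as `X`) and `A`
#'   (per-head attention matrices).
#' @export
transformer_block <- function(X, weights, heads = 1L) {
  out <- tf_block_fwd(X, weights, heads, B = 1L, nt = nrow(X), keep = FALSE)
  list(Y = out$Y, A = out$A[[1]])
}

head_fwd <- function(Y, cr, p, keep) {
  h0 <- Y[cr, , drop = FALSE]
  ln <- ln_fwd(h0, p$lnf_g, p$lnf_b)
  A1 <- addb(ln$y %*% p$head_W1, p$head_b1)
  R1 <- A1 * (A1 > 0)
  logits <- addb(R1 %*% p$head_W2, p$head_b2)
  cache <- NULL
  if (keep) cache <- list(ln = ln[c("xhat", "istd", "g")], hn = ln$y,
                          A1 = A1, R1 = R1)
  list(logits = logits, cache = cache)
}

head_bwd <- function(dlog, hc, p) {
  dW2 <- crossprod(hc$R1, dlog)
  dR1 <- dlog %*% t(p$head_W2)
  dA1 <- dR1 * (hc$A1 > 0)
  dW1 <- crossprod(hc$hn, dA1)
  dhn <- dA1 %*% t(p$head_W1)
  lb <- ln_bwd(dhn, hc$ln)
  list(dh0 = lb$dx,
       grads = list(lnf_g = lb$dg, lnf_b = lb$db,
                    head_W1 = dW1, head_b1 = colSums(dA1),
                    head_W2 = dW2, head_b2 = colSums(dlog)))
}

#' Forward pass
#'
#' @param model An `rtn_model`.
#' @param x Images: a single matrix, an array `(H, W, B)`, an `rtn_cohort`,
#'   or a tall `(H*W x B)` matrix.
#' @param train Use batch statistics and update running batch-norm state
#'   (`TRUE` during optimization); `FALSE` gives deterministic evaluation.
#' @param keep Keep intermediate activations for backpropagation.
#' @param capture Also return backbone feature maps and per-block attention
#'   matrices (used by the visualization tools).
#' @return List with `logits` (B x 2), `state` (updated running statistics),
#'   and optionally `cache` / `maps`.
#' @export
rtn_forward <- function(model, x, train = FALSE, keep = FALSE, capture = FALSE) {
  cfg <- model$config; p <- model$params; st <- model$state
  x <- as_image_batch(x, cfg$img_size)
  B <- ncol(x)
  cur <- x
  bb_caches <- vector("list", 3)
  maps <- if (capture) list(backbone = vector("list", 3), attn = list()) else NULL
  for (i in 1:3) {
    rb <- res_block_fwd(cur, p, st, i, model$plans, B, train, keep)
    if (train) st[names(rb$newstate)] <- rb$newstate
    if (keep) bb_caches[[i]] <- rb$cache
    if (capture) maps$backbone[[i]] <- rb$tall
    cur <- rb$tall
  }
  n <- cfg$n_patches; d <- cfg$d; nt <- n + 1L
  pdim <- cfg$channels[3] * cfg$patch_side^2
  pm <- cur[model$pidx, , drop = FALSE]
  dim(pm) <- c(pdim, n * B)
  E <- p$embed_W %*% pm + p$embed_b
  Tm <- matrix(0, B * nt, d)
  cr <- seq(1L, B * nt, by = nt)
  Tm[cr, ] <- matrix(p$cls, B, d, byrow = TRUE)
  Tm[-cr, ] <- t(E)
  Tm <- Tm + p$pos[rep(seq_len(nt), B), ]
  tf_caches <- vector("list", cfg$n_blocks)
  for (j in seq_len(cfg$n_blocks)) {
    w <- tf_weights(p, j)
    tb <- tf_block_fwd(Tm, w, cfg$heads, B, nt, keep)
    if (keep) tf_caches[[j]] <- tb$cache
    if (capture) maps$attn[[j]] <- tb$A
    Tm <- tb$Y
  }
  hf <- head_fwd(Tm, cr, p, keep)
  cache <- NULL
  if (keep) cache <- list(B = B, cr = cr, bb = bb_caches, pm = pm,
                          tf = tf_caches, head = hf$cache)
  if (capture) maps$tokens <- Tm
  list(logits = hf$logits, state = st, cache = cache, maps = maps)
}

#' Extract the convolutional feature map for one image
#'
#' Runs only the residual backbone (evaluation mode) and returns the final
#' 64-channel feature map.
#'
#' @param model An `rtn_model`.
#' @param x A single image matrix.
#' @return Array `(C, h, w)` with `C = channels[3]`, `h = w = img_size / 8`.
#' @export
conv_backbone <- function(model, x) {
  cfg <- model$config
  xm <- as_image_batch(x, cfg$img_size)
  if (ncol(xm) != 1) stop("one image at a time")
  cur <- xm
  for (i in 1:3) {
    rb <- res_block_fwd(cur, model$params, model$state, i, model$plans,
                        1L, train = FALSE, keep = FALSE)
    cur <- rb$tall
  }
  array(cur, dim = c(cfg$channels[3], cfg$map, cfg$map))
}

#' Backpropagate through the whole network
#'
#' @param model An `rtn_model`.
#' @param cache Cache from `rtn_forward(..., keep = TRUE)` (train mode).
#' @param dlogits Gradient of the loss w.r.t. the logits (B x 2), including
#'   any per-sample weights and the reduction normalizer.
#' @return Named list of gradients matching `model$params`.
#' @export
rtn_backward <- function(model, cache, dlogits) {
  cfg <- model$config; p <- model$params
  B <- cache$B; nt <- cfg$n_patches + 1L
  grads <- vector("list", 0)
  hb <- head_bwd(dlogits, cache$head, p)
  grads[names(hb$grads)] <- hb$grads
  dY <- matrix(0, B * nt, cfg$d)
  dY[cache$cr, ] <- hb$dh0
  for (j in rev(seq_len(cfg$n_blocks))) {
    w <- tf_weights(p, j)
    tb <- tf_block_bwd(dY, cache$tf[[j]], w, cfg$heads, B, nt)
    names(tb$grads) <- paste0("t", j, "_", names(tb$grads))
    grads[names(tb$grads)] <- tb$grads
    dY <- tb$dX
  }
  ## patch embedding
  n <- cfg$n_patches; d <- cfg$d
  cr <- cache$cr
  grads$pos <- rowsum(dY, rep(seq_len(nt), B))
  dimnames(grads$pos) <- NULL
  grads$cls <- colSums(dY[cr, , drop = FALSE])
  dE <- t(dY[-cr, , drop = FALSE])
  grads$embed_W <- tcrossprod(dE, cache$pm)
  grads$embed_b <- rowSums(dE)
  dpm <- crossprod(p$embed_W, dE)
  nfeat <- cfg$channels[3] * cfg$map^2
  dim(dpm) <- c(nfeat, B)
  dtall <- matrix(0, nfeat, B)
  dtall[model$pidx, ] <- dpm
  ## backbone (gradients flow in pbc layout between blocks)
  dT <- cpp_tall2pbc(dtall, cfg$channels[3], cfg$map^2, B)
  for (i in 3:1) {
    rbb <- res_block_bwd(dT, cache$bb[[i]], p, i, model$plans, B)
    grads[names(rbb$grads)] <- rbb$grads
    dT <- rbb$dx
  }
  grads[names(model$params)]
}

## flatten a (subset of a) gradient list into one numeric vector
flatten_grads <- function(g) unlist(g, use.names = FALSE)

slice_ln <- function(lnc, ri) list(xhat = lnc$xhat[ri, , drop = FALSE],
                                   istd = lnc$istd[ri], g = lnc$g)

slice_tf_cache <- function(tc, i, nt) {
  ri <- ((i - 1L) * nt + 1L):(i * nt)
  list(X = tc$X[ri, , drop = FALSE], ln1 = slice_ln(tc$ln1, ri),
       Xn = tc$Xn[ri, , drop = FALSE], Q = tc$Q[ri, , drop = FALSE],
       K = tc$K[ri, , drop = FALSE], V = tc$V[ri, , drop = FALSE],
       A = tc$A[i], AO = tc$AO[ri, , drop = FALSE],
       Z = tc$Z[ri, , drop = FALSE], ln2 = slice_ln(tc$ln2, ri),
       Zn = tc$Zn[ri, , drop = FALSE], H1 = tc$H1[ri, , drop = FALSE],
       Hg = tc$Hg[ri, , drop = FALSE])
}

slice_head_cache <- function(hc, i) {
  list(ln = slice_ln(hc$ln, i), hn = hc$hn[i, , drop = FALSE],
       A1 = hc$A1[i, , drop = FALSE], R1 = hc$R1[i, , drop = FALSE])
}

#' Per-sample flattened parameter gradients
#'
#' Computes one flattened gradient vector per sample in the batch, over the
#' configured parameter scope. The default `"head_last"` scope (classifier
#' head, final layer norm, and last transformer block) captures the pairwise
#' similarity structure of oversampled duplicates at a fraction of the cost
#' of full-network per-sample gradients; `"full"` differentiates the whole
#' network per sample (used in oracle tests).
#'
#' @param model An `rtn_model`.
#' @param cache Forward cache (`keep = TRUE`).
#' @param dlogits Per-sample loss gradients w.r.t. the logits (B x 2),
#'   unreduced.
#' @param scope `"head_last"`, `"head"`, or `"full"`.
#' @return Matrix (B x n_params_in_scope); row i is sample i's gradient.
#' @export
per_sample_gradients <- function(model, cache, dlogits,
                                 scope = c("head_last", "head", "full")) {
  scope <- match.arg(scope)
  cfg <- model$config; p <- model$params
  B <- cache$B; nt <- cfg$n_patches + 1L
  if (scope == "full") {
    G <- lapply(seq_len(B), function(i) {
      dl <- matrix(0, B, 2)
      dl[i, ] <- dlogits[i, ]
      flatten_grads(rtn_backward(model, cache, dl))
    })
    return(do.call(rbind, G))
  }
  L <- cfg$n_blocks
  wL <- if (scope == "head_last") tf_weights(p, L) else NULL
  G <- lapply(seq_len(B), function(i) {
    hb <- head_bwd(dlogits[i, , drop = FALSE], slice_head_cache(cache$head, i), p)
    gi <- flatten_grads(hb$grads)
    if (scope == "head_last") {
      dY <- matrix(0, nt, cfg$d)
      dY[1L, ] <- hb$dh0
      tb <- tf_block_bwd(dY, slice_tf_cache(cache$tf[[L]], i, nt),
                         wL, cfg$heads, 1L, nt)
      gi <- c(gi, flatten_grads(tb$grads))
    }
    gi
  })
  do.call(rbind, G)
}
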
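## Neural-network primitives in base R linear algebra.
##
## Conventions:
##  - A batch of feature maps is a "tall" matrix (C*H*W) x B, with channel
##    fastest, then row, then column (per-image column vectors); this is the
##    inter-layer format on the forward path.
##  - Convolution outputs, batch norm, and inter-layer gradients live in
##    "pbc" layout (P*B rows = positions image-major, columns = channels),
##    which keeps the matrix products in BLAS-friendly tall-skinny
##    orientations.
##  - Convolutions go through compiled tiled-convolution kernels
##    (src/conv.cpp); batch norm (+ReLU fusion) is compiled too
##    (per-channel = per-column).

conv_plan <- function(C, H, W, k, stride, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  list(C = C, H = H, W = W, k = k, stride = stride, pad = pad,
       Ho = Ho, Wo = Wo, P = Ho * Wo, ck2 = C * k * k)
}

## conv weights are (C*k*k) x C_out; forward takes tall input, returns pbc
conv_fwd <- function(x, Wt, plan) {
  cpp_conv_fwd(x, Wt, plan$C, plan$H, plan$W, plan$k, plan$stride, plan$pad)
}

## x: cached tall input; dout in pbc layout; returns dW and the input
## gradient in pbc layout over the input grid (dx skipped with
## want_dx = FALSE for the first layer, whose input is data)
conv_bwd <- function(x, Wt, dout, plan, want_dx = TRUE) {
  cpp_conv_bwd(x, Wt, dout, plan$C, plan$H, plan$W, plan$k, plan$stride,
               plan$pad, want_dx)
}

## Layer norm over embedding dimension (columns; rows are tokens).
ln_fwd <- function(X, g, b, eps = 1e-5) {
  m <- rowMeans(X)
  v <- pmax(rowMeans(X * X) - m * m, 0)
  istd <- 1 / sqrt(v + eps)
  xhat <- (X - m) * istd
  n <- nrow(X)
  list(y = xhat * rep(g, each = n) + rep(b, each = n),
       xhat = xhat, istd = istd, g = g)
}

ln_bwd <- function(dy, cache) {
  xhat <- cache$xhat; istd <- cache$istd
  n <- nrow(dy)
  dxhat <- dy * rep(cache$g, each = n)
  dx <- istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softmax_rows <- function(x) {
  x <- exp(x - apply(x, 1, max))
  x / rowSums(x)
}

## add a bias row-vector to every row
addb <- function(M, b) M + rep(b, each = nrow(M))

trunc_normal <- function(n, sd = 0.02) {
  r <- stats::rnorm(n, 0, sd)
  pmin(pmax(r, -2 * sd), 2 * sd)
}

kaiming <- function(nout, fan_in) {
  matrix(stats::rnorm(nout * fan_in, 0, sqrt(2 / fan_in)), nout, fan_in)
}
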
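# Internal layer primitives with hand-written reverse-mode gradients.
#
# Weights of a k x k convolution mapping Cin -> Cout channels are stored as
# a (Cin k^2) x Cout matrix whose row order matches cpp_im2col (input
# channel fastest, then kernel row, then kernel column), so forward and
# backward are single BLAS products around the im2col/col2im kernels.
# Gradients are verified against central finite differences in the test
# suite.

initConvW <- function(cin, cout, k, gain = "he", sd0 = 0.02) {
  n <- cin * k * k
  w <- if (identical(gain, "he")) rnorm(n * cout, 0, sqrt(2 / n))
       else rnorm(n * cout, 0, sd0)
  matrix(w, n, cout)
}

# Weight modulation + demodulation as a pure weight transform.
# V = W scaled per input channel; each output filter then rescaled to unit
# L2 norm (plus eps). Returns the transformed weights and the cache needed
# for its backward pass.
modDemodForward <- function(Wm, scales, k, cin, eps = 1e-8) {
  sfull <- rep(scales, times = k * k)
  V <- Wm * sfull
  denom <- sqrt(colSums(V * V) + eps)
  list(W = sweep(V, 2L, denom, "/"), V = V, denom = denom, sfull = sfull)
}

modDemodBackward <- function(g, cache, Wm, k, cin) {
  V <- cache$V; denom <- cache$denom
  gv <- colSums(g * V)
  dV <- sweep(g, 2L, denom, "/") - sweep(V, 2L, gv / denom^3, "*")
  dW <- dV * cache$sfull
  tmp <- rowSums(dV * Wm)                     # sum over output filters
  ds <- rowSums(matrix(tmp, nrow = cin))      # sum over kernel offsets
  list(dW = dW, dscales = ds)
}

# act: "none", "relu" or "lrelu"; the activation is fused into the C++
# kernel, and its mask is recovered from the sign of the cached output.
ACT_CODE <- c(none = 0L, relu = 1L, lrelu = 2L)

# The training loop flips this to use single-precision convolution
# arithmetic (the precision GPU-trained translation networks use); every
# exposed operator and the gradient-check path stay double.
.icState <- new.env(parent = emptyenv())
.icState$convFloat <- FALSE

withFloatConv <- function(expr) {
  old <- .icState$convFloat
  .icState$convFloat <- TRUE
  on.exit(.icState$convFloat <- old)
  force(expr)
}

convForward <- function(x, Wm, b, k, stride = 1L, pad = 0L, scales = NULL,
                        act = "none") {
  d <- dim(x)
  md <- if (!is.null(scales)) modDemodForward(Wm, scales, k, d[1]) else NULL
  Wuse <- if (is.null(md)) Wm else md$W
  y <- if (.icState$convFloat)
    cpp_conv_fwd_f(x, d[1], d[2], d[3], Wuse, b, k, stride, pad,
                   ACT_CODE[[act]])
  else cpp_conv_fwd(x, d[1], d[2], d[3], Wuse, b, k, stride, pad,
                    ACT_CODE[[act]])
  list(y = y,
       cache = list(x = x, y = y, dims = d, k = k,
                    stride = stride, pad = pad, md = md, act = act))
}

convBackward <- function(dy, cache, Wm, scales = NULL) {
  d <- cache$dims
  Wuse <- if (is.null(cache$md)) Wm else cache$md$W
  g <- if (.icState$convFloat)
    cpp_conv_bwd_f(cache$x, d[1], d[2], d[3], Wuse, cache$y, dy,
                   cache$k, cache$stride, cache$pad, ACT_CODE[[cache$act]])
  else cpp_conv_bwd(cache$x, d[1], d[2], d[3], Wuse, cache$y, dy,
                    cache$k, cache$stride, cache$pad, ACT_CODE[[cache$act]])
  if (is.null(cache$md))
    list(dx = g$dx, dW = g$dW, db = g$db, dscales = NULL)
  else {
    mb <- modDemodBackward(g$dW, cache$md, Wm, cache$k, d[1])
    list(dx = g$dx, dW = mb$dW, db = g$db, dscales = mb$dscales)
  }
}

reluForward <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}
reluBackward <- function(dy, mask) dy * mask

lreluForward <- function(x, slope = 0.2) {
  neg <- x < 0
  y <- x
  y[neg] <- x[neg] * slope
  list(y = y, neg = neg, slope = slope)
}
lreluBackward <- function(dy, cache) {
  dy[cache$neg] <- dy[cache$neg] * cache$slope
  dy
}

sigmoidForward <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y)
}
sigmoidBackward <- function(dy, y) dy * y * (1 - y)

poolForward <- function(x) {
  d <- dim(x)
  r <- cpp_maxpool2(x, d[1], d[2], d[3])
  list(y = r$y, idx = r$idx, dims = d)
}
poolBackward <- function(dy, cache) {
  dx <- numeric(prod(cache$dims))
  dx[cache$idx] <- dy
  array(dx, cache$dims)
}

# Per-channel (spatial) batch normalisation; with batch size 1 the batch
# statistics are spatial statistics. Running moments serve inference.
bnForward <- function(x, gamma, beta, rmean, rvar, train = TRUE,
                      momentum = 0.1, eps = 1e-5) {
  d <- dim(x); C <- d[1]; N <- d[2] * d[3]
  m <- matrix(x, nrow = C)
  if (train) {
    mu <- rowMeans(m)
    xc <- m - mu
    v <- rowMeans(xc * xc)
    newR <- list(rmean = (1 - momentum) * rmean + momentum * mu,
                 rvar = (1 - momentum) * rvar + momentum * v)
  } else {
    mu <- rmean; v <- rvar
    xc <- m - mu
    newR <- NULL
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  y <- xhat * gamma + beta
  list(y = array(y, d),
       cache = list(xhat = xhat, istd = istd, dims = d, train = train),
       running = newR)
}

bnBackward <- function(dy, cache, gamma) {
  d <- cache$dims; C <- d[1]; N <- d[2] * d[3]
  g <- matrix(dy, nrow = C)
  dgamma <- rowSums(g * cache$xhat)
  dbeta <- rowSums(g)
  dxhat <- g * gamma
  if (cache$train) {
    dx <- (dxhat - rowMeans(dxhat) -
           cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$istd
  } else {
    dx <- dxhat * cache$istd
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# Dynamic upsampling layer (factor fixed at 2 inside the U-nets, but kept
# generic). theta$W is Cin x 2s^2, zero-initialised so training starts as
# plain bilinear upsampling. In "bilinear" mode the offset path is absent.
dynUpForward <- function(x, theta, s, offsetScale = 1, mode = "dynamic") {
  d <- dim(x)
  G <- makeUniformGrid(d[2], d[3], s)
  if (mode == "dynamic") {
    m <- matrix(x, nrow = d[1])
    olr <- crossprod(theta$W, m) + theta$b
    off <- pixelShuffle(array(olr, c(2L * s * s, d[2], d[3])), s) * offsetScale
    S <- G + off
  } else S <- G
  sx <- as.vector(S[1, , ]); sy <- as.vector(S[2, , ])
  y <- cpp_grid_sample(x, d[1], d[2], d[3], sx, sy)
  list(y = array(y, c(d[1], d[2] * s, d[3] * s)),
       cache = list(x = x, dims = d, sx = sx, sy = sy, s = s,
                    offsetScale = offsetScale, mode = mode))
}

dynUpBackward <- function(dy, cache, theta) {
  d <- cache$dims; s <- cache$s
  dyM <- matrix(dy, nrow = d[1])
  g <- cpp_grid_sample_backward(cache$x, d[1], d[2], d[3],
                                cache$sx, cache$sy, dyM)
  dx <- g$dx
  if (cache$mode == "dynamic") {
    dS <- array(0, c(2L, d[2] * s, d[3] * s))
    dS[1, , ] <- g$dsx; dS[2, , ] <- g$dsy
    doff <- pixelUnshuffle(dS, s) * cache$offsetScale    # 2s^2 x H x W
    dolr <- matrix(doff, nrow = 2L * s * s)
    m <- matrix(cache$x, nrow = d[1])
    dWt <- tcrossprod(m, dolr)                           # Cin x 2s^2
    dbt <- rowSums(dolr)
    dx <- dx + array(theta$W %*% dolr, d)
    list(dx = dx, dW = dWt, db = dbt)
  } else list(dx = dx, dW = NULL, db = NULL)
}
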
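# PatchGAN-style least-squares discriminator: stacked stride-2 4x4
# convolutions with LeakyReLU(0.2) (batch norm after every conv except the
# first when enabled), then a 3x3 convolution to a single-channel,
# unbounded score map.

discInit <- function(cin, widths, bn = FALSE) {
  p <- list()
  ci <- cin
  for (i in seq_along(widths)) {
    # He initialisation: the discriminator must produce informative scores
    # (and gradients) from the first iterations, which is what keeps the
    # generators from collapsing to constant translations early on
    p[[paste0("l", i, ".W")]] <- initConvW(ci, widths[i], 4L)
    p[[paste0("l", i, ".b")]] <- numeric(widths[i])
    if (bn && i > 1L) {
      p[[paste0("l", i, ".g")]] <- rep(1, widths[i])
      p[[paste0("l", i, ".be")]] <- numeric(widths[i])
      p[[paste0("l", i, ".rm")]] <- numeric(widths[i])
      p[[paste0("l", i, ".rv")]] <- rep(1, widths[i])
    }
    ci <- widths[i]
  }
  p[["out.W"]] <- initConvW(ci, 1L, 3L)
  p[["out.b"]] <- numeric(1L)
  list(params = p, meta = list(cin = cin, widths = widths, bn = bn))
}

discForward <- function(net, x, train = FALSE, keepCache = FALSE) {
  p <- net$params; meta <- net$meta
  st <- new.env(parent = emptyenv())
  st$bnUpdates <- list()
  cur <- x
  for (i in seq_along(meta$widths)) {
    hasBn <- meta$bn && i > 1L
    cf <- convForward(cur, p[[paste0("l", i, ".W")]], p[[paste0("l", i, ".b")]],
                      4L, 2L, 1L, act = if (hasBn) "none" else "lrelu")
    st[[paste0("l", i, ".conv")]] <- cf$cache
    cur <- cf$y
    if (hasBn) {
      bf <- bnForward(cur, p[[paste0("l", i, ".g")]], p[[paste0("l", i, ".be")]],
                      p[[paste0("l", i, ".rm")]], p[[paste0("l", i, ".rv")]],
                      train = train)
      st[[paste0("l", i, ".bn")]] <- bf$cache
      if (!is.null(bf$running)) {
        st$bnUpdates[[paste0("l", i, ".rm")]] <- bf$running$rmean
        st$bnUpdates[[paste0("l", i, ".rv")]] <- bf$running$rvar
      }
      lf <- lreluForward(bf$y)
      st[[paste0("l", i, ".act")]] <- lf[c("neg", "slope")]
      cur <- lf$y
    }
  }
  cf <- convForward(cur, p[["out.W"]], p[["out.b"]], 3L, 1L, 1L)
  st[["out.conv"]] <- cf$cache
  if (keepCache) list(y = cf$y, st = st) else list(y = cf$y, st = NULL)
}

discBackward <- function(net, st, dy) {
  p <- net$params; meta <- net$meta
  grads <- new.env(parent = emptyenv())
  cb <- convBackward(dy, st[["out.conv"]], p[["out.W"]])
  accGrad(grads, "out.W", cb$dW); accGrad(grads, "out.b", cb$db)
  dy <- cb$dx
  for (i in rev(seq_along(meta$widths))) {
    if (meta$bn && i > 1L) {
      dy <- lreluBackward(dy, st[[paste0("l", i, ".act")]])
      bb <- bnBackward(dy, st[[paste0("l", i, ".bn")]],
                       p[[paste0("l", i, ".g")]])
      accGrad(grads, paste0("l", i, ".g"), bb$dgamma)
      accGrad(grads, paste0("l", i, ".be"), bb$dbeta)
      dy <- bb$dx
    }
    cb <- convBackward(dy, st[[paste0("l", i, ".conv")]],
                       p[[paste0("l", i, ".W")]])
    accGrad(grads, paste0("l", i, ".W"), cb$dW)
    accGrad(grads, paste0("l", i, ".b"), cb$db)
    dy <- cb$dx
  }
  list(dx = dy, grads = as.list(grads))
}
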
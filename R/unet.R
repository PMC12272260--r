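# U-shaped encoder/decoder template.
#
# Contracting path: per level two 3x3 convolutions (optional batch norm)
# each followed by ReLU, then 2x2 max pooling. Expansive path: dynamic
# upsampling (factor 2), concatenation with the matching skip feature, two
# more 3x3 conv+ReLU units. A final 1x1 convolution maps to the output
# channel count (linear for encoders and unbounded-intensity decoders,
# optional sigmoid for [0,1] tasks). The output spatial size always equals
# the input spatial size - the full-resolution feature contract.
#
# Parameters live in a flat named list ("down1.c1.W", "up2.off.b", ...);
# forward passes stash per-layer caches in an environment which the
# backward pass consumes in reverse, accumulating gradients by name.

unetInit <- function(cin, cout, widths, bn = FALSE, mod = FALSE,
                     upsampler = "dynamic", finalAct = "linear",
                     offsetScale = 1) {
  L <- length(widths)
  p <- list()
  addConv <- function(prefix, ci, co, k) {
    p[[paste0(prefix, ".W")]] <<- initConvW(ci, co, k)
    p[[paste0(prefix, ".b")]] <<- numeric(co)
    if (bn) {
      p[[paste0(prefix, ".g")]] <<- rep(1, co)
      p[[paste0(prefix, ".be")]] <<- numeric(co)
      p[[paste0(prefix, ".rm")]] <<- numeric(co)
      p[[paste0(prefix, ".rv")]] <<- rep(1, co)
    }
    if (mod && k == 3L) p[[paste0(prefix, ".s")]] <<- rep(1, ci)
  }
  ci <- cin
  for (i in seq_len(L - 1L)) {
    addConv(paste0("down", i, ".c1"), ci, widths[i], 3L)
    addConv(paste0("down", i, ".c2"), widths[i], widths[i], 3L)
    ci <- widths[i]
  }
  addConv("bott.c1", widths[L - 1L], widths[L], 3L)
  addConv("bott.c2", widths[L], widths[L], 3L)
  for (i in rev(seq_len(L - 1L))) {
    cup <- if (i == L - 1L) widths[L] else widths[i + 1L]
    if (upsampler == "dynamic") {
      p[[paste0("up", i, ".off.W")]] <- matrix(0, cup, 8L)  # 2 s^2, s = 2
      p[[paste0("up", i, ".off.b")]] <- numeric(8L)
    }
    addConv(paste0("up", i, ".c1"), cup + widths[i], widths[i], 3L)
    addConv(paste0("up", i, ".c2"), widths[i], widths[i], 3L)
  }
  addConv("final", widths[1L], cout, 1L)
  list(params = p,
       meta = list(cin = cin, cout = cout, widths = widths, bn = bn,
                   mod = mod, upsampler = upsampler, finalAct = finalAct,
                   offsetScale = offsetScale))
}

# One conv (+ BN) (+ activation) unit. Without batch norm the activation
# is fused into the conv kernel; with it, the order is conv -> BN -> ReLU.
unitForward <- function(prefix, x, p, meta, train, st, k = 3L,
                        act = "relu") {
  scales <- if (meta$mod && k == 3L) p[[paste0(prefix, ".s")]] else NULL
  if (!meta$bn) {
    cf <- convForward(x, p[[paste0(prefix, ".W")]], p[[paste0(prefix, ".b")]],
                      k, 1L, (k - 1L) %/% 2L, scales, act = act)
    st[[paste0(prefix, ".conv")]] <- cf$cache
    return(cf$y)
  }
  cf <- convForward(x, p[[paste0(prefix, ".W")]], p[[paste0(prefix, ".b")]],
                    k, 1L, (k - 1L) %/% 2L, scales)
  st[[paste0(prefix, ".conv")]] <- cf$cache
  bf <- bnForward(cf$y, p[[paste0(prefix, ".g")]], p[[paste0(prefix, ".be")]],
                  p[[paste0(prefix, ".rm")]], p[[paste0(prefix, ".rv")]],
                  train = train)
  st[[paste0(prefix, ".bn")]] <- bf$cache
  if (!is.null(bf$running)) {
    st$bnUpdates[[paste0(prefix, ".rm")]] <- bf$running$rmean
    st$bnUpdates[[paste0(prefix, ".rv")]] <- bf$running$rvar
  }
  y <- bf$y
  if (act == "relu") {
    rf <- reluForward(y)
    st[[paste0(prefix, ".relu")]] <- rf$mask
    y <- rf$y
  }
  y
}

unitBackward <- function(prefix, dy, p, meta, st, grads, k = 3L,
                         act = "relu") {
  if (meta$bn) {
    if (act == "relu") dy <- reluBackward(dy, st[[paste0(prefix, ".relu")]])
    bb <- bnBackward(dy, st[[paste0(prefix, ".bn")]],
                     p[[paste0(prefix, ".g")]])
    accGrad(grads, paste0(prefix, ".g"), bb$dgamma)
    accGrad(grads, paste0(prefix, ".be"), bb$dbeta)
    dy <- bb$dx
  }
  scales <- if (meta$mod && k == 3L) p[[paste0(prefix, ".s")]] else NULL
  cb <- convBackward(dy, st[[paste0(prefix, ".conv")]],
                     p[[paste0(prefix, ".W")]], scales)
  accGrad(grads, paste0(prefix, ".W"), cb$dW)
  accGrad(grads, paste0(prefix, ".b"), cb$db)
  if (!is.null(cb$dscales)) accGrad(grads, paste0(prefix, ".s"), cb$dscales)
  cb$dx
}

accGrad <- function(grads, name, g) {
  if (is.null(grads[[name]])) grads[[name]] <- g
  else grads[[name]] <- grads[[name]] + g
}

unetCheckSize <- function(meta, d) {
  L <- length(meta$widths)
  div <- 2L^(L - 1L)
  if (d[2] %% div != 0L || d[3] %% div != 0L)
    stop("input spatial size ", d[2], "x", d[3], " is not divisible by ",
         div, "; pad the image (e.g. reflectively with padToMultiple()) ",
         "to a multiple of ", div, " and crop the output back",
         call. = FALSE)
  if (d[1] != meta$cin)
    stop("input has ", d[1], " channels; this network expects ", meta$cin,
         call. = FALSE)
}

# Forward pass. Returns the output plus (optionally) the cache environment
# for the backward pass; st$bnUpdates carries new batch-norm running
# moments for the training loop to fold back into the parameters.
unetForward <- function(net, x, train = FALSE, keepCache = FALSE) {
  p <- net$params; meta <- net$meta
  d <- dim(x)
  unetCheckSize(meta, d)
  L <- length(meta$widths)
  st <- new.env(parent = emptyenv())
  st$bnUpdates <- list()
  skips <- vector("list", L - 1L)
  cur <- x
  for (i in seq_len(L - 1L)) {
    cur <- unitForward(paste0("down", i, ".c1"), cur, p, meta, train, st)
    cur <- unitForward(paste0("down", i, ".c2"), cur, p, meta, train, st)
    skips[[i]] <- cur
    pf <- poolForward(cur)
    st[[paste0("pool", i)]] <- pf[c("idx", "dims")]
    cur <- pf$y
  }
  cur <- unitForward("bott.c1", cur, p, meta, train, st)
  cur <- unitForward("bott.c2", cur, p, meta, train, st)
  for (i in rev(seq_len(L - 1L))) {
    theta <- if (meta$upsampler == "dynamic")
      list(W = p[[paste0("up", i, ".off.W")]], b = p[[paste0("up", i, ".off.b")]])
    else NULL
    uf <- dynUpForward(cur, theta, 2L, meta$offsetScale, meta$upsampler)
    st[[paste0("up", i, ".dyn")]] <- uf$cache
    upC <- dim(uf$y)[1]
    skC <- dim(skips[[i]])[1]
    cur <- array(0, c(upC + skC, dim(uf$y)[2], dim(uf$y)[3]))
    cur[seq_len(upC), , ] <- uf$y
    cur[upC + seq_len(skC), , ] <- skips[[i]]
    st[[paste0("up", i, ".split")]] <- c(upC, skC)
    cur <- unitForward(paste0("up", i, ".c1"), cur, p, meta, train, st)
    cur <- unitForward(paste0("up", i, ".c2"), cur, p, meta, train, st)
  }
  out <- unitForward("final", cur, p, meta, train, st, k = 1L, act = "none")
  if (meta$finalAct == "sigmoid") {
    sf <- sigmoidForward(out)
    st$finalSig <- sf$y
    out <- sf$y
  }
  if (keepCache) list(y = out, st = st) else list(y = out, st = NULL)
}

# Backward pass; returns gradient w.r.t. the input and a flat named list of
# parameter gradients.
unetBackward <- function(net, st, dy) {
  p <- net$params; meta <- net$meta
  L <- length(meta$widths)
  grads <- new.env(parent = emptyenv())
  if (meta$finalAct == "sigmoid") dy <- sigmoidBackward(dy, st$finalSig)
  dy <- unitBackward("final", dy, p, meta, st, grads, k = 1L, act = "none")
  for (i in seq_len(L - 1L)) {
    dy <- unitBackward(paste0("up", i, ".c2"), dy, p, meta, st, grads)
    dy <- unitBackward(paste0("up", i, ".c1"), dy, p, meta, st, grads)
    sp <- st[[paste0("up", i, ".split")]]
    dup <- dy[seq_len(sp[1]), , , drop = FALSE]
    dskip <- dy[sp[1] + seq_len(sp[2]), , , drop = FALSE]
    theta <- if (meta$upsampler == "dynamic")
      list(W = p[[paste0("up", i, ".off.W")]], b = p[[paste0("up", i, ".off.b")]])
    else NULL
    ub <- dynUpBackward(dup, st[[paste0("up", i, ".dyn")]], theta)
    if (!is.null(ub$dW)) {
      accGrad(grads, paste0("up", i, ".off.W"), ub$dW)
      accGrad(grads, paste0("up", i, ".off.b"), ub$db)
    }
    dy <- ub$dx
    st[[paste0("skipGrad", i)]] <- dskip
  }
  dy2 <- unitBackward("bott.c2", dy, p, meta, st, grads)
  dy2 <- unitBackward("bott.c1", dy2, p, meta, st, grads)
  for (i in rev(seq_len(L - 1L))) {
    pc <- st[[paste0("pool", i)]]
    dcur <- poolBackward(dy2, pc) + st[[paste0("skipGrad", i)]]
    dcur <- unitBackward(paste0("down", i, ".c2"), dcur, p, meta, st, grads)
    dy2 <- unitBackward(paste0("down", i, ".c1"), dcur, p, meta, st, grads)
  }
  list(dx = dy2, grads = as.list(grads))
}
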
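# Independent oracles and small fixture builders shared across tests.

# Plain-loop bilinear resize with the same pixel-centre convention and
# border clamping as the package operator, written independently of it.
naiveBilinearResize <- function(x, s) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  out <- array(0, c(C, H * s, W * s))
  for (u in 0:(H * s - 1)) {
    for (v in 0:(W * s - 1)) {
      yy <- min(max((u + 0.5) / s - 0.5, 0), H - 1)
      xx <- min(max((v + 0.5) / s - 0.5, 0), W - 1)
      y0 <- floor(yy); x0 <- floor(xx)
      y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
      wy <- yy - y0; wx <- xx - x0
      for (c in 1:C) {
        out[c, u + 1, v + 1] <-
          (1 - wy) * (1 - wx) * x[c, y0 + 1, x0 + 1] +
          (1 - wy) * wx * x[c, y0 + 1, x1 + 1] +
          wy * (1 - wx) * x[c, y1 + 1, x0 + 1] +
          wy * wx * x[c, y1 + 1, x1 + 1]
      }
    }
  }
  out
}

# Brute-force elementwise loss recomputations (explicit loops, no reuse of
# package internals).
bruteMeanAbs <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s / length(a)
}

bruteLsgan <- function(realA, realB, fakeA, fakeB) {
  sq <- function(v, target) {
    s <- 0
    for (i in seq_along(v)) s <- s + (v[i] - target)^2
    s / length(v)
  }
  list(discriminator = 0.5 * sq(realA, 1) + 0.5 * sq(fakeA, 0) +
         0.5 * sq(realB, 1) + 0.5 * sq(fakeB, 0),
       generator = 0.5 * sq(fakeA, 1) + 0.5 * sq(fakeB, 1))
}

# Central finite-difference check of a scalar-valued function's gradient.
relGradErr <- function(f, x, g, idx, eps = 1e-5) {
  errs <- numeric(length(idx))
  for (k in seq_along(idx)) {
    j <- idx[k]
    x2 <- x; x2[j] <- x2[j] + eps
    x3 <- x; x3[j] <- x3[j] - eps
    fd <- (f(x2) - f(x3)) / (2 * eps)
    # absolute floor: a parameter with (near-)zero true effect, e.g. a
    # conv bias absorbed by batch norm, is dominated by FD roundoff
    errs[k] <- abs(fd - g[j]) / max(abs(fd), abs(g[j]), 1e-6)
  }
  max(errs)
}

# A small cell field with traces, used across modules.
tinyField <- function(nCells = 3L, seed = 11L, T = 12L) {
  f <- generateCellField(nCells, c(64L, 64L), seed = seed)
  simulateTraces(f, T = T, seed = seed + 1L)
}

# A reduced architecture for fast network tests.
tinySpec <- function(...) {
  args <- modifyList(list(widths = c(3L, 5L), cz = 2L, discWidths = c(4L)),
                     list(...))
  do.call(translationSpec, args)
}

# A desk config shrunk to a 32x32 patch and a 2-level network for smoke
# tests of the training loop; spec-level toggles from the YAML overrides
# (upsampler, batch norm) carry over into the reduced spec.
tinyConfig <- function(...) {
  cfg <- taskConfig("synthetic", ...)
  cfg@patchSize <- 32L
  cfg@spec <- translationSpec(widths = c(4L, 8L), cz = 4L,
                              discWidths = c(8L),
                              upsampler = cfg@spec@upsampler,
                              useBatchNorm = cfg@spec@useBatchNorm)
  cfg
}

tinyImages <- function(n = 6L, seed = 5L, size = 32L) {
  lapply(seq_len(n), function(i) {
    f <- generateCellField(2L, c(size, size), radiusParams = list(rCyto = 6, rNuc = 3),
                           seed = seed + i)
    renderField(f, domain = if (seed %% 2) "A" else "B",
                noise = list(sigma = 0.05), seed = seed + 100L + i)
  })
}
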
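# Data pipeline and optimisation loop.

#' Percentile normalisation
#'
#' Two modes. \code{"affine"}: (x - P_lo) / (P_hi - P_lo) with percentiles
#' computed per image by linear interpolation. \code{"scale"}: x / P_hi,
#' the scaling-only variant used for calcium recordings whose baseline is
#' meaningful. Degenerate images (P_hi equal to P_lo, or P_hi = 0 in scale
#' mode) map to all zeros rather than dividing by zero.
#'
#' @param x numeric array or matrix (finite values).
#' @param lo,hi percentile positions in [0, 100].
#' @param mode "affine" or "scale".
#' @return normalised array of the same shape.
#' @examples
#' percentileNormalize(matrix(0:99, 10), 0, 100)
#' @export
percentileNormalize <- function(x, lo = 0.1, hi = 99.9,
                                mode = c("affine", "scale")) {
  mode <- match.arg(mode)
  stopifnot(all(is.finite(x)))
  if (mode == "affine") {
    p <- quantile(x, c(lo, hi) / 100, names = FALSE, type = 7)
    if (p[2] <= p[1]) return(x * 0)
    (x - p[1]) / (p[2] - p[1])
  } else {
    p <- quantile(x, hi / 100, names = FALSE, type = 7)
    if (p <= 0) return(x * 0)
    x / p
  }
}

#' Random patch from an image stack
#'
#' Draws a uniformly random frame and a uniformly random top-left corner,
#' deterministic per seed.
#'
#' @param stack a T x H x W array (or H x W matrix, or 1 x H x W array
#'   treated as one frame).
#' @param patchHW integer c(h, w) patch size.
#' @param seed integer seed; NULL draws from the current RNG state.
#' @return an h x w matrix.
#' @export
samplePatch <- function(stack, patchHW, seed = NULL) {
  if (is.matrix(stack)) stack <- array(stack, c(1L, nrow(stack), ncol(stack)))
  d <- dim(stack)
  h <- patchHW[1]; w <- patchHW[2]
  if (d[2] < h || d[3] < w)
    stop("stack (", d[2], "x", d[3], ") smaller than patch (", h, "x", w, ")")
  draw <- function() {
    f <- sample.int(d[1], 1L)
    r0 <- sample.int(d[2] - h + 1L, 1L)
    c0 <- sample.int(d[3] - w + 1L, 1L)
    stack[f, r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

rot90cw <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]

applyDihedral <- function(m, k, flipH, flipV) {
  k <- k %% 4L
  for (j in seq_len(k)) m <- rot90cw(m)
  if (flipH) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (flipV) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m
}

#' Random dihedral augmentation
#'
#' Composition of a random multiple of 90 degree rotation and independent
#' horizontal/vertical flips. An isometry of the pixel grid: the multiset
#' of pixel values is preserved. \code{draw} (or the returned attribute)
#' records the sampled transform so it can be inverted with
#' \code{invertAugment}.
#'
#' @param m square matrix (rotations require a square patch) or C x H x W
#'   array (transform applied per channel).
#' @param seed integer seed; NULL draws from the current RNG state.
#' @param draw optional list(k, flipH, flipV) to apply a fixed transform.
#' @return transformed image with attribute \code{"draw"}.
#' @export
augmentPatch <- function(m, seed = NULL, draw = NULL) {
  if (is.null(draw)) {
    sampleDraw <- function() list(k = sample(0:3, 1L),
                                  flipH = sample(c(TRUE, FALSE), 1L),
                                  flipV = sample(c(TRUE, FALSE), 1L))
    draw <- if (is.null(seed)) sampleDraw() else withSeed(seed, sampleDraw())
  }
  isArr <- is.array(m) && length(dim(m)) == 3L
  if (!isArr && nrow(m) != ncol(m) && draw$k %% 2L == 1L)
    stop("90-degree rotations require a square patch")
  out <- if (isArr) {
    d <- dim(m)
    res <- lapply(seq_len(d[1]), function(c)
      applyDihedral(m[c, , ], draw$k, draw$flipH, draw$flipV))
    aperm(array(unlist(res), c(dim(res[[1]]), d[1])), c(3L, 1L, 2L))
  } else applyDihedral(m, draw$k, draw$flipH, draw$flipV)
  attr(out, "draw") <- draw
  out
}

#' @rdname augmentPatch
#' @param aug an augmented image carrying a \code{"draw"} attribute (or
#'   pass \code{draw} explicitly).
#' @export
invertAugment <- function(aug, draw = attr(aug, "draw")) {
  # inverse of (rot^k then flips): undo flips, then rotate back
  m <- aug
  if (draw$flipV) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (draw$flipH) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  k <- (4L - draw$k %% 4L) %% 4L
  for (j in seq_len(k)) m <- rot90cw(m)
  attr(m, "draw") <- NULL
  m
}

# AdamW step over a flat named parameter list. state holds m/v/t.
adamwInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamwStep <- function(params, grads, state, lr = 3e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weightDecay = 0) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
    params[[nm]] <- params[[nm]] - lr * (upd + weightDecay * params[[nm]])
  }
  list(params = params, state = state)
}

applyBnUpdates <- function(params, updates) {
  for (nm in names(updates)) params[[nm]] <- updates[[nm]]
  params
}

# One optimisation iteration: update discriminators on (real, detached
# fake), then generators through adversarial + cycle + (optional) info
# terms with the freshly updated discriminators.
trainStep <- function(params, opt, xA, xB, cfg, lambdaCycEff) {
  sp <- cfg@spec
  useInfo <- cfg@infoLossOn
  # ---- generator forward (cached) ----
  eA <- unetForward(params$encA, xA, train = TRUE, keepCache = TRUE)
  dB <- unetForward(params$decB, eA$y, train = TRUE, keepCache = TRUE)   # xAB
  eB <- unetForward(params$encB, xB, train = TRUE, keepCache = TRUE)
  dA <- unetForward(params$decA, eB$y, train = TRUE, keepCache = TRUE)   # xBA
  xAB <- dB$y; xBA <- dA$y
  eB2 <- unetForward(params$encB, xAB, train = TRUE, keepCache = TRUE)   # zAB
  dA2 <- unetForward(params$decA, eB2$y, train = TRUE, keepCache = TRUE) # xABA
  eA2 <- unetForward(params$encA, xBA, train = TRUE, keepCache = TRUE)   # zBA
  dB2 <- unetForward(params$decB, eA2$y, train = TRUE, keepCache = TRUE) # xBAB
  zA <- eA$y; zB <- eB$y; zAB <- eB2$y; zBA <- eA2$y
  xABA <- dA2$y; xBAB <- dB2$y

  # ---- discriminator update (fakes detached) ----
  fRA <- discForward(params$discA, xA, train = TRUE, keepCache = TRUE)
  fFA <- discForward(params$discA, xBA, train = TRUE, keepCache = TRUE)
  fRB <- discForward(params$discB, xB, train = TRUE, keepCache = TRUE)
  fFB <- discForward(params$discB, xAB, train = TRUE, keepCache = TRUE)
  adv <- adversarialLoss(fRA$y, fRB$y, fFA$y, fFB$y)
  gDA <- addGradLists(
    discBackward(params$discA, fRA$st, (fRA$y - 1) / length(fRA$y))$grads,
    discBackward(params$discA, fFA$st, fFA$y / length(fFA$y))$grads)
  gDB <- addGradLists(
    discBackward(params$discB, fRB$st, (fRB$y - 1) / length(fRB$y))$grads,
    discBackward(params$discB, fFB$st, fFB$y / length(fFB$y))$grads)
  sA <- adamwStep(params$discA$params, gDA, opt$discA)
  params$discA$params <- applyBnUpdates(sA$params, fRA$st$bnUpdates)
  params$discA$params <- applyBnUpdates(params$discA$params, fFA$st$bnUpdates)
  opt$discA <- sA$state
  sB <- adamwStep(params$discB$params, gDB, opt$discB)
  params$discB$params <- applyBnUpdates(sB$params, fRB$st$bnUpdates)
  params$discB$params <- applyBnUpdates(params$discB$params, fFB$st$bnUpdates)
  opt$discB <- sB$state

  # ---- generator losses with updated discriminators ----
  gFB <- discForward(params$discB, xAB, keepCache = TRUE)   # eval-mode scores
  gFA <- discForward(params$discA, xBA, keepCache = TRUE)
  lossAdvG <- 0.5 * mean((gFB$y - 1)^2) + 0.5 * mean((gFA$y - 1)^2)
  lossCyc <- l1Mean(xA, xABA) + l1Mean(xB, xBAB)
  lossInfo <- if (useInfo) l1Mean(zA, zAB) + l1Mean(zB, zBA) else 0
  total <- cfg@lambdaAdv * lossAdvG + lambdaCycEff * lossCyc +
    cfg@lambdaInfo * lossInfo * as.numeric(useInfo)
  if (!is.finite(total))
    stop(sprintf(paste0("non-finite loss at iteration: adv=%g cyc=%g info=%g; ",
                        "aborting with diagnostic snapshot"),
                 lossAdvG, lossCyc, lossInfo))

  # ---- generator backward ----
  # B-side cycle: xBAB through decB, then zBA through encA, then xBA.
  dxBAB <- lambdaCycEff * l1Grad(xBAB, xB)
  bDB2 <- unetBackward(params$decB, dB2$st, dxBAB)
  dzBA <- bDB2$dx
  if (useInfo) dzBA <- dzBA + cfg@lambdaInfo * l1Grad(zBA, zB)
  bEA2 <- unetBackward(params$encA, eA2$st, dzBA)
  dxBA <- bEA2$dx +
    discBackward(params$discA, gFA$st,
                 cfg@lambdaAdv * (gFA$y - 1) / length(gFA$y))$dx
  bDA <- unetBackward(params$decA, dA$st, dxBA)
  dzB <- bDA$dx
  if (useInfo) dzB <- dzB - cfg@lambdaInfo * l1Grad(zBA, zB)
  bEB <- unetBackward(params$encB, eB$st, dzB)
  # A-side cycle: xABA through decA, then zAB through encB, then xAB.
  dxABA <- lambdaCycEff * l1Grad(xABA, xA)
  bDA2 <- unetBackward(params$decA, dA2$st, dxABA)
  dzAB <- bDA2$dx
  if (useInfo) dzAB <- dzAB + cfg@lambdaInfo * l1Grad(zAB, zA)
  bEB2 <- unetBackward(params$encB, eB2$st, dzAB)
  dxAB <- bEB2$dx +
    discBackward(params$discB, gFB$st,
                 cfg@lambdaAdv * (gFB$y - 1) / length(gFB$y))$dx
  bDB <- unetBackward(params$decB, dB$st, dxAB)
  dzA <- bDB$dx
  if (useInfo) dzA <- dzA - cfg@lambdaInfo * l1Grad(zAB, zA)
  bEA <- unetBackward(params$encA, eA$st, dzA)

  gEncA <- addGradLists(bEA$grads, bEA2$grads)
  gEncB <- addGradLists(bEB$grads, bEB2$grads)
  gDecA <- addGradLists(bDA$grads, bDA2$grads)
  gDecB <- addGradLists(bDB$grads, bDB2$grads)
  for (nm in c("encA", "encB", "decA", "decB")) {
    g <- switch(nm, encA = gEncA, encB = gEncB, decA = gDecA, decB = gDecB)
    stp <- adamwStep(params[[nm]]$params, g, opt[[nm]])
    params[[nm]]$params <- stp$params
    opt[[nm]] <- stp$state
  }
  if (sp@useBatchNorm) {
    params$encA$params <- applyBnUpdates(params$encA$params,
      c(eA$st$bnUpdates, eA2$st$bnUpdates))
    params$encB$params <- applyBnUpdates(params$encB$params,
      c(eB$st$bnUpdates, eB2$st$bnUpdates))
    params$decA$params <- applyBnUpdates(params$decA$params,
      c(dA$st$bnUpdates, dA2$st$bnUpdates))
    params$decB$params <- applyBnUpdates(params$decB$params,
      c(dB$st$bnUpdates, dB2$st$bnUpdates))
  }
  list(params = params, opt = opt,
       log = c(lossD = adv$discriminator, lossAdvG = lossAdvG,
               lossCyc = lossCyc, lossInfo = lossInfo,
               lossG = total, cycWeight = lambdaCycEff))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

addGradLists <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

#' Train a translation model
#'
#' The optimisation loop: per iteration one random patch per domain
#' (online, batch size 1), optional dihedral augmentation, forward passes
#' through both translation directions and both cycles, discriminator
#' update then generator update (AdamW, learning rate 3e-4, no weight
#' decay), with the cycle weight following its schedule. Fully seeded: the
#' master seed is split into independent data, augmentation and
#' initialisation streams, so two runs with the same seed produce identical
#' loss logs (single-threaded BLAS assumed for bit identity).
#'
#' @param config a \linkS4class{TaskConfig}.
#' @param imagesA,imagesB lists of C x H x W arrays (or H x W matrices),
#'   the two unpaired training sets. Images are percentile-normalised per
#'   full frame according to the config before patch sampling.
#' @param iterations number of iterations (default from the config).
#' @param seed master seed.
#' @param model optionally continue training an existing model.
#' @param state optimiser/RNG state returned by a previous call; resuming
#'   with it reproduces the uninterrupted loss trajectory bit-for-bit.
#' @param checkpointDir if non-NULL, checkpoints are written every
#'   \code{config@checkpointEvery} iterations (keeping the last 3 and the
#'   best by generator loss) plus a final checkpoint.
#' @param logFile if non-NULL, the loss log is streamed there as JSONL.
#' @param normalizeInputs set FALSE if the images are already normalised.
#' @return list(model, log, state) with the per-iteration loss log as a
#'   data.frame and the serialisable training state (optimiser moments and
#'   RNG streams) for exact resumption.
#' @export
trainModel <- function(config, imagesA, imagesB,
                       iterations = config@iterations, seed = 1L,
                       model = NULL, checkpointDir = NULL, logFile = NULL,
                       normalizeInputs = TRUE, state = NULL) {
  stopifnot(is(config, "TaskConfig"), length(imagesA) > 0, length(imagesB) > 0)
  norm <- config@normalization
  prep <- function(img) {
    img <- asCHW(img)
    if (normalizeInputs)
      img <- percentileNormalize(img, norm$lo, norm$hi, norm$mode)
    img
  }
  imagesA <- lapply(imagesA, prep)
  imagesB <- lapply(imagesB, prep)
  if (is.null(model)) model <- buildModel(config@spec, deriveSeed(seed, 1L))
  params <- model@params
  if (is.null(state)) {
    opt <- list(encA = adamwInit(params$encA$params),
                encB = adamwInit(params$encB$params),
                decA = adamwInit(params$decA$params),
                decB = adamwInit(params$decB$params),
                discA = adamwInit(params$discA$params),
                discB = adamwInit(params$discB$params))
    streams <- list(data = makeStream(deriveSeed(seed, 2L)),
                    aug = makeStream(deriveSeed(seed, 3L)))
  } else {
    opt <- state$opt
    streams <- state$streams
  }
  ps <- config@patchSize
  logRows <- vector("list", iterations)
  if (!is.null(logFile)) {
    con <- file(logFile, open = "wt")
    on.exit(close(con), add = TRUE)
  }
  pickPatch <- function(imgs) {
    i <- sample.int(length(imgs), 1L)
    img <- imgs[[i]]
    d <- dim(img)
    stack <- array(img, c(d[1], d[2], d[3]))  # channels act as frames == 1
    if (d[1] != 1L) {
      r0 <- sample.int(d[2] - ps + 1L, 1L)
      c0 <- sample.int(d[3] - ps + 1L, 1L)
      img[, r0:(r0 + ps - 1L), c0:(c0 + ps - 1L), drop = FALSE]
    } else {
      asCHW(samplePatch(stack, c(ps, ps)))
    }
  }
  for (it in seq_len(iterations)) {
    wd <- withStream(streams, "data", list(A = pickPatch(imagesA),
                                           B = pickPatch(imagesB)))
    streams <- wd$streams
    wa <- withStream(streams, "aug", {
      a <- augmentPatch(wd$value$A)
      b <- augmentPatch(wd$value$B)
      list(A = a, B = b)
    })
    streams <- wa$streams
    xA <- wa$value$A; attr(xA, "draw") <- NULL
    xB <- wa$value$B; attr(xB, "draw") <- NULL
    lamCyc <- cycleWeight(config@schedule, model@iteration + it,
                          model@iteration + iterations, config@lambdaCyc)
    res <- withFloatConv(trainStep(params, opt, xA, xB, config, lamCyc))
    params <- res$params; opt <- res$opt
    row <- c(iteration = model@iteration + it, res$log)
    logRows[[it]] <- row
    if (!is.null(logFile))
      writeLines(jsonlite::toJSON(as.list(row), auto_unbox = TRUE,
                                  digits = NA), con)
    if (!is.null(checkpointDir) && it %% config@checkpointEvery == 0L) {
      model@params <- params
      model@iteration <- model@iteration + it
      writeCheckpointRolling(model, checkpointDir, res$log[["lossG"]])
      model@iteration <- model@iteration - it
    }
  }
  model@params <- params
  model@iteration <- model@iteration + as.integer(iterations)
  if (!is.null(checkpointDir))
    saveCheckpoint(model, file.path(checkpointDir, "final.rds"))
  log <- as.data.frame(do.call(rbind, logRows))
  list(model = model, log = log, state = list(opt = opt, streams = streams))
}

# Keep the last 3 periodic checkpoints plus the best by generator loss.
writeCheckpointRolling <- function(model, dir, lossG) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, sprintf("iter%06d.rds", model@iteration))
  saveCheckpoint(model, path)
  kept <- sort(list.files(dir, pattern = "^iter\\d+\\.rds$", full.names = TRUE))
  if (length(kept) > 3L)
    file.remove(head(kept, length(kept) - 3L))
  bestFile <- file.path(dir, "best.rds")
  bestLoss <- file.path(dir, "best_loss.txt")
  prev <- if (file.exists(bestLoss))
    as.numeric(readLines(bestLoss, warn = FALSE)[1]) else Inf
  if (lossG < prev) {
    saveCheckpoint(model, bestFile)
    writeLines(format(lossG, digits = 17), bestLoss)
  }
  invisible(path)
}
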
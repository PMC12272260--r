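# Model-level surface: build, run and serialise a translation model.

#' Construct a TranslationSpec
#'
#' @param channelsA,channelsB image channel counts of the two domains.
#' @param cz feature-map channel count.
#' @param widths channel widths per spatial level.
#' @param useBatchNorm,useModulation logical toggles.
#' @param upsampler "dynamic" or "bilinear" (ablation).
#' @param finalActivation "linear" or "sigmoid".
#' @param discWidths discriminator widths.
#' @param offsetScale multiplier on predicted grid offsets.
#' @return a \linkS4class{TranslationSpec}.
#' @export
translationSpec <- function(channelsA = 1L, channelsB = 1L, cz = 8L,
                            widths = c(8L, 16L, 32L),
                            useBatchNorm = FALSE, useModulation = FALSE,
                            upsampler = c("dynamic", "bilinear"),
                            finalActivation = c("linear", "sigmoid"),
                            discWidths = c(64L, 128L, 256L, 512L),
                            offsetScale = 1) {
  new("TranslationSpec", channelsA = as.integer(channelsA),
      channelsB = as.integer(channelsB), cz = as.integer(cz),
      widths = as.integer(widths), useBatchNorm = useBatchNorm,
      useModulation = useModulation, upsampler = match.arg(upsampler),
      finalActivation = match.arg(finalActivation),
      discWidths = as.integer(discWidths), offsetScale = offsetScale)
}

#' Build a translation model from a spec
#'
#' Initialises both encoders (image -> CZ-channel full-resolution feature
#' map), both decoders (feature map -> target-domain image) and both
#' least-squares discriminators. Hidden 3x3 convolutions use He
#' initialisation, offset-predicting 1x1 convolutions start at zero (so the
#' dynamic upsampler begins as exact bilinear upsampling) and discriminator
#' weights use N(0, 0.02).
#'
#' @param spec a \linkS4class{TranslationSpec}.
#' @param seed initialisation seed.
#' @return a \linkS4class{TranslationModel}.
#' @export
buildModel <- function(spec, seed = 1L) {
  stopifnot(is(spec, "TranslationSpec"))
  params <- withSeed(seed, list(
    encA = unetInit(spec@channelsA, spec@cz, spec@widths, spec@useBatchNorm,
                    spec@useModulation, spec@upsampler, "linear",
                    spec@offsetScale),
    encB = unetInit(spec@channelsB, spec@cz, spec@widths, spec@useBatchNorm,
                    spec@useModulation, spec@upsampler, "linear",
                    spec@offsetScale),
    decA = unetInit(spec@cz, spec@channelsA, spec@widths, spec@useBatchNorm,
                    spec@useModulation, spec@upsampler, spec@finalActivation,
                    spec@offsetScale),
    decB = unetInit(spec@cz, spec@channelsB, spec@widths, spec@useBatchNorm,
                    spec@useModulation, spec@upsampler, spec@finalActivation,
                    spec@offsetScale),
    discA = discInit(spec@channelsA, spec@discWidths, spec@useBatchNorm),
    discB = discInit(spec@channelsB, spec@discWidths, spec@useBatchNorm)))
  new("TranslationModel", spec = spec, params = params,
      iteration = 0L, seed = as.integer(seed))
}

#' Encode an image into the shared feature domain
#'
#' Runs the domain's encoder; the feature map has \code{cz} channels and
#' exactly the spatial size of the input (the full-resolution contract).
#'
#' @param object a \linkS4class{TranslationModel}.
#' @param x a C x H x W image array (or H x W matrix for 1 channel).
#' @param domain which encoder, "A" or "B".
#' @return a cz x H x W feature array.
#' @rdname encode
#' @export
setMethod("encode", "TranslationModel", function(object, x, domain = c("A", "B"), ...) {
  domain <- match.arg(domain)
  x <- asCHW(x)
  net <- if (domain == "A") object@params$encA else object@params$encB
  unetForward(net, x)$y
})

#' Decode a feature map into an image domain
#'
#' @param object a \linkS4class{TranslationModel}.
#' @param z a cz x H x W feature array.
#' @param domain target image domain.
#' @return a C_domain x H x W image array.
#' @rdname decode
#' @export
setMethod("decode", "TranslationModel", function(object, z, domain = c("A", "B"), ...) {
  domain <- match.arg(domain)
  net <- if (domain == "A") object@params$decA else object@params$decB
  unetForward(net, z)$y
})

#' Translate an image between domains
#'
#' Composition of the source-domain encoder and the target-domain decoder
#' (A to B: decoder B applied to encoder A's feature map). Deterministic:
#' no stochastic layers act at inference. Images whose sides are not
#' divisible by 2^(levels - 1) are reflectively padded and the output is
#' cropped back.
#'
#' @param object a \linkS4class{TranslationModel}.
#' @param x image array (C x H x W or H x W).
#' @param direction "AtoB" or "BtoA".
#' @param pad pad arbitrary sizes reflectively (default TRUE).
#' @return translated image array, target-domain channel count, same H, W.
#' @rdname translate
#' @export
setMethod("translate", "TranslationModel",
  function(object, x, direction = c("AtoB", "BtoA"), pad = TRUE, ...) {
    direction <- match.arg(direction)
    x <- asCHW(x)
    d <- dim(x)
    div <- 2L^(length(object@spec@widths) - 1L)
    padded <- FALSE
    if (pad && (d[2] %% div != 0L || d[3] %% div != 0L)) {
      x <- padToMultiple(x, div)
      padded <- TRUE
    }
    z <- encode(object, x, substr(direction, 1L, 1L))
    out <- decode(object, z, substr(direction, 4L, 4L))
    if (padded) out <- out[, seq_len(d[2]), seq_len(d[3]), drop = FALSE]
    out
  })

#' Discriminator score map for an image
#'
#' @param object a \linkS4class{TranslationModel}.
#' @param x image array in the discriminator's domain.
#' @param domain "A" or "B".
#' @return a 1 x h' x w' real-valued score map (no sigmoid; scores feed the
#'   least-squares objective).
#' @rdname discriminate
#' @export
setMethod("discriminate", "TranslationModel",
  function(object, x, domain = c("A", "B"), ...) {
    domain <- match.arg(domain)
    x <- asCHW(x)
    net <- if (domain == "A") object@params$discA else object@params$discB
    discForward(net, x)$y
  })

#' Reflective padding to a size multiple
#'
#' @param x C x H x W array.
#' @param div required divisor of the padded H and W.
#' @return padded array (bottom/right reflection padding).
#' @export
padToMultiple <- function(x, div) {
  x <- asCHW(x)
  d <- dim(x)
  H2 <- as.integer(ceiling(d[2] / div) * div)
  W2 <- as.integer(ceiling(d[3] / div) * div)
  if (H2 == d[2] && W2 == d[3]) return(x)
  refl <- function(n, n2) {
    idx <- seq_len(n2)
    over <- idx > n
    idx[over] <- n - (idx[over] - n)  # reflect without repeating the edge
    pmax(idx, 1L)
  }
  x[, refl(d[2], H2), refl(d[3], W2), drop = FALSE]
}

#' Weight modulation and demodulation
#'
#' Scales convolution weights per input channel, then renormalises each
#' output filter to unit L2 norm (plus a small epsilon), the mechanism used
#' to suppress droplet-like artifacts in the intermediate feature maps.
#' With all scales equal the transform reduces to pure per-filter
#' normalisation, and rescaling all scales by a common factor leaves the
#' result unchanged.
#'
#' @param W convolution weights: a (Cin k^2) x Cout matrix (input channel
#'   fastest along rows) or a k x k x Cin x Cout array.
#' @param scales positive per-input-channel scale vector.
#' @param eps numerical stabiliser inside the filter-norm square root.
#' @return adjusted weights in the shape they were supplied.
#' @export
modulateDemodulate <- function(W, scales, eps = 1e-8) {
  stopifnot(all(scales > 0))
  asArray <- is.array(W) && length(dim(W)) == 4L
  if (asArray) {
    dW <- dim(W)
    k <- dW[1]; cin <- dW[3]
    Wm <- matrix(aperm(W, c(3L, 1L, 2L, 4L)), ncol = dW[4])
  } else {
    Wm <- W
    cin <- length(scales)
    k <- as.integer(sqrt(nrow(Wm) / cin))
  }
  out <- modDemodForward(Wm, scales, k, cin, eps)$W
  if (asArray) {
    dW <- dim(W)
    out <- array(out, c(cin, k, k, dW[4]))
    out <- aperm(out, c(2L, 3L, 1L, 4L))
  }
  out
}

#' @rdname accessors
#' @export
setMethod("modelSpec", "TranslationModel", function(object) object@spec)

#' @rdname accessors
#' @export
setMethod("modelSpec", "TaskConfig", function(object) object@spec)

#' @rdname accessors
#' @export
setMethod("parameterCount", "TranslationModel", function(object) {
  vapply(object@params, function(net)
    sum(vapply(net$params, length, 1L)), 1L)
})

setMethod("show", "TranslationSpec", function(object) {
  cat(sprintf(paste0("TranslationSpec: %d/%d image channels, CZ=%d, levels [%s],\n",
                     "  batchnorm=%s modulation=%s upsampler=%s final=%s disc=[%s]\n"),
              object@channelsA, object@channelsB, object@cz,
              paste(object@widths, collapse = ","),
              object@useBatchNorm, object@useModulation, object@upsampler,
              object@finalActivation,
              paste(object@discWidths, collapse = ",")))
})

setMethod("show", "TranslationModel", function(object) {
  pc <- parameterCount(object)
  cat(sprintf("TranslationModel (iteration %d, seed %d)\n",
              object@iteration, object@seed))
  cat("  parameters:", paste(sprintf("%s=%d", names(pc), pc), collapse = " "),
      "\n")
  show(object@spec)
})

setMethod("show", "TaskConfig", function(object) {
  cat(sprintf(paste0("TaskConfig '%s': patch %d, lambda(adv,cyc,info)=(%g,%g,%g),\n",
                     "  normalization %s [%g,%g], schedule=%s, info loss %s, %d iterations\n"),
              object@name, object@patchSize, object@lambdaAdv,
              object@lambdaCyc, object@lambdaInfo, object@normalization$mode,
              object@normalization$lo, object@normalization$hi,
              object@schedule$enabled,
              if (object@infoLossOn) "on" else "off", object@iterations))
  show(object@spec)
})

#' Save / load model checkpoints
#'
#' Checkpoints embed the architecture spec alongside every parameter
#' tensor; loading verifies the embedded spec against an expected one when
#' given and errors on mismatch.
#'
#' @param model a \linkS4class{TranslationModel}.
#' @param path file path (.rds).
#' @param expectedSpec optional \linkS4class{TranslationSpec} to verify.
#' @return \code{loadCheckpoint} returns the model; \code{saveCheckpoint}
#'   the path, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(spec = model@spec, params = model@params,
               iteration = model@iteration, seed = model@seed,
               package = "InfoCycle", version = "0.1.0"),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path, expectedSpec = NULL) {
  obj <- readRDS(path)
  if (!is.null(expectedSpec) && !isTRUE(all.equal(obj$spec, expectedSpec)))
    stop("checkpoint spec does not match the expected architecture spec")
  new("TranslationModel", spec = obj$spec, params = obj$params,
      iteration = obj$iteration, seed = obj$seed)
}
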
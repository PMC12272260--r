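#' Latent synthetic cell field
#'
#' Ground truth behind a pair of synthetic image domains: cell centres and
#' radii on a pixel grid, a shared background level, and per-cell activity
#' traces. The same field renders either as cytosolic rings (domain A) or as
#' nuclear disks (domain B), so the two domains share all latent
#' information by construction.
#'
#' @slot cells data.frame with columns \code{x}, \code{y} (0-based centre
#'   coordinates, x = column, y = row), \code{rCyto}, \code{rNuc} (pixels).
#' @slot imageSize integer c(H, W).
#' @slot backgroundLevel background intensity as a fraction of dynamic
#'   range, in [0, 1].
#' @slot traces numeric matrix, one row per cell, one column per timepoint;
#'   nonnegative amplitudes. May have zero columns before
#'   \code{\link{simulateTraces}} is called.
#' @slot minSeparation minimum pairwise centre distance (pixels).
#' @slot seed integer seed the field was generated from.
#' @seealso \code{\link{generateCellField}}, \code{\link{renderField}},
#'   \code{\link{groundTruthMask}}
#' @exportClass CellField
setClass("CellField", representation(
  cells = "data.frame",
  imageSize = "integer",
  backgroundLevel = "numeric",
  traces = "matrix",
  minSeparation = "numeric",
  seed = "integer"
))

setValidity("CellField", function(object) {
  msgs <- character()
  cl <- object@cells
  need <- c("x", "y", "rCyto", "rNuc")
  if (!all(need %in% names(cl)))
    return(paste("cells must have columns", paste(need, collapse = ", ")))
  if (length(object@imageSize) != 2L || any(object@imageSize < 1L))
    msgs <- c(msgs, "imageSize must be two positive integers c(H, W)")
  if (nrow(cl)) {
    H <- object@imageSize[1]; W <- object@imageSize[2]
    if (any(cl$rNuc >= cl$rCyto))
      msgs <- c(msgs, "rNuc must be strictly smaller than rCyto for every cell")
    if (any(cl$x < 0 | cl$x > W - 1 | cl$y < 0 | cl$y > H - 1))
      msgs <- c(msgs, "cell centres must lie inside the image")
    if (nrow(cl) > 1L) {
      d <- as.matrix(stats::dist(cl[, c("x", "y")]))
      diag(d) <- Inf
      if (min(d) < object@minSeparation - 1e-9)
        msgs <- c(msgs, "pairwise centre distances must be >= minSeparation")
    }
    if (ncol(object@traces)) {
      if (nrow(object@traces) != nrow(cl))
        msgs <- c(msgs, "traces must have one row per cell")
      if (!all(is.finite(object@traces)) || any(object@traces < 0))
        msgs <- c(msgs, "all trace amplitudes must be finite and >= 0")
    }
  }
  if (object@backgroundLevel < 0 || object@backgroundLevel > 1)
    msgs <- c(msgs, "backgroundLevel must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Unpaired synthetic two-domain dataset
#'
#' Training images for two domains generated from disjoint sets of latent
#' cell fields (unpaired by construction) plus a paired held-out test set
#' where both domains, ground-truth label masks and activity traces come
#' from one shared field.
#'
#' @slot trainA,trainB lists of 1 x H x W image arrays.
#' @slot testPaired list; each element holds \code{field} (CellField),
#'   \code{imagesA}/\code{imagesB} (T x H x W arrays), \code{maskA}/
#'   \code{maskB} (integer H x W label matrices) and \code{traces}.
#' @slot noise list with \code{sigma} (Gaussian sd as a fraction of dynamic
#'   range) and \code{poisson} flag.
#' @slot seed master integer seed.
#' @slot metadata list carrying the field seeds behind each split.
#' @seealso \code{\link{makeSyntheticDataset}}
#' @exportClass SyntheticDataset
setClass("SyntheticDataset", representation(
  trainA = "list",
  trainB = "list",
  testPaired = "list",
  noise = "list",
  seed = "integer",
  metadata = "list"
))

setValidity("SyntheticDataset", function(object) {
  sa <- object@metadata$fieldSeedsA
  sb <- object@metadata$fieldSeedsB
  if (length(intersect(sa, sb)))
    return("train_A and train_B must come from disjoint cell fields")
  TRUE
})

#' Architecture specification for one translation model
#'
#' Describes the encoder/decoder U-nets (channel widths per spatial level,
#' feature-domain width CZ, batch norm, weight modulation, choice of
#' upsampler) and the discriminators for a pair of image domains.
#'
#' @slot channelsA,channelsB image channel counts of the two domains.
#' @slot cz feature-map channel count (the shared domain width).
#' @slot widths integer vector of channel widths per spatial level
#'   (>= 2 levels).
#' @slot useBatchNorm,useModulation logical toggles.
#' @slot upsampler "dynamic" (learned offsets) or "bilinear" (fixed grid,
#'   the ablation setting).
#' @slot finalActivation decoder output activation, "linear" or "sigmoid".
#' @slot discWidths discriminator channel widths (one stride-2 4x4 conv per
#'   entry, then a 3x3 conv to a single-channel score map).
#' @slot offsetScale multiplier applied to predicted grid offsets.
#' @exportClass TranslationSpec
setClass("TranslationSpec", representation(
  channelsA = "integer",
  channelsB = "integer",
  cz = "integer",
  widths = "integer",
  useBatchNorm = "logical",
  useModulation = "logical",
  upsampler = "character",
  finalActivation = "character",
  discWidths = "integer",
  offsetScale = "numeric"
))

setValidity("TranslationSpec", function(object) {
  msgs <- character()
  if (length(object@widths) < 2L) msgs <- c(msgs, "need at least 2 levels")
  if (object@cz < 1L) msgs <- c(msgs, "cz must be >= 1")
  if (!object@upsampler %in% c("dynamic", "bilinear"))
    msgs <- c(msgs, "upsampler must be 'dynamic' or 'bilinear'")
  if (!object@finalActivation %in% c("linear", "sigmoid"))
    msgs <- c(msgs, "finalActivation must be 'linear' or 'sigmoid'")
  if (length(msgs)) msgs else TRUE
})

#' A translation model: two encoders, two decoders, two discriminators
#'
#' Parameters are plain named lists of numeric arrays so that checkpoints
#' are transparent; all forward/backward passes run through package
#' internals. Build with \code{\link{buildModel}}, train with
#' \code{\link{trainModel}}, apply with \code{\link{translate}}.
#'
#' @slot spec the \linkS4class{TranslationSpec} the networks were built from.
#' @slot params named list with elements encA, encB, decA, decB, discA,
#'   discB.
#' @slot iteration training iterations already applied.
#' @slot seed initialisation seed.
#' @exportClass TranslationModel
setClass("TranslationModel", representation(
  spec = "TranslationSpec",
  params = "list",
  iteration = "integer",
  seed = "integer"
))

#' Per-task training configuration
#'
#' One object per translation task bundling the architecture, loss weights,
#' normalisation mode and data-pipeline settings. Shipped presets
#' (\code{\link{taskConfig}}) mirror published recipes per task.
#'
#' @slot name task identifier.
#' @slot patchSize training patch side (pixels), divisible by
#'   2^(levels - 1).
#' @slot normalization list(mode = "affine"|"scale", lo, hi) percentile
#'   normalisation settings.
#' @slot lambdaAdv,lambdaCyc,lambdaInfo loss weights.
#' @slot schedule list(enabled, k, m): sigmoid growth schedule for the
#'   cycle-consistency weight.
#' @slot iterations default training iteration count.
#' @slot infoLossOn logical ablation toggle for the information-consistency
#'   term.
#' @slot spec the \linkS4class{TranslationSpec}.
#' @slot checkpointEvery checkpoint cadence (iterations).
#' @exportClass TaskConfig
setClass("TaskConfig", representation(
  name = "character",
  patchSize = "integer",
  normalization = "list",
  lambdaAdv = "numeric",
  lambdaCyc = "numeric",
  lambdaInfo = "numeric",
  schedule = "list",
  iterations = "integer",
  infoLossOn = "logical",
  spec = "TranslationSpec",
  checkpointEvery = "integer"
))

setValidity("TaskConfig", function(object) {
  msgs <- character()
  nm <- object@normalization
  if (!nm$mode %in% c("affine", "scale"))
    msgs <- c(msgs, "normalization mode must be 'affine' or 'scale'")
  if (nm$mode == "affine" && !(nm$lo >= 0 && nm$lo < nm$hi && nm$hi <= 100))
    msgs <- c(msgs, "percentiles must satisfy 0 <= lo < hi <= 100")
  if (any(c(object@lambdaAdv, object@lambdaCyc, object@lambdaInfo) < 0))
    msgs <- c(msgs, "loss weights must be nonnegative")
  lv <- length(object@spec@widths)
  if (object@patchSize %% (2L^(lv - 1L)) != 0L)
    msgs <- c(msgs, sprintf("patchSize must be divisible by %d", 2L^(lv - 1L)))
  if (length(msgs)) msgs else TRUE
})
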
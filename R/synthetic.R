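# Synthetic two-domain microscopy generator.
#
# A latent CellField renders either as cytosolic rings (domain A) or as
# nuclear disks (domain B). Both renderings scale linearly with the same
# per-cell activity a_i(t), so across cells the mean intensities of the two
# domains are perfectly positively correlated (cell-level monotonicity),
# while inside a cell the radial profiles run in opposite directions:
# domain A is dim at the centre and bright near the rim, domain B the
# reverse (pixel-level anti-monotonicity).

#' Generate a latent synthetic cell field
#'
#' Rejection-samples non-overlapping cell centres on an H x W pixel grid.
#' Centres sit on integer pixel positions, so every cell's rasterised
#' footprint samples the radial profiles identically - this is what makes
#' the cell-level A/B mean-intensity relationship exactly linear rather
#' than linear up to sub-pixel jitter. Centres keep a margin of
#' \code{rCyto} from the border so every footprint lies inside the image,
#' and pairwise centre distances respect \code{minSeparation} (default
#' \code{2 * rCyto}: cell footprints are disjoint).
#'
#' @param nCells number of cells (>= 0).
#' @param imageSize integer c(H, W); must be at least 4 * rCyto.
#' @param radiusParams list with \code{rCyto} (default 8), \code{rNuc}
#'   (default 4) and \code{jitter} (sd of per-cell radius jitter in pixels,
#'   default 0).
#' @param backgroundLevel background intensity fraction, default 0.1.
#' @param minSeparation minimum pairwise centre distance; default
#'   \code{2 * rCyto}.
#' @param seed integer seed; the same seed reproduces the field exactly.
#' @param maxAttempts rejection-sampling budget per cell.
#' @return a valid \linkS4class{CellField} (with an empty trace matrix).
#' @examples
#' f <- generateCellField(5, c(64, 64), seed = 7)
#' nCells(f)
#' @export
generateCellField <- function(nCells, imageSize = c(64L, 64L),
                              radiusParams = list(),
                              backgroundLevel = 0.1,
                              minSeparation = NULL,
                              seed = 1L, maxAttempts = 200L * max(nCells, 1L)) {
  rp <- modifyList(list(rCyto = 8, rNuc = 4, jitter = 0), radiusParams)
  if (rp$rCyto <= 0 || rp$rNuc <= 0 || rp$rNuc >= rp$rCyto)
    stop("need 0 < rNuc < rCyto")
  H <- as.integer(imageSize[1]); W <- as.integer(imageSize[2])
  if (H < 4 * rp$rCyto || W < 4 * rp$rCyto)
    stop("imageSize must be at least 4 * rCyto in both dimensions")
  if (is.null(minSeparation)) minSeparation <- 2 * rp$rCyto
  if (nCells > 0) {
    # Necessary packing condition: disjoint disks of radius minSeparation/2
    # cannot exceed the hexagonal packing density of the image area.
    if (nCells * pi * (minSeparation / 2)^2 > 0.9069 * H * W)
      stop("packing infeasible: ", nCells, " cells with minSeparation ",
           minSeparation, " cannot fit a ", H, "x", W, " image")
  }
  field <- withSeed(seed, {
    xs <- ys <- numeric(0)
    attempts <- 0L
    m <- rp$rCyto
    while (length(xs) < nCells) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop("packing infeasible: could not place ", nCells,
             " cells after ", maxAttempts, " attempts")
      cx <- round(runif(1, m, W - 1 - m))
      cy <- round(runif(1, m, H - 1 - m))
      if (!length(xs) ||
          min(sqrt((xs - cx)^2 + (ys - cy)^2)) >= minSeparation) {
        xs <- c(xs, cx); ys <- c(ys, cy)
      }
    }
    rc <- pmax(rp$rCyto + rnorm(nCells, 0, rp$jitter), rp$rCyto * 0.5)
    rn <- pmin(rp$rNuc * rc / rp$rCyto, rc * 0.9)
    data.frame(x = xs, y = ys, rCyto = rc, rNuc = rn)
  })
  if (nCells == 0)
    field <- data.frame(x = numeric(0), y = numeric(0),
                        rCyto = numeric(0), rNuc = numeric(0))
  new("CellField", cells = field, imageSize = c(H, W),
      backgroundLevel = backgroundLevel,
      traces = matrix(numeric(0), nrow = nCells, ncol = 0),
      minSeparation = minSeparation, seed = as.integer(seed))
}

#' Simulate per-cell activity traces
#'
#' Each trace is a Poisson spike train convolved with a causal exponential
#' kernel \code{exp(-t / decayTau)} on top of a constant baseline, the
#' standard shape of somatic calcium-indicator activity.
#'
#' @param field a \linkS4class{CellField}.
#' @param T number of timepoints (>= 1).
#' @param spikeRate expected spikes per frame per cell.
#' @param decayTau decay time constant in frames (> 0).
#' @param baseline constant baseline amplitude (>= 0).
#' @param spikeAmp amplitude added per spike.
#' @param seed integer seed.
#' @return the field with its \code{traces} slot filled (nCells x T).
#' @rdname simulateTraces
#' @export
setMethod("simulateTraces", "CellField",
  function(field, T, spikeRate = 0.05, decayTau = 5, baseline = 0.3,
           spikeAmp = 1, seed = 1L) {
    T <- as.integer(T)
    if (T < 1L) stop("T must be >= 1")
    if (decayTau <= 0) stop("decayTau must be > 0")
    if (spikeRate < 0 || baseline < 0) stop("spikeRate and baseline must be >= 0")
    n <- nCells(field)
    tr <- withSeed(seed, {
      kern <- exp(-(seq_len(T) - 1) / decayTau)
      out <- matrix(baseline, n, T)
      if (n > 0) for (i in seq_len(n)) {
        spikes <- rpois(T, spikeRate)
        if (any(spikes > 0)) {
          resp <- stats::convolve(spikes, rev(kern), type = "open")[seq_len(T)]
          out[i, ] <- out[i, ] + spikeAmp * resp
        }
        out
      }
      out
    })
    field@traces <- tr
    validObject(field)
    field
  })

# Smooth radial intensity profiles, truncated at the cytosolic radius so
# that non-overlapping cells contribute strictly disjoint footprints.
# Domain A: difference of Gaussians of the two radii (bright ring, dim
# centre); domain B: Gaussian nuclear disk. Both scale with a_i(t).
cellProfileA <- function(d, rCyto, rNuc, centerDip = 0.9) {
  p <- exp(-d^2 / (2 * (rCyto / 2)^2)) - centerDip * exp(-d^2 / (2 * (rNuc / 2)^2))
  p[d > rCyto] <- 0
  p
}

cellProfileB <- function(d, rCyto, rNuc) {
  p <- exp(-d^2 / (2 * (rNuc / 2)^2))
  p[d > rCyto] <- 0
  p
}

#' Render a cell field as an image of one domain
#'
#' Domain A paints each cell as a ring (bright between nuclear and
#' cytosolic radius, dimmer at the centre); domain B paints a nuclear disk.
#' Pixel intensities scale with the cell's activity \code{a_i(t)}; the
#' shared background level is added everywhere, then optional noise, and
#' the result is clipped at zero.
#'
#' @param field a \linkS4class{CellField} with traces (or without, in which
#'   case unit amplitudes are used).
#' @param t timepoint index (1-based, <= ncol(traces)).
#' @param domain "A" (cytosolic rings) or "B" (nuclear disks).
#' @param noise list(sigma = Gaussian sd as fraction of dynamic range,
#'   poisson = flag, scale = Poisson photon scale); NULL for a noiseless
#'   render.
#' @param seed seed for the noise draw.
#' @return a 1 x H x W image array.
#' @examples
#' f <- generateCellField(3, c(64, 64), seed = 2)
#' f <- simulateTraces(f, T = 10, seed = 3)
#' imgA <- renderField(f, 1, "A")
#' imgB <- renderField(f, 1, "B")
#' @rdname renderField
#' @export
setMethod("renderField", "CellField",
  function(field, t = 1L, domain = c("A", "B"), noise = NULL, seed = 1L) {
    domain <- match.arg(domain)
    H <- field@imageSize[1]; W <- field@imageSize[2]
    n <- nCells(field)
    amps <- if (ncol(field@traces)) {
      if (t > ncol(field@traces)) stop("t exceeds trace length")
      field@traces[, t]
    } else rep(1, n)
    img <- matrix(field@backgroundLevel, H, W)
    if (n > 0) {
      xs <- 0:(W - 1); ys <- 0:(H - 1)
      for (i in seq_len(n)) {
        ci <- field@cells[i, ]
        dx2 <- (xs - ci$x)^2; dy2 <- (ys - ci$y)^2
        d <- sqrt(outer(dy2, dx2, "+"))
        prof <- if (domain == "A") cellProfileA(d, ci$rCyto, ci$rNuc)
                else cellProfileB(d, ci$rCyto, ci$rNuc)
        img <- img + amps[i] * prof
      }
    }
    if (!is.null(noise)) {
      img <- withSeed(seed, {
        out <- img
        if (isTRUE(noise$poisson)) {
          scale <- if (is.null(noise$scale)) 100 else noise$scale
          out <- rpois(length(out), pmax(out, 0) * scale) / scale
          out <- matrix(out, H, W)
        }
        sigma <- if (is.null(noise$sigma)) 0 else noise$sigma
        if (sigma > 0) out <- out + matrix(rnorm(H * W, 0, sigma), H, W)
        out
      })
    }
    img[img < 0] <- 0
    array(img, c(1L, H, W))
  })

#' Ground-truth instance label mask for a cell field
#'
#' Integer labels 1..nCells over each cell's footprint: the filled
#' cell-body disk of radius \code{rCyto} in domain A, the nuclear disk of
#' radius \code{rNuc} in domain B (so the nuclear ROI is always a subset of
#' the matching cytosolic ROI). Pixels claimed by several cells go to the
#' nearer centre.
#'
#' @param field a \linkS4class{CellField}.
#' @param domain "A" or "B".
#' @return an integer H x W matrix, 0 = background.
#' @rdname groundTruthMask
#' @export
setMethod("groundTruthMask", "CellField",
  function(field, domain = c("A", "B")) {
    domain <- match.arg(domain)
    H <- field@imageSize[1]; W <- field@imageSize[2]
    lab <- matrix(0L, H, W)
    n <- nCells(field)
    if (n == 0) return(lab)
    best <- matrix(Inf, H, W)
    xs <- 0:(W - 1); ys <- 0:(H - 1)
    for (i in seq_len(n)) {
      ci <- field@cells[i, ]
      d <- sqrt(outer((ys - ci$y)^2, (xs - ci$x)^2, "+"))
      r <- if (domain == "A") ci$rCyto else ci$rNuc
      hit <- d <= r & d < best
      lab[hit] <- i
      best[hit] <- d[hit]
    }
    lab
  })

#' Build an unpaired two-domain synthetic dataset
#'
#' Training images for the two domains come from disjoint sets of latent
#' fields (so the dataset is unpaired by construction, which the object's
#' validity check enforces on the stored field seeds); the paired test set
#' shares one field per item and carries ground-truth masks and traces.
#' Regeneration with the same seed is bit-identical.
#'
#' @param nTrainA,nTrainB number of training images per domain.
#' @param nTestFields number of paired test fields.
#' @param testFrames frames rendered per paired test field.
#' @param nCells cells per field.
#' @param imageSize c(H, W).
#' @param noise list(sigma, poisson) applied to every rendered image.
#' @param radiusParams see \code{\link{generateCellField}}.
#' @param traceT trace length per field.
#' @param seed master seed.
#' @return a \linkS4class{SyntheticDataset}.
#' @export
makeSyntheticDataset <- function(nTrainA = 40L, nTrainB = 40L,
                                 nTestFields = 6L, testFrames = 10L,
                                 nCells = 5L, imageSize = c(64L, 64L),
                                 noise = list(sigma = 0.05, poisson = FALSE),
                                 radiusParams = list(), traceT = 20L,
                                 seed = 1L) {
  mkField <- function(fs) {
    f <- generateCellField(nCells, imageSize, radiusParams, seed = fs)
    simulateTraces(f, T = traceT, seed = deriveSeed(fs, 17L))
  }
  seedsA <- vapply(seq_len(nTrainA), function(i) deriveSeed(seed, 3L * i), 1L)
  seedsB <- vapply(seq_len(nTrainB), function(i) deriveSeed(seed, 3L * i + 1L), 1L)
  seedsT <- vapply(seq_len(nTestFields), function(i) deriveSeed(seed, 3L * i + 2L), 1L)
  stopifnot(!length(intersect(seedsA, seedsB)))
  renderOne <- function(fs, domain) {
    f <- mkField(fs)
    tsel <- 1L + (fs %% max(ncol(f@traces), 1L))
    renderField(f, tsel, domain, noise = noise, seed = deriveSeed(fs, 29L))
  }
  trainA <- lapply(seedsA, renderOne, domain = "A")
  trainB <- lapply(seedsB, renderOne, domain = "B")
  testPaired <- lapply(seedsT, function(fs) {
    f <- mkField(fs)
    Tn <- min(testFrames, ncol(f@traces))
    stackA <- array(0, c(Tn, imageSize[1], imageSize[2]))
    stackB <- array(0, c(Tn, imageSize[1], imageSize[2]))
    for (t in seq_len(Tn)) {
      stackA[t, , ] <- renderField(f, t, "A", noise = noise,
                                   seed = deriveSeed(fs, 100L + t))[1, , ]
      stackB[t, , ] <- renderField(f, t, "B", noise = noise,
                                   seed = deriveSeed(fs, 500L + t))[1, , ]
    }
    list(field = f, imagesA = stackA, imagesB = stackB,
         maskA = groundTruthMask(f, "A"), maskB = groundTruthMask(f, "B"),
         traces = f@traces[, seq_len(Tn), drop = FALSE])
  })
  new("SyntheticDataset", trainA = trainA, trainB = trainB,
      testPaired = testPaired, noise = noise, seed = as.integer(seed),
      metadata = list(fieldSeedsA = seedsA, fieldSeedsB = seedsB,
                      fieldSeedsTest = seedsT))
}

#' @rdname accessors
#' @export
setMethod("cells", "CellField", function(object) object@cells)

#' @rdname accessors
#' @export
setMethod("traces", "CellField", function(object) object@traces)

#' @rdname accessors
#' @export
setMethod("imageSize", "CellField", function(object) object@imageSize)

#' @rdname accessors
#' @export
setMethod("nCells", "CellField", function(object) nrow(object@cells))

setMethod("show", "CellField", function(object) {
  cat(sprintf("CellField: %d cells on %dx%d grid, background %.2f, %d trace frames\n",
              nCells(object), object@imageSize[1], object@imageSize[2],
              object@backgroundLevel, ncol(object@traces)))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(paste0("SyntheticDataset: %d train A, %d train B (unpaired), ",
                     "%d paired test fields, noise sigma %.3f, seed %d\n"),
              length(object@trainA), length(object@trainB),
              length(object@testPaired), object@noise$sigma, object@seed))
})
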
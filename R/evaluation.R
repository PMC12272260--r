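# Evaluation: image-similarity metrics, ROI correspondence, trace
# extraction and dF/F.

#' Image similarity metrics
#'
#' Computes, against a reference image y: root-mean-squared error
#' RMSE = sqrt(mean((x - y)^2)), mean absolute error, peak signal-to-noise
#' ratio PSNR = 10 log10(max(x)^2 / RMSE^2), the structural similarity
#' index from GLOBAL image statistics
#' SSIM = (2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#' ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2)) with
#' C1 = (0.01 L)^2, C2 = (0.03 L)^2 and L the data range of the reference,
#' and the Pearson correlation coefficient. Identical images give
#' rmse = mae = 0, ssim = pcc = 1 and psnr = +Inf. A zero-variance input
#' makes pcc NA (undefined) rather than an error. A windowed SSIM variant
#' (8x8 blocks) is available behind \code{windowedSSIM} for cross-tool
#' comparison; the global form is the default and the one tested.
#'
#' @param x image (array or matrix); the first argument is the estimate
#'   whose max defines the PSNR peak.
#' @param y reference image, same shape.
#' @param windowedSSIM use a sliding 8x8 block mean of local SSIM instead
#'   of global statistics.
#' @return named list(rmse, mae, psnr, ssim, pcc).
#' @examples
#' imageMetrics(matrix(c(0, 1, 1, 1), 2), matrix(1, 2, 2))
#' @export
imageMetrics <- function(x, y, windowedSSIM = FALSE) {
  if (!identical(dim(x), dim(y)) || !length(x))
    stop("x and y must be nonempty and of identical shape")
  xv <- as.numeric(x); yv <- as.numeric(y)
  rmse <- sqrt(mean((xv - yv)^2))
  mae <- mean(abs(xv - yv))
  psnr <- if (rmse == 0) Inf else 10 * log10(max(xv)^2 / rmse^2)
  L <- diff(range(yv))
  if (L == 0) L <- max(abs(yv), 1)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  ssimOf <- function(a, b) {
    mx <- mean(a); my <- mean(b)
    vx <- mean((a - mx)^2); vy <- mean((b - my)^2)
    cxy <- mean((a - mx) * (b - my))
    (2 * mx * my + C1) * (2 * cxy + C2) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  ssim <- if (!windowedSSIM) ssimOf(xv, yv) else {
    xm <- as.matrix(if (is.matrix(x)) x else x[1, , ])
    ym <- as.matrix(if (is.matrix(y)) y else y[1, , ])
    n <- 8L
    vals <- c()
    for (r in seq(1L, max(nrow(xm) - n + 1L, 1L), by = n))
      for (cc in seq(1L, max(ncol(xm) - n + 1L, 1L), by = n)) {
        rr <- r:min(r + n - 1L, nrow(xm)); ccc <- cc:min(cc + n - 1L, ncol(xm))
        vals <- c(vals, ssimOf(xm[rr, ccc], ym[rr, ccc]))
      }
    mean(vals)
  }
  pcc <- if (sd(xv) == 0 || sd(yv) == 0) NA_real_ else cor(xv, yv)
  list(rmse = rmse, mae = mae, psnr = psnr, ssim = ssim, pcc = pcc)
}

#' ROI centroids of a label mask
#'
#' Unweighted centroid (mean pixel coordinate, 0-based, x = column,
#' y = row) of every labelled ROI.
#'
#' @param mask integer label matrix (0 = background).
#' @return data.frame(label, x, y), empty for an empty mask.
#' @export
roiCentroids <- function(mask) {
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs))
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0)))
  idx <- which(mask > 0, arr.ind = TRUE)
  vals <- mask[mask > 0]
  xs <- tapply(idx[, 2] - 1, vals, mean)
  ys <- tapply(idx[, 1] - 1, vals, mean)
  data.frame(label = as.integer(names(xs)), x = as.numeric(xs),
             y = as.numeric(ys))
}

#' Match ROIs between a reference and a translated mask
#'
#' For every reference ROI the translated ROI with the nearest centroid
#' (Euclidean distance) is selected (one-directional matching, reuse
#' allowed); the centroid distance and the IoU of the two single-ROI binary
#' masks are reported, together with total ROI counts per mask. An empty
#' translated mask yields NA distances and IoUs with count 0.
#'
#' @param maskRef,maskTrans integer label matrices of the same shape.
#' @return list(perRoi = data.frame(label, matchLabel, dist, iou),
#'   countRef, countTrans).
#' @export
matchAndScore <- function(maskRef, maskTrans) {
  if (!identical(dim(maskRef), dim(maskTrans)))
    stop("masks must have the same shape")
  cRef <- roiCentroids(maskRef)
  cTr <- roiCentroids(maskTrans)
  if (!nrow(cRef)) {
    return(list(perRoi = data.frame(label = integer(0),
                                    matchLabel = integer(0),
                                    dist = numeric(0), iou = numeric(0)),
                countRef = 0L, countTrans = nrow(cTr)))
  }
  if (!nrow(cTr)) {
    per <- data.frame(label = cRef$label, matchLabel = NA_integer_,
                      dist = NA_real_, iou = NA_real_)
    return(list(perRoi = per, countRef = nrow(cRef), countTrans = 0L))
  }
  per <- lapply(seq_len(nrow(cRef)), function(i) {
    d2 <- (cTr$x - cRef$x[i])^2 + (cTr$y - cRef$y[i])^2
    j <- which.min(d2)
    a <- maskRef == cRef$label[i]
    b <- maskTrans == cTr$label[j]
    inter <- sum(a & b); uni <- sum(a | b)
    data.frame(label = cRef$label[i], matchLabel = cTr$label[j],
               dist = sqrt(d2[j]), iou = inter / uni)
  })
  list(perRoi = do.call(rbind, per), countRef = nrow(cRef),
       countTrans = nrow(cTr))
}

#' Extract per-ROI activity traces from an image stack
#'
#' Mean intensity over each ROI's member pixels, per frame.
#'
#' @param stack T x H x W array (or H x W matrix for a single frame).
#' @param mask integer label matrix matching the spatial dimensions.
#' @return numeric matrix, one row per ROI (rownames = labels), one column
#'   per frame.
#' @export
extractTraces <- function(stack, mask) {
  if (is.matrix(stack)) stack <- array(stack, c(1L, nrow(stack), ncol(stack)))
  d <- dim(stack)
  if (!identical(as.integer(d[2:3]), as.integer(dim(mask))))
    stop("stack spatial dimensions must match the mask")
  labs <- sort(unique(mask[mask > 0]))
  out <- matrix(NA_real_, length(labs), d[1],
                dimnames = list(labs, NULL))
  sel <- mask > 0
  v <- mask[sel]
  for (t in seq_len(d[1])) {
    frame <- stack[t, , ]
    out[, t] <- as.numeric(tapply(frame[sel], v, mean))
  }
  out
}

#' dF/F from a trailing moving-average baseline
#'
#' The baseline at sample n is the trailing moving average of the last k
#' samples (a shrinking window covers the first k - 1 samples); dF/F_n =
#' (p_n - MA_n) / MA_n. Samples whose baseline is <= 0 are masked as NA.
#' \code{invert = TRUE} flips the sign convention to (MA_n - p_n) / MA_n.
#'
#' @param trace numeric vector.
#' @param k window length (>= 1).
#' @param invert flip the sign convention.
#' @return numeric vector of the same length.
#' @examples
#' dff(c(1, 2, 3, 4), k = 2)  # last element: (4 - 3.5) / 3.5
#' @export
dff <- function(trace, k, invert = FALSE) {
  stopifnot(k >= 1)
  n <- length(trace)
  cs <- cumsum(trace)
  ma <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - k + 1L)
    ma[i] <- (cs[i] - if (lo > 1L) cs[lo - 1L] else 0) / (i - lo + 1L)
  }
  out <- (trace - ma) / ma
  if (invert) out <- -out
  out[ma <= 0] <- NA_real_
  out
}

#' Threshold-based instance segmentation of a translated image
#'
#' Simple evaluation-side segmentation: threshold the image (Otsu's method
#' on the intensity histogram by default) and label connected components,
#' discarding specks below \code{minArea}. This supplies label masks for
#' ROI correspondence scoring where no trained segmentation model is in
#' play.
#'
#' @param img H x W matrix or 1 x H x W array.
#' @param threshold intensity cutoff; NULL for Otsu.
#' @param minArea minimum component size in pixels.
#' @return integer label matrix.
#' @export
segmentLabels <- function(img, threshold = NULL, minArea = 5L) {
  m <- if (is.matrix(img)) img else img[1, , ]
  if (is.null(threshold)) {
    rng <- range(m)
    if (diff(rng) <= 0) return(matrix(0L, nrow(m), ncol(m)))
    scaled <- (m - rng[1]) / diff(rng)
    threshold <- rng[1] + diff(rng) *
      as.numeric(EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)))
  }
  bw <- m > threshold
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(m), ncol(m))
  if (minArea > 1L) {
    tab <- table(lab[lab > 0])
    drop <- as.integer(names(tab)[tab < minArea])
    if (length(drop)) lab[lab %in% drop] <- 0L
    labs <- sort(unique(lab[lab > 0]))
    if (length(labs)) lab[] <- match(lab, labs, nomatch = 0L)
  }
  lab
}

#' ROI-correspondence evaluation of a trained model on a paired test set
#'
#' Translates each domain-A test frame, segments the translation, and
#' scores it against the ground-truth domain-B label mask: per-ROI centroid
#' distances and IoUs, ROI counts, image metrics against the paired
#' domain-B render, and Pearson correlations between ground-truth traces
#' and traces extracted from the translated stack under the true nuclear
#' mask.
#'
#' @param model a \linkS4class{TranslationModel}.
#' @param testPaired the \code{testPaired} list of a
#'   \linkS4class{SyntheticDataset}.
#' @param config the \linkS4class{TaskConfig} used in training (for input
#'   normalisation).
#' @param frames how many frames per test field to evaluate.
#' @return list(perRoi data.frame, medianDist, medianIoU, tracePcc,
#'   countRef, countTrans, imageMetrics).
#' @export
evaluateTranslation <- function(model, testPaired, config, frames = 3L) {
  norm <- config@normalization
  allRoi <- list()
  cntR <- cntT <- 0L
  imgMet <- list()
  tracePcc <- c()
  for (item in testPaired) {
    Tn <- min(frames, dim(item$imagesA)[1])
    transStack <- array(0, c(dim(item$imagesA)[1], dim(item$imagesA)[2],
                             dim(item$imagesA)[3]))
    for (t in seq_len(dim(item$imagesA)[1])) {
      xa <- percentileNormalize(item$imagesA[t, , ], norm$lo, norm$hi,
                                norm$mode)
      tr <- translate(model, xa, "AtoB")
      transStack[t, , ] <- tr[1, , ]
    }
    for (t in seq_len(Tn)) {
      segTrans <- segmentLabels(transStack[t, , ])
      ms <- matchAndScore(item$maskB, segTrans)
      allRoi[[length(allRoi) + 1L]] <- ms$perRoi
      cntR <- cntR + ms$countRef; cntT <- cntT + ms$countTrans
      yb <- percentileNormalize(item$imagesB[t, , ], norm$lo, norm$hi,
                                norm$mode)
      imgMet[[length(imgMet) + 1L]] <-
        unlist(imageMetrics(transStack[t, , ], yb))
    }
    trTraces <- extractTraces(transStack, item$maskB)
    gt <- item$traces
    for (i in seq_len(nrow(gt))) {
      lab <- as.character(i)
      if (lab %in% rownames(trTraces) && sd(trTraces[lab, ]) > 0 &&
          sd(gt[i, ]) > 0)
        tracePcc <- c(tracePcc, cor(gt[i, ], trTraces[lab, ]))
    }
  }
  perRoi <- do.call(rbind, allRoi)
  # a reference ROI with no translated counterpart counts as an infinitely
  # distant, zero-overlap match rather than being dropped
  dists <- perRoi$dist; dists[is.na(dists)] <- Inf
  ious <- perRoi$iou; ious[is.na(ious)] <- 0
  list(perRoi = perRoi,
       medianDist = median(dists),
       medianIoU = median(ious),
       tracePcc = if (length(tracePcc)) median(tracePcc) else NA_real_,
       countRef = cntR, countTrans = cntT,
       imageMetrics = colMeans(do.call(rbind, imgMet)))
}
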
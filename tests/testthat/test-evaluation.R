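# Evaluation metrics: image similarity, ROI correspondence, traces, dF/F.

test_that("image metrics reproduce hand-derived values and identities", {
  x <- matrix(c(0, 1, 1, 1), 2)
  y <- matrix(1, 2, 2)
  m <- imageMetrics(x, y)
  expect_equal(m$rmse, 0.5)
  expect_equal(m$mae, 0.25)
  expect_equal(m$psnr, 10 * log10(1 / 0.25), tolerance = 1e-12)  # ~6.0206 dB
  # identical images
  set.seed(51)
  r <- matrix(runif(64), 8)
  mi <- imageMetrics(r, r)
  expect_equal(mi$rmse, 0); expect_equal(mi$mae, 0)
  expect_equal(mi$ssim, 1); expect_equal(mi$pcc, 1)
  expect_identical(mi$psnr, Inf)
  # zero-mean anti-correlation
  z <- r - mean(r)
  expect_equal(imageMetrics(z, -z)$pcc, -1)
  # zero-variance input yields an undefined (NA) correlation, not an error
  expect_true(is.na(imageMetrics(matrix(1, 4, 4), r[1:4, 1:4])$pcc))
})

test_that("metric symmetries hold: rmse/mae symmetric, psnr/ssim directional", {
  set.seed(52)
  a <- matrix(runif(64), 8); b <- matrix(runif(64) * 3, 8)
  m1 <- imageMetrics(a, b); m2 <- imageMetrics(b, a)
  expect_equal(m1$rmse, m2$rmse)
  expect_equal(m1$mae, m2$mae)
  expect_false(isTRUE(all.equal(m1$psnr, m2$psnr)))
  # pcc invariant under positive affine rescaling of either argument
  expect_equal(imageMetrics(2 * a + 1, b)$pcc, m1$pcc)
  expect_equal(imageMetrics(a, 0.3 * b - 2)$pcc, m1$pcc)
})

test_that("ROI centroids are unweighted pixel means in (x, y)", {
  mask <- matrix(0L, 10, 10)
  mask[8, 4] <- 1L                    # row 8 (y = 7), col 4 (x = 3)
  mask[1:2, 1:2] <- 2L
  cen <- roiCentroids(mask)
  expect_equal(cen$x[cen$label == 1], 3)
  expect_equal(cen$y[cen$label == 1], 7)
  expect_equal(cen$x[cen$label == 2], 0.5)
  expect_equal(cen$y[cen$label == 2], 0.5)
  expect_equal(nrow(roiCentroids(matrix(0L, 4, 4))), 0)
  # flip equivariance
  flipped <- mask[, ncol(mask):1]
  cf <- roiCentroids(flipped)
  expect_equal(cf$x[cf$label == 1], ncol(mask) - 1 - 3)
})

test_that("nearest-centroid matching reports distances, IoU and counts", {
  ref <- matrix(0L, 8, 8); tr <- matrix(0L, 8, 8)
  ref[1:2, 1:2] <- 1L
  tr[2:3, 1:2] <- 1L                  # shifted one row: overlap 2, union 6
  ms <- matchAndScore(ref, tr)
  expect_equal(ms$perRoi$iou, 1 / 3)
  expect_equal(ms$perRoi$dist, 1)
  expect_equal(ms$countRef, 1L); expect_equal(ms$countTrans, 1L)
  # identical masks: all distances 0, all IoUs 1
  f <- tinyField(3, seed = 61)
  mB <- groundTruthMask(f, "B")
  ms2 <- matchAndScore(mB, mB)
  expect_true(all(ms2$perRoi$dist == 0))
  expect_true(all(ms2$perRoi$iou == 1))
  # disjoint far-apart ROIs: IoU 0 at positive distance
  far <- matrix(0L, 8, 8); far[7:8, 7:8] <- 1L
  ms3 <- matchAndScore(ref, far)
  expect_equal(ms3$perRoi$iou, 0)
  expect_gt(ms3$perRoi$dist, 0)
  # empty translated mask: NA sentinel with count 0
  ms4 <- matchAndScore(ref, matrix(0L, 8, 8))
  expect_true(is.na(ms4$perRoi$dist))
  expect_equal(ms4$countTrans, 0L)
})

test_that("matching on paired synthetic masks recovers the known geometry", {
  f <- tinyField(4, seed = 62)
  mA <- groundTruthMask(f, "A"); mB <- groundTruthMask(f, "B")
  ms <- matchAndScore(mB, mA)
  # shared centres: nuclear-vs-cytosolic centroid distance ~ 0
  expect_lt(max(ms$perRoi$dist), 0.3)
  # IoU equals the analytic area ratio (r_nuc / r_cyto)^2 = 0.25 up to
  # rasterisation
  expect_equal(mean(ms$perRoi$iou), 0.25, tolerance = 0.02)
})

test_that("trace extraction equals a per-frame loop oracle", {
  set.seed(53)
  stack <- array(rnorm(5 * 6 * 6), c(5, 6, 6))
  mask <- matrix(0L, 6, 6); mask[2:3, 2:3] <- 1L; mask[5, 5] <- 2L
  tr <- extractTraces(stack, mask)
  for (t in 1:5) {
    expect_equal(unname(tr["1", t]), mean(stack[t, 2:3, 2:3]))
    expect_equal(unname(tr["2", t]), stack[t, 5, 5])  # one-pixel ROI: raw series
  }
  # constant stack gives constant traces
  cst <- array(2.5, c(3, 6, 6))
  expect_true(all(extractTraces(cst, mask) == 2.5))
})

test_that("dF/F uses a trailing shrinking-window moving-average baseline", {
  expect_true(all(dff(rep(4, 10), k = 3) == 0))
  d <- dff(c(1, 2, 3, 4), k = 2)
  expect_equal(d[4], (4 - 3.5) / 3.5)          # MA over the last 2 samples
  expect_equal(d[1], 0)                        # shrinking window: MA = p_1
  # k = length: baseline is the full prefix mean
  p <- c(2, 4, 6, 8)
  dk <- dff(p, k = 4)
  expect_equal(dk[4], (8 - mean(p)) / mean(p))
  expect_equal(dk[2], (4 - 3) / 3)
  # nonpositive baseline is masked, and the sign flag inverts
  expect_true(is.na(dff(c(-1, 1, 1), k = 1)[1]))
  expect_equal(dff(c(1, 2, 3, 4), k = 2, invert = TRUE), -d)
})

test_that("threshold segmentation recovers synthetic nuclei", {
  f <- tinyField(4, seed = 63)
  img <- renderField(f, 2, "B")
  seg <- segmentLabels(img)
  expect_equal(max(seg), 4L)
  ms <- matchAndScore(groundTruthMask(f, "B"), seg)
  expect_lt(median(ms$perRoi$dist), 1.5)
  # flat image: nothing to segment
  expect_equal(max(segmentLabels(matrix(0.2, 32, 32))), 0L)
})
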
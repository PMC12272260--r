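# Synthetic two-domain generator: geometry, traces, rendering structure,
# masks and determinism.

test_that("cell field generation respects geometry and determinism", {
  f <- generateCellField(5, c(64L, 64L), seed = 7)
  expect_s4_class(f, "CellField")
  expect_equal(nCells(f), 5L)
  cl <- cells(f)
  expect_true(all(cl$rNuc < cl$rCyto))
  d <- as.matrix(dist(cl[, c("x", "y")])); diag(d) <- Inf
  expect_gte(min(d), f@minSeparation)
  # same seed twice -> identical fields
  f2 <- generateCellField(5, c(64L, 64L), seed = 7)
  expect_identical(cells(f), cells(f2))
  # empty case renders to pure background
  f0 <- generateCellField(0, c(64L, 64L), seed = 1)
  img <- renderField(f0, domain = "A")
  expect_true(all(img == f0@backgroundLevel))
  f0@backgroundLevel <- 0
  expect_true(all(renderField(f0, domain = "B") == 0))
})

test_that("infeasible packings are rejected, not silently truncated", {
  # 20 cells with min separation 16 cannot pack into 64x64
  expect_error(generateCellField(20, c(64L, 64L), seed = 1),
               "packing infeasible")
  # a merely crowded request fails after bounded rejection attempts
  expect_error(generateCellField(8, c(64L, 64L), seed = 1,
                                 maxAttempts = 50L),
               "packing infeasible")
})

test_that("traces are exponential-kernel spike convolutions on a baseline", {
  f <- generateCellField(1, c(64L, 64L), seed = 3)
  # no events -> constant baseline
  f0 <- simulateTraces(f, T = 50, spikeRate = 0, baseline = 0.3, seed = 1)
  expect_true(all(traces(f0) == 0.3))
  # deconvolve with the AR(1) structure of the exponential kernel: between
  # spikes the trace decays exactly by exp(-1/tau) toward the baseline
  tau <- 5; base <- 0.3
  ft <- simulateTraces(f, T = 1000, spikeRate = 0.1, decayTau = tau,
                       baseline = base, seed = 42)
  tr <- traces(ft)[1, ]
  expect_true(all(tr >= base - 1e-12))
  resid <- tr - base
  spikes <- c(resid[1], resid[-1] - exp(-1 / tau) * resid[-length(resid)])
  expect_true(all(spikes > -1e-8))
  # where no spike fell, the decay relation holds exactly (monotone decay)
  quiet <- which(abs(spikes) < 1e-8)[-1]
  expect_true(all(resid[quiet] <= resid[quiet - 1] + 1e-12))
  # Poisson count within 3 sigma of rate * T = 100
  count <- sum(round(spikes) >= 1 | spikes > 0.5)
  expect_lt(abs(sum(round(spikes)) - 100), 3 * sqrt(100))
})

test_that("renders are anti-monotonic at pixel level, monotonic at cell level", {
  f <- tinyField(4, seed = 21)
  imgA <- renderField(f, 3, "A")[1, , ]
  imgB <- renderField(f, 3, "B")[1, , ]
  cl <- cells(f)
  for (i in seq_len(nrow(cl))) {
    cy <- round(cl$y[i]) + 1L; cx <- round(cl$x[i]) + 1L
    rimx <- cx + round(cl$rCyto[i]) - 1L   # pixel at radius r_cyto - 1
    # centre: A dim, B bright; rim: A brighter than B
    expect_lt(imgA[cy, cx], imgB[cy, cx])
    expect_gt(imgA[cy, rimx], imgB[cy, rimx])
    # rank order reversed between centre and rim within the cell
    expect_gt(imgA[cy, rimx], imgA[cy, cx])
    expect_lt(imgB[cy, rimx], imgB[cy, cx])
  }
  # cell-level monotone linear relationship: per-cell means correlate at 1
  maskA <- groundTruthMask(f, "A"); maskB <- groundTruthMask(f, "B")
  meansA <- vapply(seq_len(nCells(f)), function(i) mean(imgA[maskA == i]), 1)
  meansB <- vapply(seq_len(nCells(f)), function(i) mean(imgB[maskB == i]), 1)
  expect_equal(cor(meansA, meansB), 1, tolerance = 1e-9)
})

test_that("ground-truth masks cover the expected footprints", {
  f1 <- generateCellField(1, c(64L, 64L), seed = 5)
  mA <- groundTruthMask(f1, "A"); mB <- groundTruthMask(f1, "B")
  expect_equal(sort(unique(as.vector(mA))), c(0L, 1L))
  # nuclear disk area within 10% of pi * r^2 for r = 4
  expect_lt(abs(sum(mB == 1) - pi * 16) / (pi * 16), 0.10)
  # nuclear mask strictly inside cytosolic mask
  expect_true(all(mA[mB > 0] > 0))
  # multi-cell: overlap assignment keeps every label nonempty
  f <- tinyField(4, seed = 33)
  mA4 <- groundTruthMask(f, "A")
  expect_setequal(unique(as.vector(mA4[mA4 > 0])), 1:4)
})

test_that("datasets are unpaired by construction and seed-deterministic", {
  ds <- makeSyntheticDataset(nTrainA = 4, nTrainB = 4, nTestFields = 2,
                             testFrames = 3, seed = 9)
  expect_length(intersect(ds@metadata$fieldSeedsA, ds@metadata$fieldSeedsB), 0)
  ds2 <- makeSyntheticDataset(nTrainA = 4, nTrainB = 4, nTestFields = 2,
                              testFrames = 3, seed = 9)
  expect_identical(ds@trainA, ds2@trainA)
  expect_identical(ds@testPaired[[1]]$imagesB, ds2@testPaired[[1]]$imagesB)
  # paired test items share one field between domains
  item <- ds@testPaired[[1]]
  expect_identical(dim(item$imagesA), dim(item$imagesB))
  expect_true(all(item$maskB[item$maskB > 0] <= nCells(item$field)))
  # validity refuses overlapping splits
  bad <- ds
  expect_error({
    bad@metadata$fieldSeedsB[1] <- bad@metadata$fieldSeedsA[1]
    validObject(bad)
  }, "disjoint")
})
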
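# Data pipeline (normalisation, patch sampling, augmentation) and the
# optimisation loop.

test_that("percentile normalisation matches its interpolation oracle", {
  m <- matrix(0:99, 10)
  n <- percentileNormalize(m, 0, 100)
  expect_equal(range(n), c(0, 1))
  # constant image maps to zeros, both modes
  expect_true(all(percentileNormalize(matrix(3, 4, 4), 0.1, 99.9) == 0))
  expect_true(all(percentileNormalize(matrix(0, 4, 4), hi = 99,
                                      mode = "scale") == 0))
  # scale-only: values 0..999, 99th percentile by linear interpolation
  v <- matrix(0:999, 50)
  h <- 0.99 * 999 + 1                       # type-7 position
  p99 <- floor(h) - 1 + (h - floor(h))      # value on the 0..999 grid
  expect_equal(p99, 989.01)
  s <- percentileNormalize(v, hi = 99, mode = "scale")
  expect_equal(max(s), 999 / 989.01, tolerance = 1e-12)
  # affine subtracts the low percentile
  a <- percentileNormalize(v, 10, 90)
  expect_equal(a[1], (0 - quantile(0:999, 0.1, names = FALSE)) /
                 diff(quantile(0:999, c(0.1, 0.9), names = FALSE)))
})

test_that("patch sampling is seeded, bounded and uniform", {
  stack <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
  # exact-size patch returns a whole frame regardless of seed
  p <- samplePatch(stack, c(8, 8), seed = 99)
  expect_true(any(vapply(1:3, function(f) identical(p, stack[f, , ]), TRUE)))
  expect_identical(samplePatch(stack, c(5, 5), seed = 7),
                   samplePatch(stack, c(5, 5), seed = 7))
  expect_error(samplePatch(stack, c(9, 9), seed = 1), "smaller")
  # corner distribution uniform over a 4x4 grid of positions
  big <- array(0, c(1, 7, 7))
  for (r in 1:7) for (cc in 1:7) big[1, r, cc] <- (r - 1) * 7 + (cc - 1)
  counts <- matrix(0, 4, 4)
  set.seed(31)
  for (i in 1:4000) {
    pt <- samplePatch(big, c(4, 4))
    corner <- pt[1, 1]
    counts[corner %/% 7 + 1, corner %% 7 + 1] <-
      counts[corner %/% 7 + 1, corner %% 7 + 1] + 1
  }
  chi <- sum((counts - 250)^2 / 250)
  expect_lt(chi, qchisq(0.999, 15))
})

test_that("dihedral augmentation is an invertible isometry", {
  set.seed(32)
  m <- matrix(rnorm(64), 8, 8)
  # identity draw leaves the patch unchanged
  id <- augmentPatch(m, draw = list(k = 0, flipH = FALSE, flipV = FALSE))
  expect_equal(unname(id[, ]), m, ignore_attr = TRUE)
  for (i in 1:10) {
    a <- augmentPatch(m, seed = i)
    expect_equal(sort(as.vector(a)), sort(as.vector(m)))   # isometry
    back <- invertAugment(a)
    expect_equal(back, m, ignore_attr = TRUE)              # exact inverse
  }
  # channelwise application on C x H x W arrays
  arr <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  aa <- augmentPatch(arr, draw = list(k = 1, flipH = FALSE, flipV = FALSE))
  expect_equal(aa[2, , ], InfoCycle:::rot90cw(arr[2, , ]))
})

test_that("short training runs complete, log every iteration and are seeded", {
  cfg <- tinyConfig()
  imgsA <- tinyImages(5, seed = 2)
  imgsB <- tinyImages(5, seed = 3)
  res <- trainModel(cfg, imgsA, imgsB, iterations = 10, seed = 17)
  expect_equal(nrow(res$log), 10)
  expect_true(all(is.finite(res$log$lossG)))
  expect_equal(res$model@iteration, 10L)
  # identical seeds reproduce the loss log exactly
  res2 <- trainModel(cfg, imgsA, imgsB, iterations = 10, seed = 17)
  expect_identical(res$log, res2$log)
  # a different seed gives a different trajectory
  res3 <- trainModel(cfg, imgsA, imgsB, iterations = 10, seed = 18)
  expect_false(identical(res$log$lossG, res3$log$lossG))
  # resuming from the returned state reproduces the trajectory exactly
  h1 <- trainModel(cfg, imgsA, imgsB, iterations = 5, seed = 17)
  h2 <- trainModel(cfg, imgsA, imgsB, iterations = 5, seed = 17,
                   model = h1$model, state = h1$state)
  expect_identical(unname(as.matrix(h2$log[, -1])),
                   unname(as.matrix(res$log[6:10, -1])))
})

test_that("ablation and schedule toggles act on the training loop", {
  imgsA <- tinyImages(4, seed = 4)
  imgsB <- tinyImages(4, seed = 5)
  # info loss off: the logged info component is identically zero
  cfgOff <- tinyConfig(info_loss = FALSE)
  resOff <- trainModel(cfgOff, imgsA, imgsB, iterations = 4, seed = 1)
  expect_true(all(resOff$log$lossInfo == 0))
  # bilinear-upsampler ablation: no offset parameters exist, training runs
  cfgBil <- tinyConfig(upsampler = "bilinear")
  expect_false(any(grepl("off\\.", names(
    buildModel(cfgBil@spec, 1)@params$encA$params))))
  resBil <- trainModel(cfgBil, imgsA, imgsB, iterations = 3, seed = 1)
  expect_equal(nrow(resBil$log), 3)
  # sigmoid schedule shows up in the logged effective cycle weight
  cfgSch <- tinyConfig(schedule = list(enabled = TRUE, k = 10, m = 0.5))
  resSch <- trainModel(cfgSch, imgsA, imgsB, iterations = 4, seed = 1)
  expect_equal(resSch$log$cycWeight,
               vapply(1:4, function(i)
                 cycleWeight(list(enabled = TRUE, k = 10, m = 0.5), i, 4,
                             cfgSch@lambdaCyc), 1))
  expect_true(all(diff(resSch$log$cycWeight) > 0))
})

test_that("non-finite losses abort with a diagnostic", {
  cfg <- tinyConfig()
  m <- buildModel(cfg@spec, 1)
  m@params$encA$params[["final.W"]][1] <- NaN
  opt <- list(encA = InfoCycle:::adamwInit(m@params$encA$params),
              encB = InfoCycle:::adamwInit(m@params$encB$params),
              decA = InfoCycle:::adamwInit(m@params$decA$params),
              decB = InfoCycle:::adamwInit(m@params$decB$params),
              discA = InfoCycle:::adamwInit(m@params$discA$params),
              discB = InfoCycle:::adamwInit(m@params$discB$params))
  xA <- array(runif(32 * 32), c(1, 32, 32))
  expect_error(InfoCycle:::trainStep(m@params, opt, xA, xA, cfg, 1),
               "non-finite loss")
})

test_that("checkpointing keeps a rolling window plus the best model", {
  cfg <- tinyConfig()
  cfg@checkpointEvery <- 2L
  dir <- file.path(tempdir(), "ckpt-test")
  unlink(dir, recursive = TRUE)
  res <- trainModel(cfg, tinyImages(3, seed = 6), tinyImages(3, seed = 7),
                    iterations = 10, seed = 2, checkpointDir = dir,
                    logFile = file.path(tempdir(), "log.jsonl"))
  files <- list.files(dir)
  expect_lte(sum(grepl("^iter", files)), 3L)
  expect_true("best.rds" %in% files)
  expect_true("final.rds" %in% files)
  fin <- loadCheckpoint(file.path(dir, "final.rds"))
  expect_equal(fin@iteration, 10L)
  # the JSONL log has one row per iteration
  expect_length(readLines(file.path(tempdir(), "log.jsonl")), 10L)
})
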
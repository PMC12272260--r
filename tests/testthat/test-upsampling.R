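# Dynamic upsampling operator: grids, pixel shuffle, offset prediction,
# bilinear sampling and the composed operator.

test_that("uniform grids follow the pixel-centre convention", {
  # s = 1 is the identity grid
  g <- makeUniformGrid(3, 4, 1)
  expect_equal(g[1, 2, 3], 2)  # x = column index (0-based)
  expect_equal(g[2, 2, 3], 1)  # y = row index
  # 1x1 input at s = 2: four positions at +/- 0.25
  g2 <- makeUniformGrid(1, 1, 2)
  expect_equal(sort(unique(as.vector(g2))), c(-0.25, 0.25))
  # spacing exactly 1/s along each axis
  g4 <- makeUniformGrid(2, 2, 4)
  expect_equal(unique(diff(g4[1, 1, ])), 1 / 4)
  expect_equal(unique(diff(g4[2, , 1])), 1 / 4)
})

test_that("pixel shuffle rearranges channels into space bijectively", {
  x <- array(rnorm(8 * 3 * 3), c(8, 3, 3))
  y <- pixelShuffle(x, 2)
  expect_equal(dim(y), c(2L, 6L, 6L))
  expect_equal(sort(as.vector(y)), sort(as.vector(x)))
  expect_identical(pixelShuffle(x, 1), x)
  expect_equal(InfoCycle:::pixelUnshuffle(y, 2), x)
  # channel c s^2 + i s + j lands at (h s + i, w s + j)
  expect_equal(y[1, 1, 2], x[2, 1, 1])  # i = 0, j = 1
  expect_equal(y[2, 2, 1], x[7, 1, 1])  # c = 1, i = 1, j = 0
  expect_error(pixelShuffle(array(0, c(6, 2, 2)), 2), "divisible")
})

test_that("offset prediction is a 1x1 conv followed by pixel shuffle", {
  x <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  thZero <- list(W = matrix(0, 3, 8), b = numeric(8))
  expect_true(all(predictOffsets(x, thZero, 2) == 0))
  th <- list(W = matrix(rnorm(24), 3, 8), b = rnorm(8))
  off <- predictOffsets(x, th, 2)
  expect_equal(dim(off), c(2L, 8L, 10L))
  # constant input: the 1x1 conv is translation invariant, so after pixel
  # shuffle each s-strided sublattice of the offset grid is constant
  xc <- array(rep(c(1, -2, 0.5), 4 * 5), c(3, 4, 5))
  offc <- predictOffsets(xc, th, 2)
  for (ch in 1:2) for (i in 1:2) for (j in 1:2) {
    sub <- offc[ch, seq(i, 8, 2), seq(j, 10, 2)]
    expect_equal(diff(range(sub)), 0, tolerance = 1e-12)
  }
  expect_error(predictOffsets(x, list(W = matrix(0, 2, 8), b = numeric(8)), 2),
               "channels")
})

test_that("bilinear grid sampling interpolates and clamps", {
  x <- array(c(0, 2, 1, 3), c(1, 2, 2))   # rows y, cols x: [[0,1],[2,3]]
  S <- array(c(0.5, 0.5), c(2, 1, 1))
  expect_equal(gridSampleBilinear(x, S)[1, 1, 1], 1.5)
  # integer knots return exact values
  Sk <- array(0, c(2, 2, 2))
  Sk[1, , ] <- matrix(c(0, 1, 0, 1), 2)   # x coords
  Sk[2, , ] <- matrix(c(0, 0, 1, 1), 2)   # y coords
  # output (u, v) samples X at (x, y) = (Sk[1,u,v], Sk[2,u,v])
  expect_equal(gridSampleBilinear(x, Sk)[1, , ], matrix(c(0, 1, 2, 3), 2))
  # constant input -> constant output for any grid, even out of range
  xc <- array(5, c(2, 3, 3))
  Sr <- array(rnorm(2 * 4 * 4, sd = 5), c(2, 4, 4))
  expect_true(all(gridSampleBilinear(xc, Sr) == 5))
  # clamping: far-out positions return border values
  Sfar <- array(c(100, 100), c(2, 1, 1))
  expect_equal(gridSampleBilinear(x, Sfar)[1, 1, 1], 3)
})

test_that("zero-offset dynamic upsampling equals an independent bilinear oracle", {
  set.seed(40)
  for (rep in 1:8) {
    C <- sample(1:3, 1); H <- sample(3:8, 1); W <- sample(3:8, 1)
    s <- sample(c(1L, 2L, 4L), 1)
    x <- array(rnorm(C * H * W), c(C, H, W))
    th <- list(W = matrix(0, C, 2 * s * s), b = numeric(2 * s * s))
    got <- dynamicUpsample(x, th, s)
    expect_equal(dim(got), c(C, H * s, W * s))
    expect_lt(max(abs(got - naiveBilinearResize(x, s))), 1e-10)
  }
  # s = 1 with zero offsets is the identity
  x <- array(rnorm(2 * 5 * 5), c(2, 5, 5))
  th1 <- list(W = matrix(0, 2, 2), b = numeric(2))
  expect_equal(dynamicUpsample(x, th1, 1), x)
})

test_that("the operator is differentiable in offsets and input", {
  set.seed(41)
  # use a smooth interior configuration: small nonzero offsets keep all
  # sampling positions away from integers and borders
  x <- array(rnorm(2 * 6 * 6), c(2, 6, 6))
  th <- list(W = matrix(rnorm(16, sd = 0.01), 2, 8), b = rnorm(8, sd = 0.01))
  wfix <- array(rnorm(2 * 12 * 12), c(2, 12, 12))
  fwd <- InfoCycle:::dynUpForward(x, th, 2L)
  bk <- InfoCycle:::dynUpBackward(wfix, fwd$cache, th)
  lossW <- function(w) {
    sum(InfoCycle:::dynUpForward(x, list(W = w, b = th$b), 2L)$y * wfix)
  }
  expect_lt(relGradErr(lossW, th$W, bk$dW, sample(length(th$W), 6), 1e-6), 1e-3)
  lossX <- function(xx) sum(InfoCycle:::dynUpForward(xx, th, 2L)$y * wfix)
  expect_lt(relGradErr(lossX, x, bk$dx, sample(length(x), 6), 1e-6), 1e-3)
  # gradient w.r.t. offsets is nonzero for non-constant input
  expect_gt(max(abs(bk$dW)), 0)
})
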
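# Translation networks: full-resolution contract, composition, the
# discriminator, modulation/demodulation, parameter counts and gradients.

test_that("encoders keep full spatial resolution across configurations", {
  x <- array(rnorm(32 * 32), c(1, 32, 32))
  for (bn in c(FALSE, TRUE)) for (up in c("dynamic", "bilinear")) {
    spec <- tinySpec(useBatchNorm = bn, upsampler = up)
    m <- buildModel(spec, seed = 2)
    z <- encode(m, x, "A")
    expect_equal(dim(z), c(2L, 32L, 32L))
    out <- decode(m, z, "B")
    expect_equal(dim(out), c(1L, 32L, 32L))
  }
  # modulated variant
  mm <- buildModel(tinySpec(useModulation = TRUE), seed = 2)
  expect_equal(dim(encode(mm, x, "B")), c(2L, 32L, 32L))
})

test_that("non-divisible sizes error with padding guidance; translate pads", {
  m <- buildModel(tinySpec(), seed = 1)
  bad <- array(0, c(1, 33, 33))
  expect_error(encode(m, bad, "A"), "divisible")
  expect_error(encode(m, bad, "A"), "pad")
  # translate() pads reflectively and crops back
  out <- translate(m, bad, "AtoB")
  expect_equal(dim(out), c(1L, 33L, 33L))
})

test_that("translation is a deterministic encoder-decoder composition", {
  m <- buildModel(tinySpec(), seed = 3)
  x <- array(runif(32 * 32), c(1, 32, 32))
  t1 <- translate(m, x, "AtoB")
  t2 <- translate(m, x, "AtoB")
  expect_identical(t1, t2)
  expect_equal(t1, decode(m, encode(m, x, "A"), "B"))
  # the cycle path is well-typed: B -> A on the translation
  cyc <- translate(m, t1, "BtoA")
  expect_equal(dim(cyc), dim(x))
})

test_that("discriminators emit reduced single-channel unbounded score maps", {
  m <- buildModel(tinySpec(), seed = 4)
  x <- array(rnorm(32 * 32), c(1, 32, 32))
  s <- discriminate(m, x, "A")
  expect_equal(dim(s)[1], 1L)
  expect_lt(dim(s)[2], 32L)
  expect_identical(s, discriminate(m, x, "A"))
  # least-squares scores are raw reals: scaling the input escapes [0, 1]
  sBig <- discriminate(m, x * 500, "A")
  expect_true(any(sBig < 0 | sBig > 1))
})

test_that("weight modulation/demodulation normalises filters and cancels scale", {
  set.seed(9)
  W <- matrix(rnorm(3 * 9 * 4), 27, 4)
  sc <- runif(3, 0.5, 2)
  Wd <- modulateDemodulate(W, sc)
  expect_equal(unname(sqrt(colSums(Wd^2))), rep(1, 4), tolerance = 1e-6)
  # all scales 1 on already unit-norm filters is (near) identity
  Wu <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  expect_equal(modulateDemodulate(Wu, rep(1, 3)), Wu, tolerance = 1e-6)
  # multiplying all scales by a common factor changes nothing
  expect_equal(modulateDemodulate(W, sc * 2), Wd, tolerance = 1e-9)
  # 4-d array form round-trips the shape
  W4 <- array(rnorm(3 * 3 * 2 * 5), c(3, 3, 2, 5))
  out4 <- modulateDemodulate(W4, c(1.3, 0.7))
  expect_equal(dim(out4), dim(W4))
})

test_that("parameter counts are fixed functions of the spec", {
  m <- buildModel(translationSpec(), seed = 1)
  expect_identical(unname(parameterCount(m)),
                   c(30080L, 30080L, 30521L, 30521L, 2759105L, 2759105L))
  # batch norm and modulation add their parameters
  mb <- buildModel(tinySpec(useBatchNorm = TRUE), seed = 1)
  mp <- buildModel(tinySpec(), seed = 1)
  expect_gt(parameterCount(mb)[["encA"]], parameterCount(mp)[["encA"]])
})

test_that("a zero-weight network is the bias field", {
  spec <- tinySpec()
  m <- buildModel(spec, seed = 6)
  net <- m@params$encA
  net$params <- lapply(net$params, function(p) p * 0)
  net$params[["final.b"]] <- rep(0.7, 2)
  x <- array(rnorm(32 * 32), c(1, 32, 32))
  out <- InfoCycle:::unetForward(net, x)$y
  expect_true(all(abs(out - 0.7) < 1e-12))
})

test_that("network gradients agree with finite differences", {
  set.seed(12)
  x <- array(rnorm(16 * 16), c(1, 16, 16))
  for (variant in list(list(bn = FALSE, mod = FALSE),
                       list(bn = TRUE, mod = FALSE),
                       list(bn = FALSE, mod = TRUE))) {
    net <- InfoCycle:::unetInit(1, 2, c(3L, 5L), bn = variant$bn,
                                mod = variant$mod)
    wfix <- array(rnorm(2 * 16 * 16), c(2, 16, 16))
    f <- InfoCycle:::unetForward(net, x, train = TRUE, keepCache = TRUE)
    bk <- InfoCycle:::unetBackward(net, f$st, wfix)
    lossOf <- function(nm) function(v) {
      n2 <- net; n2$params[[nm]] <- v
      sum(InfoCycle:::unetForward(n2, x, train = TRUE)$y * wfix)
    }
    for (nm in sample(names(net$params), 6)) {
      if (grepl("\\.(rm|rv)$", nm)) next   # running stats are not trained
      # a conv bias directly followed by batch norm has exactly zero
      # effect (the mean subtraction absorbs it): nothing to compare
      if (variant$bn && grepl("c[12]\\.b$", nm)) next
      g <- bk$grads[[nm]]
      expect_false(is.null(g), info = nm)
      err <- relGradErr(lossOf(nm), net$params[[nm]], g,
                        sample(length(g), min(3, length(g))))
      expect_lt(err, 1e-3)
    }
  }
  # discriminator parameters and input
  dn <- InfoCycle:::discInit(1, c(3L, 4L), bn = FALSE)
  f <- InfoCycle:::discForward(dn, x, train = TRUE, keepCache = TRUE)
  wd <- array(rnorm(length(f$y)), dim(f$y))
  bk <- InfoCycle:::discBackward(dn, f$st, wd)
  for (nm in names(dn$params)) {
    lossOf <- function(v) {
      d2 <- dn; d2$params[[nm]] <- v
      sum(InfoCycle:::discForward(d2, x)$y * wd)
    }
    err <- relGradErr(lossOf, dn$params[[nm]], bk$grads[[nm]],
                      sample(length(dn$params[[nm]]),
                             min(2L, length(dn$params[[nm]]))))
    expect_lt(err, 1e-3)
  }
})

test_that("checkpoints round-trip and reject mismatched specs", {
  m <- buildModel(tinySpec(), seed = 8)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(m, path)
  m2 <- loadCheckpoint(path, expectedSpec = m@spec)
  x <- array(runif(32 * 32), c(1, 32, 32))
  expect_identical(translate(m, x, "AtoB"), translate(m2, x, "AtoB"))
  expect_error(loadCheckpoint(path, expectedSpec = tinySpec(cz = 3L)),
               "spec")
})
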
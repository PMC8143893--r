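test_that("initial level set is piecewise +rho / 0 / -rho at the border", {
  cfg <- segmentationConfig(borderMargin = 5L, rho = 2)
  st <- initializeLevelSet(c(100, 100), cfg)
  expect_equal(sum(st$phi == 2), 88 * 88)
  expect_equal(sum(st$phi == 0), 90 * 90 - 88 * 88)
  expect_equal(sum(st$phi == -2), 100 * 100 - 90 * 90)
  expect_identical(st$mask, matrix(as.numeric(st$phi > 0), 100, 100))
  expect_error(segmentationConfig(rho = 0), "rho")
  expect_error(initializeLevelSet(c(8, 8), cfg), "too small")
})

test_that("smoothed Heaviside and Dirac obey their closed forms", {
  expect_equal(heavisideEps(0, 1.5), 0.5)
  z <- seq(-4, 4, by = 0.37)
  expect_equal(heavisideEps(z, 2) + heavisideEps(-z, 2), rep(1, length(z)))
  expect_equal(heavisideEps(1, 1), 0.75)
  expect_error(heavisideEps(1, 0), "epsilon")

  expect_equal(diracEps(0, 1.5), 1 / (pi * 1.5))
  expect_equal(diracEps(z, 1.2), diracEps(-z, 1.2))
  quad <- stats::integrate(function(x) diracEps(x, 1.5), -1000, 1000)
  expect_equal(quad$value, 1, tolerance = 1e-3)
  expect_error(diracEps(1, -1), "epsilon")
})

test_that("region means, fitted image and SPF match brute-force oracles", {
  set.seed(11)
  for (rep in 1:5) {
    img <- matrix(runif(64, 0, 255), 8, 8)
    phi <- matrix(runif(64, -3, 3), 8, 8)
    M <- matrix(rbinom(64, 1, 0.7), 8, 8)
    eps <- runif(1, 0.5, 3)
    st <- lesionDx:::levelSetState(phi)
    rm <- regionMeans(img, st, eps, regionMask = M)
    ref <- oracleRegionMeans(img, phi, M, eps)
    expect_equal(rm$c1, unname(ref["c1"]), tolerance = 1e-10)
    expect_equal(rm$c2, unname(ref["c2"]), tolerance = 1e-10)

    fit <- globalFittedImage(rm$c1, rm$c2, st, eps)
    expect_equal(fit, oracleFittedImage(rm$c1, rm$c2, phi, eps),
                 tolerance = 1e-10)

    spf <- spfField(img, fit, st$mask)
    expect_equal(spf, oracleSpf(img, fit, st$mask), tolerance = 1e-10)
  }
})

test_that("region means behave on constant and two-level images", {
  img <- matrix(100, 10, 10)
  st <- lesionDx:::levelSetState(matrix(c(-1, 1), 10, 10))
  rm <- regionMeans(img, st, 1.5)
  expect_equal(rm$c1, 100)
  expect_equal(rm$c2, 100)

  # sharp-Heaviside limit on a two-level disc
  rr <- outer(1:32, rep(1, 32)) - 16
  cc <- t(outer(1:32, rep(1, 32))) - 16
  disc <- (rr^2 + cc^2 <= 64) * 1
  img2 <- 60 * disc + 180 * (1 - disc)
  st2 <- lesionDx:::levelSetState(2 * disc - 1)
  rm2 <- regionMeans(img2, st2, 1e-9)
  expect_equal(rm2$c1, 60, tolerance = 1e-6)
  expect_equal(rm2$c2, 180, tolerance = 1e-6)
})

test_that("SPF is normalized, mask-gated and zero at zero intensity", {
  img <- matrix(c(0, 50, 120, 200), 2, 2)
  fit <- matrix(90, 2, 2)
  mask <- matrix(1, 2, 2)
  spf <- spfField(img, fit, mask)
  expect_true(all(spf >= -1 & spf <= 1))
  expect_equal(spf[1, 1], 0)                       # I = 0 branch
  expect_equal(spf[2, 2], (200 - 90) / 110)        # attains +1
  expect_equal(spfField(img, img, mask), matrix(0, 2, 2))
  expect_error(spfField(img, fit, matrix(1, 3, 3)), "match")
})

test_that("one evolution step equals an independent finite-difference oracle", {
  set.seed(21)
  cfg <- segmentationConfig(regSigma = 1, maxIter = 5L)
  img <- matrix(runif(36, 0, 255), 6, 6)
  phi <- matrix(runif(36, -2, 2), 6, 6)
  st <- lesionDx:::levelSetState(phi)
  out <- evolveStep(img, st, cfg)
  ref <- oracleEvolveStep(img, phi, st$mask, cfg)
  expect_equal(out$phi, ref, tolerance = 1e-8)
  expect_identical(out$mask, matrix(as.numeric(out$phi > 0), 6, 6))
  expect_identical(out$prevMask, st$mask)
  expect_equal(out$iteration, 1L)

  # zero pressure: constant image gives spf = 0, phi changes only by the
  # regularization smoothing
  cfg0 <- segmentationConfig(regSigma = 0)
  stc <- lesionDx:::levelSetState(phi)
  outc <- evolveStep(matrix(42, 6, 6), stc, cfg0)
  expect_equal(outc$phi, phi)
})

test_that("contour shrinks inward on a dark lesion under the default config", {
  fx <- makeTestLesion(seed = 1, shape = c(96, 96), semiAxes = c(18, 13))
  cfg <- segmentationConfig()
  st <- initializeLevelSet(dim(fx$smooth), cfg)
  counts <- numeric(10)
  for (k in 1:10) {
    st <- evolveStep(fx$smooth, st, cfg)
    counts[k] <- sum(st$mask)
    expect_true(all(st$spf >= -1 & st$spf <= 1))
  }
  expect_true(all(diff(counts) <= 0))
})

test_that("subregion difference is the set difference with its identities", {
  prev <- matrix(1, 10, 10)
  cur <- matrix(0, 10, 10); cur[3:8, 3:8] <- 1
  ring <- subregionDifference(prev, cur)
  expect_equal(sum(ring), 100 - 36)
  expect_identical(lesionDx:::asBinary(ring + cur > 0), prev)   # union
  expect_equal(sum(ring * cur), 0)                              # disjoint
  expect_equal(sum(subregionDifference(cur, cur)), 0)
})

test_that("the pixel-count stop rule fires on similarity", {
  cfg <- segmentationConfig(stopValue = 98)
  prev <- matrix(1, 20, 50)                       # 1000 pixels
  cur981 <- prev; cur981[1, 1:19] <- 0
  cur979 <- prev; cur979[1, 1:21] <- 0
  expect_true(checkStop(prev, cur981, cfg))
  expect_false(checkStop(prev, cur979, cfg))
  expect_true(checkStop(prev, prev, segmentationConfig(stopValue = 100)))
})

test_that("stop-rule intensity gate eliminates near-black pixels", {
  cfg <- segmentationConfig(stopValue = 99, smallValueThreshold = 10)
  prev <- matrix(1, 10, 10)
  cur <- prev; cur[1, 1:5] <- 0
  img <- matrix(200, 10, 10)
  img[1, ] <- 0          # the whole changed row is near-black: ignored
  expect_true(checkStop(prev, cur, cfg, image = img))
  expect_false(checkStop(prev, cur, cfg, image = matrix(200, 10, 10)))
})

test_that("segmentation recovers clean and noisy lesions", {
  fx <- makeTestLesion(seed = 1)
  res <- segmentLesion(fx$smooth)
  expect_true(converged(res))
  expect_gte(diceCoefficient(roiMask(res), fx$mask), 0.95)
  expect_lte(iterations(res), segmentationConfig()$maxIter)
  expect_length(res@c1Trace, iterations(res))

  fxN <- makeTestLesion(seed = 2, noiseSd = 10, irregularity = 0.15,
                        textureContrast = 20)
  resN <- segmentLesion(fxN$smooth)
  expect_gte(diceCoefficient(roiMask(resN), fxN$mask), 0.90)
})

test_that("segmentation always terminates, even on a constant image", {
  res <- segmentLesion(matrix(128, 40, 40),
                       segmentationConfig(maxIter = 40L))
  expect_lte(iterations(res), 40L)
  expect_true(all(roiMask(res) %in% c(0, 1)))
})

test_that("largest connected component filtering keeps one lesion", {
  m <- matrix(0, 20, 20)
  m[2:4, 2:4] <- 1          # 9 px blob
  m[10:16, 10:16] <- 1      # 49 px blob
  lc <- lesionDx:::largestComponent(m)
  expect_equal(sum(lc), 49)
  expect_equal(sum(lc[10:16, 10:16]), 49)
  # 8-connectivity: a diagonal touch joins components
  d <- matrix(0, 5, 5); d[1, 1] <- 1; d[2, 2] <- 1; d[3, 3] <- 1
  expect_equal(sum(lesionDx:::largestComponent(d)), 3)
})
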
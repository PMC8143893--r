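test_that("LBP codes follow the thresholded circular comparison", {
  expect_equal(lbpCode(matrix(5, 3, 3), P = 8, R = 1), 255)
  lo <- matrix(5, 3, 3); lo[2, 2] <- 4
  expect_equal(lbpCode(lo, P = 8, R = 1), 255)
  hi <- matrix(1, 3, 3); hi[2, 2] <- 9
  expect_equal(lbpCode(hi, P = 8, R = 1), 0)
  expect_error(lbpCode(matrix(1, 3, 3), P = 8, R = 2), "window")

  # mixed patches, bit by bit against the loop oracle
  set.seed(31)
  for (rep in 1:10) {
    w <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
    expect_equal(lbpCode(w, P = 8, R = 1), oracleLbpCode(w, 3, 3, 8, 1))
    expect_equal(lbpCode(w, P = 8, R = 2), oracleLbpCode(w, 3, 3, 8, 2))
  }
})

test_that("LBP is invariant to a constant gray offset", {
  set.seed(32)
  img <- matrix(runif(400, 20, 200), 20, 20)
  roi <- matrix(1, 20, 20)
  h1 <- lbpHistogram(img, roi)
  h2 <- lbpHistogram(img + 20, roi)
  expect_identical(h1, h2)
})

test_that("uniform LBP histograms are normalized and match brute force", {
  set.seed(33)
  img <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
  roi <- matrix(rbinom(256, 1, 0.8), 16, 16)
  cfg <- lbpConfig()
  hs <- lbpHistogram(img, roi, cfg)
  expect_named(hs, c("r1", "r2", "r3"))
  for (h in hs) {
    expect_length(h, 59)
    expect_equal(sum(h), 1, tolerance = 1e-12)
  }

  # brute-force recomputation: per-pixel oracle codes, independent
  # transition counting, own binning
  for (R in cfg$radii) {
    hcl <- ceiling(R)
    codes <- c()
    for (i in (hcl + 1):(16 - hcl)) for (j in (hcl + 1):(16 - hcl))
      if (roi[i, j] == 1) codes <- c(codes, oracleLbpCode(img, i, j, 8, R))
    uni <- Filter(function(cd) oracleTransitions(cd) <= 2, 0:255)
    bins <- ifelse(codes %in% uni, match(codes, uni), 59)
    ref <- tabulate(bins, nbins = 59) / length(bins)
    expect_equal(unname(hs[[paste0("r", R)]]), ref, tolerance = 1e-12)
  }

  # constant ROI: all mass in the (uniform) bin of code 255
  flat <- lbpHistogram(matrix(7, 12, 12), matrix(1, 12, 12), cfg)
  for (h in flat) {
    expect_equal(max(h), 1)
    expect_lt(which.max(h), 59)        # 255 is uniform, not the catch-all
  }

  badRoi <- matrix(0, 16, 16); badRoi[1, 1] <- 1
  expect_error(lbpHistogram(img, badRoi, cfg), "radius")
  expect_error(lbpHistogram(img, matrix(0, 16, 16)), "empty")
})

test_that("GLCM counts match brute-force pair enumeration", {
  set.seed(34)
  cfgRaw <- glcmConfig(symmetric = FALSE, normalized = FALSE)
  for (rep in 1:3) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    roi <- matrix(rbinom(64, 1, 0.85), 8, 8)
    for (a in c(0, 45, 90, 135)) for (d in 1:2) {
      got <- tryCatch(glcmMatrix(img, roi, d, a, cfgRaw),
                      error = function(e) NULL)
      ref <- oracleGlcm(img, roi, d, a, 8, symmetric = FALSE,
                        normalized = FALSE)
      if (!is.null(got)) expect_equal(got, ref)
      sym <- glcmMatrix(img, roi, d, a, glcmConfig())
      expect_equal(sym, oracleGlcm(img, roi, d, a, 8), tolerance = 1e-12)
      expect_equal(sum(sym), 1, tolerance = 1e-12)
    }
  }
})

test_that("GLCM of flat and checkerboard images is as enumerated", {
  flat <- glcmMatrix(matrix(100, 6, 6), matrix(1, 6, 6), 1, 0, glcmConfig())
  expect_equal(sum(diag(flat)), 1)
  expect_equal(sum(flat) - sum(diag(flat)), 0)
  expect_equal(flat[4, 4], 1)      # 100 quantizes to level 3 (0-based)

  cb <- (outer(1:4, 1:4, `+`) %% 2) * 255          # 2-level checkerboard
  cbm <- glcmMatrix(cb, matrix(1, 4, 4), 1, 0, glcmConfig(levels = 2L))
  expect_equal(sum(diag(cbm)), 0)                  # all mass off-diagonal
  expect_equal(sum(cbm), 1)

  tiny <- matrix(1, 2, 2)
  expect_error(glcmMatrix(tiny, matrix(0, 2, 2), 1, 0), "ROI|pairs")
})

test_that("the 13 GLCM statistics follow their definitions", {
  single <- matrix(0, 8, 8); single[4, 4] <- 1
  f <- glcmFeatures(single)
  expect_length(f, 13)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["dissimilarity"]), 0)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["homogeneity"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["correlation"]), 0)   # degenerate sigma = 0
  expect_equal(unname(f["smoothness"]), 0)
  expect_equal(unname(f["mean"]), 3)          # level index 3

  m2 <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  f2 <- glcmFeatures(m2)
  expect_equal(unname(f2["energy"]), 0.5)
  expect_equal(unname(f2["entropy"]), 1)
  expect_equal(unname(f2["contrast"]), 0)

  expect_error(glcmFeatures(matrix(1, 2, 2)), "normalized")
})

test_that("angle-averaged symmetric GLCM features ignore transposition", {
  set.seed(35)
  img <- matrix(runif(400, 0, 255), 20, 20)
  roi <- matrix(1, 20, 20)
  f1 <- glcmFeatures(lesionDx:::glcmAveraged(img, roi, 1))
  f2 <- glcmFeatures(lesionDx:::glcmAveraged(t(img), t(roi), 1))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("fusion yields exactly 216 uniquely named stable features", {
  set.seed(36)
  img <- matrix(runif(1024, 0, 255), 32, 32)
  roi <- matrix(1, 32, 32)
  fv <- extractFeatures(img, roi)
  expect_length(fv, 216)
  expect_equal(3 * 59 + 3 * 13, 216)
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extractFeatures(img, roi))     # deterministic

  expect_identical(names(fv)[1], "lbp_r1_bin01")
  expect_identical(names(fv)[216], "glcm_d3_kurtosis")

  # wrong component counts are rejected with a diagnostic
  hs <- lbpHistogram(img, roi)
  gs <- list(d1 = glcmFeatures(lesionDx:::glcmAveraged(img, roi, 1)))
  expect_error(fuseFeatures(hs, gs), "216")
})
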
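test_that("stratified 80/20 split reproduces the protocol counts", {
  lab840 <- rep(paste0("c", 1:7), each = 120)
  sp <- splitDataset(lab840, fraction = 0.8, seed = 4)
  expect_length(sp$train, 672)
  expect_length(sp$test, 168)

  lab120 <- rep(c("cn", "an", "mel"), each = 40)
  sp2 <- splitDataset(lab120, fraction = 0.8, seed = 4)
  expect_length(sp2$train, 96)
  expect_length(sp2$test, 24)
  # per-stratum 32/8
  expect_true(all(table(lab120[sp2$train]) == 32))

  # partition identities and determinism
  expect_identical(sort(c(sp2$train, sp2$test)), seq_along(lab120))
  expect_length(intersect(sp2$train, sp2$test), 0)
  expect_identical(sp2, splitDataset(lab120, fraction = 0.8, seed = 4))
  expect_false(identical(sp2$train,
                         splitDataset(lab120, fraction = 0.8, seed = 5)$train))

  expect_error(splitDataset(c("a", "a", "b"), fraction = 0.8), "fewer than 2")
  expect_error(splitDataset(lab120, fraction = 1.2), "fraction")
})

# small separable feature problem used across classifier tests: two
# synthetic lesion classes with disjoint texture contrast, ground-truth ROIs
makeTwoClassFeatures <- function(nPerClass = 40, seed = 10) {
  specs <- list(
    benign = list(semiAxes = c(12, 18), lesionIntensity = c(95, 115),
                  backgroundIntensity = c(170, 185),
                  textureContrast = c(4, 12), textureScale = 1.2,
                  microContrast = c(6, 9), noiseSd = c(4, 8)),
    malignant = list(semiAxes = c(12, 18), lesionIntensity = c(55, 75),
                     backgroundIntensity = c(170, 185),
                     textureContrast = c(45, 58), textureScale = 4,
                     microContrast = c(1, 3), noiseSd = c(4, 8)))
  ds <- simulateDataset(nPerClass, classSpecs = specs, shape = c(80, 80),
                        seed = seed)
  sm <- lapply(ds, function(li)
    lesionImage(pmin(pmax(smoothImage(imgData(li)), 0), 255),
                maskData(li), imgLabel(li)))
  extractFeatureMatrix(sm)
}

test_that("the MLP separates two well-separated synthetic classes", {
  X <- makeTwoClassFeatures()
  lab <- attr(X, "labels")
  sp <- splitDataset(lab, seed = 2)
  model <- mlpFit(X[sp$train, ], lab[sp$train], trainConfig(seed = 3))
  acc <- mean(mlpPredict(model, X[sp$test, ]) == lab[sp$test])
  expect_gte(acc, 0.95)

  # determinism: identical data + seed -> identical weights
  model2 <- mlpFit(X[sp$train, ], lab[sp$train], trainConfig(seed = 3))
  expect_identical(model@weights, model2@weights)
  expect_identical(model@biases, model2@biases)

  # training loss non-increasing over the first 5 epochs on separable data
  expect_true(all(diff(model@fitInfo$trainLoss[1:5]) <= 0))

  expect_error(mlpFit(X, rep("one", nrow(X))), "2 classes")
  expect_error(mlpFit(X * NA, lab), "non-finite")
})

test_that("probability predictions live on the simplex", {
  X <- makeTwoClassFeatures(nPerClass = 10, seed = 20)
  lab <- attr(X, "labels")
  model <- mlpFit(X, lab, trainConfig(seed = 1, maxEpochs = 50L))
  P <- mlpPredictProba(model, X)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-9)
  expect_true(all(P >= 0))
  expect_identical(colnames(P), model@classes)
  expect_identical(mlpPredict(model, X),
                   model@classes[apply(P, 1, which.max)])
  expect_length(mlpPredict(model, X), nrow(X))
  expect_error(mlpPredictProba(model, X[, 1:10]), "width")
})

test_that("zero weights give uniform probabilities and low-index tie-break", {
  zero <- new("MLPModel", layerSizes = c(4L, 3L, 2L),
              weights = list(matrix(0, 4, 3), matrix(0, 3, 2)),
              biases = list(numeric(3), numeric(2)),
              center = numeric(4), scale = rep(1, 4),
              classes = c("a", "b"), fitInfo = list())
  P <- mlpPredictProba(zero, matrix(rnorm(8), 2, 4))
  expect_equal(unname(P), matrix(0.5, 2, 2))
  expect_identical(mlpPredict(zero, matrix(rnorm(4), 1, 4)), "a")
})

test_that("standardization round-trips to 1e-10", {
  set.seed(7)
  X <- matrix(rnorm(60, 5, 3), 10, 6)
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  Z <- lesionDx:::standardizeFeatures(X, ctr, scl)
  back <- sweep(sweep(Z, 2, scl, "*"), 2, ctr, "+")
  expect_equal(back, X, tolerance = 1e-10)
})

test_that("models survive a JSON save/load round trip", {
  X <- makeTwoClassFeatures(nPerClass = 10, seed = 30)
  lab <- attr(X, "labels")
  model <- mlpFit(X, lab, trainConfig(seed = 2, maxEpochs = 80L))
  path <- withr::local_tempfile(fileext = ".json")
  saveModel(model, path)
  back <- loadModel(path)
  expect_equal(mlpPredictProba(back, X), mlpPredictProba(model, X),
               tolerance = 1e-12)
  expect_identical(back@classes, model@classes)
  expect_identical(back@layerSizes, model@layerSizes)
})

test_that("the MSE loss variant trains", {
  X <- makeTwoClassFeatures(nPerClass = 8, seed = 40)
  lab <- attr(X, "labels")
  m <- mlpFit(X, lab, trainConfig(seed = 1, maxEpochs = 150L, loss = "mse"))
  expect_gte(mean(mlpPredict(m, X) == lab), 0.8)
})
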
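#' Stratified train/test split
#'
#' Shuffles within each class and assigns `round(fraction * n)` samples per
#' stratum to the training set. Deterministic given `seed`.
#'
#' @param labels character or factor vector of class labels.
#' @param fraction training fraction (default 0.8, the 80/20 protocol).
#' @param stratified logical (default TRUE).
#' @param seed integer RNG seed.
#' @return List with integer index vectors `train` and `test` (a partition
#'   of `seq_along(labels)`).
#' @examples
#' sp <- splitDataset(rep(letters[1:3], each = 40))
#' lengths(sp)
#' @export
splitDataset <- function(labels, fraction = 0.8, stratified = TRUE,
                         seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)", call. = FALSE)
  labels <- as.character(labels)
  set.seed(deriveSeed(seed, 0L))
  if (!stratified) {
    idx <- sample(seq_along(labels))
    nTr <- round(fraction * length(labels))
    return(list(train = sort(idx[seq_len(nTr)]),
                test = sort(idx[-seq_len(nTr)])))
  }
  train <- integer(0)
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    if (length(ix) < 2L)
      stop("class '", cl, "' has fewer than 2 samples; cannot stratify",
           call. = FALSE)
    ix <- ix[sample.int(length(ix))]
    train <- c(train, ix[seq_len(round(fraction * length(ix)))])
  }
  list(train = sort(train),
       test = sort(setdiff(seq_along(labels), train)))
}

#' Training configuration for the MLP
#'
#' @param hidden integer vector of hidden-layer widths (default 10, one
#'   hidden layer of 10 logistic units).
#' @param maxEpochs epoch cap (default 1500).
#' @param learningRate fixed gradient-descent step (default 0.05).
#' @param momentum classical momentum coefficient for the gradient steps
#'   (default 0.9; 0 gives plain gradient descent).
#' @param validationFraction fraction of the training data held out
#'   internally for early stopping, in (0, 0.5\] (default 0.15).
#' @param patience consecutive validation checks without improvement before
#'   training halts (default 6).
#' @param checkEvery epochs between validation checks (default 10).
#' @param restarts number of random weight initializations; the run with
#'   the best validation loss is kept (default 3).
#' @param seed integer RNG seed (weight initialization and validation split).
#' @param loss `"cross_entropy"` (default) or `"mse"`.
#' @return List of class `"TrainConfig"`.
#' @export
trainConfig <- function(hidden = 10L, maxEpochs = 1500L, learningRate = 0.05,
                        momentum = 0.9, validationFraction = 0.15,
                        patience = 6L, checkEvery = 10L, restarts = 3L,
                        seed = 1L, loss = c("cross_entropy", "mse")) {
  if (validationFraction <= 0 || validationFraction > 0.5)
    stop("validationFraction must lie in (0, 0.5]", call. = FALSE)
  if (patience < 1L) stop("patience must be >= 1", call. = FALSE)
  if (momentum < 0 || momentum >= 1)
    stop("momentum must lie in [0, 1)", call. = FALSE)
  if (checkEvery < 1L) stop("checkEvery must be >= 1", call. = FALSE)
  if (restarts < 1L) stop("restarts must be >= 1", call. = FALSE)
  structure(list(hidden = as.integer(hidden),
                 maxEpochs = as.integer(maxEpochs),
                 learningRate = learningRate, momentum = momentum,
                 validationFraction = validationFraction,
                 patience = as.integer(patience),
                 checkEvery = as.integer(checkEvery),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 loss = match.arg(loss)),
            class = "TrainConfig")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlpForward <- function(model, X) {
  A <- X
  nL <- length(model@weights)
  acts <- vector("list", nL + 1L)
  acts[[1]] <- A
  for (l in seq_len(nL)) {
    Z <- A %*% model@weights[[l]] +
      matrix(model@biases[[l]], nrow(A), length(model@biases[[l]]),
             byrow = TRUE)
    A <- if (l < nL) sigmoid(Z) else softmaxRows(Z)
    acts[[l + 1L]] <- A
  }
  acts
}

standardizeFeatures <- function(X, center, scale) {
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

mlpLoss <- function(P, Y, loss) {
  if (loss == "mse") mean((P - Y)^2)
  else -mean(rowSums(Y * log(pmax(P, 1e-12))))
}

#' Fit the shallow MLP on hybrid texture features
#'
#' Features are z-score standardized with fit-time parameters; the network
#' (logistic-sigmoid hidden layer(s), softmax readout) is trained with
#' full-batch gradient descent on cross-entropy against one-hot targets. An
#' internal stratified validation holdout drives early stopping: training
#' halts when validation loss has failed to improve for `patience`
#' consecutive checks (one per epoch) or at `maxEpochs`, and the weights of
#' the best validation epoch are kept. Deterministic given the config seed.
#'
#' @param X numeric matrix (samples x 216) of feature vectors.
#' @param labels class label per row (>= 2 classes required).
#' @param cfg a [trainConfig()].
#' @return An [MLPModel-class].
#' @export
mlpFit <- function(X, labels, cfg = trainConfig()) {
  if (!is.matrix(X)) X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("need at least 2 classes to fit", call. = FALSE)
  if (anyNA(X) || !all(is.finite(X)))
    stop("non-finite feature values", call. = FALSE)

  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1       # constant features carry no information
  Xs <- standardizeFeatures(X, center, scale)
  Y <- outer(labels, classes, `==`) * 1

  set.seed(deriveSeed(cfg$seed, 1L))
  # stratified internal validation holdout
  vIdx <- integer(0)
  for (cl in classes) {
    ix <- which(labels == cl)
    nV <- max(1L, round(cfg$validationFraction * length(ix)))
    if (nV >= length(ix)) nV <- length(ix) - 1L
    vIdx <- c(vIdx, ix[sample.int(length(ix))][seq_len(max(nV, 0L))])
  }
  tIdx <- setdiff(seq_len(nrow(Xs)), vIdx)
  Xtr <- Xs[tIdx, , drop = FALSE]; Ytr <- Y[tIdx, , drop = FALSE]
  Xv <- Xs[vIdx, , drop = FALSE]; Yv <- Y[vIdx, , drop = FALSE]

  sizes <- c(ncol(X), cfg$hidden, length(classes))
  nL <- length(sizes) - 1L
  n <- nrow(Xtr)

  model <- new("MLPModel", layerSizes = as.integer(sizes),
               weights = vector("list", nL), biases = vector("list", nL),
               center = center, scale = scale, classes = classes,
               fitInfo = list())

  runOnce <- function() {
    model@weights <- lapply(seq_len(nL), function(l)
      matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, 1 / sqrt(sizes[l])),
             sizes[l], sizes[l + 1]))
    model@biases <- lapply(seq_len(nL), function(l) numeric(sizes[l + 1]))
    vW <- lapply(model@weights, function(w) w * 0)
    vB <- lapply(model@biases, function(b) b * 0)
    best <- list(loss = Inf, W = model@weights, B = model@biases,
                 epoch = 0L)
    badChecks <- 0L
    trainTrace <- numeric(0); valTrace <- numeric(0)
    earlyStopped <- FALSE

    for (epoch in seq_len(cfg$maxEpochs)) {
      acts <- mlpForward(model, Xtr)
      P <- acts[[nL + 1L]]
      if (!all(is.finite(P)))
        stop("non-finite loss at epoch ", epoch, call. = FALSE)
      trainTrace <- c(trainTrace, mlpLoss(P, Ytr, cfg$loss))

      # backprop; softmax + cross-entropy gives the simple output delta,
      # MSE needs the full softmax Jacobian
      if (cfg$loss == "cross_entropy") {
        delta <- (P - Ytr) / n
      } else {
        G <- (2 / (n * ncol(P))) * (P - Ytr)
        delta <- (G - rowSums(G * P)) * P
      }
      for (l in nL:1) {
        A <- acts[[l]]
        gW <- t(A) %*% delta
        gB <- colSums(delta)
        if (l > 1L) {
          Ah <- acts[[l]]
          delta <- (delta %*% t(model@weights[[l]])) * Ah * (1 - Ah)
        }
        vW[[l]] <- cfg$momentum * vW[[l]] - cfg$learningRate * gW
        vB[[l]] <- cfg$momentum * vB[[l]] - cfg$learningRate * gB
        model@weights[[l]] <- model@weights[[l]] + vW[[l]]
        model@biases[[l]] <- model@biases[[l]] + vB[[l]]
      }

      if (epoch %% cfg$checkEvery == 0L || epoch == cfg$maxEpochs) {
        Pv <- mlpForward(model, Xv)[[nL + 1L]]
        vl <- mlpLoss(Pv, Yv, cfg$loss)
        valTrace <- c(valTrace, vl)
        if (vl < best$loss - 1e-9) {
          best <- list(loss = vl, W = model@weights, B = model@biases,
                       epoch = epoch)
          badChecks <- 0L
        } else {
          badChecks <- badChecks + 1L
          if (badChecks >= cfg$patience) { earlyStopped <- TRUE; break }
        }
      }
    }
    list(best = best, trainTrace = trainTrace, valTrace = valTrace,
         earlyStopped = earlyStopped)
  }

  runs <- lapply(seq_len(cfg$restarts), function(r) runOnce())
  pick <- which.min(vapply(runs, function(r) r$best$loss, numeric(1)))
  run <- runs[[pick]]
  model@weights <- run$best$W
  model@biases <- run$best$B
  model@fitInfo <- list(epochs = length(run$trainTrace),
                        bestEpoch = run$best$epoch,
                        earlyStopped = run$earlyStopped,
                        restartPicked = pick,
                        trainLoss = run$trainTrace, valLoss = run$valTrace,
                        config = unclass(cfg))
  validObject(model)
  model
}

#' Class-probability predictions
#'
#' Applies the fit-time standardization, the sigmoid hidden layer(s) and the
#' softmax readout; each returned row is a probability vector.
#'
#' @param model an [MLPModel-class].
#' @param X feature matrix (samples x 216) or single feature vector.
#' @return Matrix (samples x classes) of probabilities; rows sum to 1.
#' @export
mlpPredictProba <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  if (ncol(X) != model@layerSizes[1])
    stop("feature width ", ncol(X), " does not match model input width ",
         model@layerSizes[1], call. = FALSE)
  Xs <- standardizeFeatures(as.matrix(X), model@center, model@scale)
  P <- mlpForward(model, Xs)[[length(model@weights) + 1L]]
  colnames(P) <- model@classes
  P
}

#' Hard label predictions
#'
#' Argmax of [mlpPredictProba()] with lowest-index tie-break.
#'
#' @inheritParams mlpPredictProba
#' @return Character vector of predicted class labels.
#' @export
mlpPredict <- function(model, X) {
  P <- mlpPredictProba(model, X)
  model@classes[apply(P, 1, which.max)]
}

#' Serialize / restore an MLP model as portable JSON
#'
#' The file records a format version, layer sizes, weights, biases,
#' standardization parameters, class names and the training configuration.
#'
#' @param model an [MLPModel-class].
#' @param path output file.
#' @return `saveModel` returns `path` invisibly; `loadModel` returns the
#'   restored [MLPModel-class].
#' @export
saveModel <- function(model, path) {
  obj <- list(format = "lesionDx-mlp-1",
              layerSizes = model@layerSizes,
              weights = lapply(model@weights, function(w)
                list(dim = dim(w), values = as.numeric(w))),
              biases = model@biases,
              center = model@center, scale = model@scale,
              classes = model@classes,
              fitInfo = model@fitInfo[c("epochs", "bestEpoch",
                                        "earlyStopped", "config")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "lesionDx-mlp-1"))
    stop("unrecognized model format: ", obj$format, call. = FALSE)
  num <- function(x) vapply(x, as.numeric, numeric(1))
  W <- lapply(obj$weights, function(w)
    matrix(num(w$values), num(w$dim)[1], num(w$dim)[2]))
  new("MLPModel",
      layerSizes = as.integer(num(obj$layerSizes)), weights = W,
      biases = lapply(obj$biases, num),
      center = num(obj$center), scale = num(obj$scale),
      classes = vapply(obj$classes, as.character, character(1)),
      fitInfo = obj$fitInfo)
}
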
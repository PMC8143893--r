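#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Labeled dermoscopy-style image
#'
#' Container for one grayscale image, an optional binary ground-truth lesion
#' mask of the same dimensions, and an optional class label. This is the unit
#' that flows through the pipeline: the synthetic generator produces it, the
#' segmenter consumes its image, and feature extraction and classification
#' consume image + mask + label.
#'
#' @slot image numeric matrix of gray levels in \[0, 255\].
#' @slot mask binary matrix (0/1) of the same dimensions, or `NULL`.
#' @slot label character scalar class label, or `NA_character_`.
#'
#' @seealso [lesionImage()], [simulateDataset()], [segmentLesion()]
#' @export
setClass("LesionImage",
  representation(image = "matrix", mask = "matrixOrNULL", label = "character"),
  prototype(mask = NULL, label = NA_character_)
)

setValidity("LesionImage", function(object) {
  msg <- character()
  img <- object@image
  if (!is.numeric(img) || length(img) == 0L)
    msg <- c(msg, "image must be a nonempty numeric matrix")
  else {
    if (anyNA(img) || !all(is.finite(img)))
      msg <- c(msg, "image must be finite")
    if (min(img) < 0 || max(img) > 255)
      msg <- c(msg, "image values must lie in [0, 255]")
  }
  if (!is.null(object@mask)) {
    if (!identical(dim(object@mask), dim(img)))
      msg <- c(msg, "mask and image dimensions differ")
    if (!all(object@mask %in% c(0, 1)))
      msg <- c(msg, "mask must be strictly binary (0/1)")
  }
  if (length(object@label) != 1L)
    msg <- c(msg, "label must be a single character value")
  if (length(msg)) msg else TRUE
})

#' Construct a LesionImage
#'
#' @param image numeric matrix of gray levels in \[0, 255\].
#' @param mask optional binary matrix (0/1, 1 = lesion) of the same shape.
#' @param label optional class label (character scalar).
#' @return A [LesionImage-class] object.
#' @examples
#' li <- lesionImage(matrix(128, 8, 8), mask = matrix(0, 8, 8), label = "nevus")
#' imgLabel(li)
#' @export
lesionImage <- function(image, mask = NULL, label = NA_character_) {
  if (!is.null(mask)) {
    mask <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  }
  new("LesionImage", image = image, mask = mask, label = as.character(label))
}

#' @describeIn lesionImage gray-level pixel matrix.
#' @param x a `LesionImage`.
#' @export
imgData <- function(x) x@image

#' @describeIn lesionImage binary ground-truth mask (or `NULL`).
#' @export
maskData <- function(x) x@mask

#' @describeIn lesionImage class label.
#' @export
imgLabel <- function(x) x@label

setMethod("show", "LesionImage", function(object) {
  d <- dim(object@image)
  cat("LesionImage ", d[1], " x ", d[2],
      " | mask: ", if (is.null(object@mask)) "none" else
        paste0(sum(object@mask), " lesion px"),
      " | label: ", object@label, "\n", sep = "")
})

#' Result of SPF level-set segmentation
#'
#' Holds the final binary region-of-interest mask (largest connected
#' component of the converged level-set interior), the number of iterations
#' used, whether the pixel-count stopping rule fired before the iteration
#' cap, and the per-iteration traces of the inside/outside region means
#' (c1, c2).
#'
#' @slot roiMask binary matrix, 1 = lesion.
#' @slot iterations integer, evolution steps performed.
#' @slot converged logical, `TRUE` if the stopping rule fired.
#' @slot c1Trace,c2Trace numeric vectors of per-iteration region means.
#'
#' @seealso [segmentLesion()]
#' @export
setClass("SegmentationResult",
  representation(roiMask = "matrix", iterations = "integer",
                 converged = "logical", c1Trace = "numeric",
                 c2Trace = "numeric")
)

setValidity("SegmentationResult", function(object) {
  msg <- character()
  if (!all(object@roiMask %in% c(0, 1)))
    msg <- c(msg, "roiMask must be binary")
  if (object@iterations < 0L)
    msg <- c(msg, "iterations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SegmentationResult-class final binary lesion mask.
#' @param x a `SegmentationResult`.
#' @export
roiMask <- function(x) x@roiMask

#' @describeIn SegmentationResult-class number of evolution iterations run.
#' @export
iterations <- function(x) x@iterations

#' @describeIn SegmentationResult-class whether the stopping rule fired.
#' @export
converged <- function(x) x@converged

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult | ", sum(object@roiMask), " ROI px | ",
      object@iterations, " iterations | converged: ", object@converged,
      "\n", sep = "")
})

#' Trained multilayer perceptron model
#'
#' A shallow feed-forward network (logistic-sigmoid hidden layer, softmax
#' readout) mapping the 216-dimensional hybrid texture descriptor to class
#' probabilities, together with the feature standardization parameters
#' captured at fit time and the class-name dictionary.
#'
#' @slot layerSizes integer vector, e.g. `c(216, 10, 3)`.
#' @slot weights list of weight matrices, one per layer transition.
#' @slot biases list of bias vectors, one per layer transition.
#' @slot center,scale numeric vectors of per-feature standardization
#'   parameters (z-score), captured at fit time.
#' @slot classes character vector of class names in output order.
#' @slot fitInfo list with training metadata (loss traces, epochs run,
#'   whether early stopping fired, the training configuration).
#'
#' @seealso [mlpFit()], [mlpPredict()], [mlpPredictProba()]
#' @export
setClass("MLPModel",
  representation(layerSizes = "integer", weights = "list", biases = "list",
                 center = "numeric", scale = "numeric", classes = "character",
                 fitInfo = "list")
)

setValidity("MLPModel", function(object) {
  msg <- character()
  L <- object@layerSizes
  if (length(L) < 2L) msg <- c(msg, "need at least input and output layers")
  if (length(object@weights) != length(L) - 1L)
    msg <- c(msg, "one weight matrix per layer transition required")
  if (length(object@classes) != L[length(L)])
    msg <- c(msg, "output width must equal number of classes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MLPModel", function(object) {
  cat("MLPModel ", paste(object@layerSizes, collapse = "-"),
      " | classes: ", paste(object@classes, collapse = ", "), "\n", sep = "")
  if (!is.null(object@fitInfo$epochs))
    cat("  trained ", object@fitInfo$epochs, " epochs",
        if (isTRUE(object@fitInfo$earlyStopped)) " (early stopped)", "\n",
        sep = "")
})
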
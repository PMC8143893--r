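#' Gaussian filter specification
#'
#' @param sigma standard deviation in pixels (> 0). Default 1.5.
#' @param kernelSize odd integer >= 3; derived as `2*ceiling(3*sigma) + 1`
#'   when absent.
#' @return List of class `"GaussianSpec"`.
#' @export
gaussianSpec <- function(sigma = 1.5, kernelSize = NULL) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (is.null(kernelSize)) kernelSize <- 2L * ceiling(3 * sigma) + 1L
  kernelSize <- as.integer(kernelSize)
  if (kernelSize < 3L || kernelSize %% 2L == 0L)
    stop("kernelSize must be an odd integer >= 3", call. = FALSE)
  structure(list(sigma = sigma, kernelSize = kernelSize),
            class = "GaussianSpec")
}

#' Sampled 2-D Gaussian kernel
#'
#' `h(x, y) = 1/(2*pi*sigma^2) * exp(-(x^2 + y^2) / (2*sigma^2))` sampled on
#' the integer grid centred at 0, then (by default) normalized to sum to 1.
#'
#' @param spec a [gaussianSpec()].
#' @param normalize logical; if `FALSE` the raw sampled values are returned.
#' @return `kernelSize x kernelSize` numeric matrix.
#' @examples
#' k <- gaussianKernel(gaussianSpec(sigma = 1))
#' sum(k)
#' @export
gaussianKernel <- function(spec, normalize = TRUE) {
  h <- (spec$kernelSize - 1L) %/% 2L
  x <- -h:h
  g2 <- outer(x, x, function(x, y)
    exp(-(x^2 + y^2) / (2 * spec$sigma^2)) / (2 * pi * spec$sigma^2))
  if (normalize) g2 / sum(g2) else g2
}

# Fold an out-of-range index back into 1..n by mirror reflection
# (edge pixel repeated: ... 2 1 | 1 2 3 ... n | n n-1 ...).
reflectIndex <- function(j, n) {
  repeat {
    bad <- j < 1L | j > n
    if (!any(bad)) return(j)
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
  }
}

# 1-D smoothing operator (n x n) for a symmetric kernel with reflective
# boundary handling; smoothing is then two matrix products (separable).
smoothOperator <- function(n, k1) {
  h <- (length(k1) - 1L) %/% 2L
  S <- matrix(0, n, n)
  for (t in -h:h) {
    j <- reflectIndex(seq_len(n) + t, n)
    S[cbind(seq_len(n), j)] <- S[cbind(seq_len(n), j)] + k1[t + h + 1L]
  }
  S
}

#' Gaussian smoothing of a 2-D image
#'
#' Convolution with [gaussianKernel()] using reflective boundary handling;
#' output has the same shape as the input. The normalized Gaussian is
#' separable, so the convolution is applied as row and column passes.
#'
#' @param image 2-D numeric matrix.
#' @param spec a [gaussianSpec()].
#' @return Smoothed matrix of identical dimensions.
#' @export
smoothImage <- function(image, spec = gaussianSpec()) {
  stopIfNot2D(image)
  h <- (spec$kernelSize - 1L) %/% 2L
  x <- -h:h
  k1 <- exp(-x^2 / (2 * spec$sigma^2))
  k1 <- k1 / sum(k1)
  Sr <- smoothOperator(nrow(image), k1)
  Sc <- smoothOperator(ncol(image), k1)
  Sr %*% image %*% t(Sc)
}

#' Luma grayscale conversion
#'
#' `0.299 R + 0.587 G + 0.114 B` on a 3-channel array with values in
#' \[0, 255\].
#'
#' @param image numeric array of dimension `(rows, cols, 3)`.
#' @return 2-D matrix of gray levels.
#' @export
toGrayscale <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("toGrayscale expects a (rows, cols, 3) array", call. = FALSE)
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  matrix(g, dim(image)[1], dim(image)[2])
}

ebToMat <- function(x) {
  d <- EBImage::imageData(x)
  matrix(d, dim(d)[1], dim(d)[2])
}

#' Remove dark hair strokes from a grayscale image
#'
#' Dark thin curvilinear structures are detected with a morphological
#' black-hat (grayscale closing with a disc structuring element minus the
#' image), thresholded, and inpainted with the closing value (the local
#' hair-free neighbourhood estimate). Non-hair regions are returned
#' unchanged.
#'
#' @param image 2-D gray matrix in \[0, 255\].
#' @param brushSize odd disc diameter in pixels; must exceed the hair width
#'   (default 9).
#' @param threshold black-hat response (gray levels) above which a pixel is
#'   treated as hair (default 20).
#' @return Matrix of the same shape with hair pixels inpainted.
#' @export
removeHair <- function(image, brushSize = 9L, threshold = 20) {
  stopIfNot2D(image)
  brush <- EBImage::makeBrush(as.integer(brushSize), shape = "disc")
  # EBImage grayscale morphology operates on [0, 1] intensities
  closed <- ebToMat(EBImage::closing(image / 255, brush)) * 255
  blackhat <- closed - image
  hair <- blackhat > threshold
  out <- image
  out[hair] <- closed[hair]
  out
}

#' Preprocess an image for segmentation
#'
#' Optional hair removal followed by Gaussian smoothing (the default stage
#' order; configurable).
#'
#' @param image 2-D gray matrix.
#' @param spec a [gaussianSpec()].
#' @param hairRemoval logical, run [removeHair()] first.
#' @param order `"hair_first"` or `"smooth_first"`.
#' @return Preprocessed matrix.
#' @export
preprocessImage <- function(image, spec = gaussianSpec(),
                            hairRemoval = FALSE,
                            order = c("hair_first", "smooth_first")) {
  order <- match.arg(order)
  if (hairRemoval && order == "hair_first") image <- removeHair(image)
  image <- smoothImage(image, spec)
  if (hairRemoval && order == "smooth_first") image <- removeHair(image)
  image
}
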
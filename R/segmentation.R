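#' Configuration of the SPF level-set segmenter
#'
#' The contour is the zero level of a field `phi` initialized just inside the
#' image frame and evolved inward by the gradient flow
#' `dphi/dt = lambda * div(spf * grad(phi)/|grad(phi)|) + nu * spf *
#' dirac_eps(phi)`, where `spf` is the mask-restricted signed pressure force
#' built from the global fitted image of the region means. Evolution stops
#' when consecutive interior masks retain at least `stopValue` percent of
#' their pixels.
#'
#' @param lambdaWeight weight (>= 0) of the curvature/length term. Default 1.
#' @param nuWeight signed weight of the area/pressure term. With the
#'   inside-positive sign convention used here (`phi > 0` inside the
#'   contour) a negative value shrinks the contour from the frame onto the
#'   lesion, which is the intended inward evolution; default -25.
#' @param epsilon Heaviside/Dirac smoothing width (> 0). Default 1.5.
#' @param rho magnitude of the piecewise-constant initial level set (> 0).
#'   Default 2.
#' @param dt explicit time step (> 0). Default 1.
#' @param stopValue stopping percentage in \[98, 100\]: stop once the current
#'   mask retains at least this percentage of the reference mask's pixels.
#'   Default 99.
#' @param smallValueThreshold gray-level threshold `T >= 0`; pixels with
#'   image intensity below `T` are eliminated from the stop-rule pixel
#'   counts. Default 10.
#' @param maxIter iteration cap (>= 1). Default 300.
#' @param regSigma width of the Gaussian regularization of `phi` applied
#'   after each step, in lieu of signed-distance re-initialization. Default 1.
#' @param borderMargin pixels between the frame and the initial contour.
#'   Default 5.
#' @param checkInterval iterations between stop-rule checks (the reference
#'   mask is the mask at the previous check); 1 compares consecutive
#'   iterations. Default 10.
#' @param meansEpsilon Heaviside width used for the region means inside the
#'   evolution (default 1e-9, the sharp-partition limit). The evolving
#'   field keeps magnitudes on the order of `rho`, so a finite-width
#'   Heaviside would leak outside intensities into the inside mean; the
#'   fitted image and the Dirac term keep the finite `epsilon`.
#' @return List of class `"SegmentationConfig"`.
#' @export
segmentationConfig <- function(lambdaWeight = 1, nuWeight = -25,
                               epsilon = 1.5, rho = 2, dt = 1,
                               stopValue = 99, smallValueThreshold = 10,
                               maxIter = 300L, regSigma = 1,
                               borderMargin = 5L, checkInterval = 10L,
                               meansEpsilon = 1e-9) {
  if (lambdaWeight < 0) stop("lambdaWeight must be >= 0", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (rho <= 0) stop("rho must be > 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (stopValue < 98 || stopValue > 100)
    stop("stopValue must lie in [98, 100]", call. = FALSE)
  if (smallValueThreshold < 0)
    stop("smallValueThreshold must be >= 0", call. = FALSE)
  if (maxIter < 1L) stop("maxIter must be >= 1", call. = FALSE)
  if (regSigma < 0) stop("regSigma must be >= 0", call. = FALSE)
  if (checkInterval < 1L) stop("checkInterval must be >= 1", call. = FALSE)
  structure(list(lambdaWeight = lambdaWeight, nuWeight = nuWeight,
                 epsilon = epsilon, rho = rho, dt = dt,
                 stopValue = stopValue,
                 smallValueThreshold = smallValueThreshold,
                 maxIter = as.integer(maxIter), regSigma = regSigma,
                 borderMargin = as.integer(borderMargin),
                 checkInterval = as.integer(checkInterval),
                 meansEpsilon = meansEpsilon),
            class = "SegmentationConfig")
}

# Level-set state: a plain list kept internally consistent by this
# constructor (mask is always the characteristic function of phi > 0).
levelSetState <- function(phi, iteration = 0L, prevMask = NULL,
                          c1 = NA_real_, c2 = NA_real_, spf = NULL) {
  mask <- asBinary(phi > 0)
  if (is.null(prevMask)) prevMask <- mask
  structure(list(phi = phi, mask = mask, prevMask = prevMask,
                 iteration = as.integer(iteration), c1 = c1, c2 = c2,
                 spf = spf),
            class = "LevelSetState")
}

#' Initialize the level-set field at the image border
#'
#' The initial contour is a rectangle inset `borderMargin` pixels from the
#' image frame; `phi0` is piecewise constant: `+rho` strictly inside the
#' rectangle, `0` on its boundary, `-rho` outside (inside-positive sign
#' convention, so the interior mask is `phi > 0`).
#'
#' @param shape integer length-2, image dimensions.
#' @param cfg a [segmentationConfig()].
#' @return A `LevelSetState` list with fields `phi`, `mask`, `prevMask`,
#'   `iteration`, `c1`, `c2`, `spf`.
#' @export
initializeLevelSet <- function(shape, cfg = segmentationConfig()) {
  m <- cfg$borderMargin
  if (shape[1] <= 2L * m + 2L || shape[2] <= 2L * m + 2L)
    stop("image too small for borderMargin ", m, call. = FALSE)
  phi <- matrix(-cfg$rho, shape[1], shape[2])
  # inset rectangle boundary at rows/cols m+1 and n-m
  phi[(m + 1):(shape[1] - m), (m + 1):(shape[2] - m)] <- 0
  phi[(m + 2):(shape[1] - m - 1), (m + 2):(shape[2] - m - 1)] <- cfg$rho
  levelSetState(phi)
}

#' Smoothed Heaviside step
#'
#' `H_eps(z) = 0.5 * (1 + (2/pi) * atan(z/eps))`.
#'
#' @param z numeric scalar, vector or matrix.
#' @param epsilon smoothing width (> 0).
#' @return Values in (0, 1), same shape as `z`.
#' @export
heavisideEps <- function(z, epsilon) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  0.5 * (1 + (2 / pi) * atan(z / epsilon))
}

#' Smoothed Dirac delta
#'
#' `delta_eps(z) = eps / (pi * (z^2 + eps^2))`, the derivative of
#' [heavisideEps()].
#'
#' @inheritParams heavisideEps
#' @return Nonnegative values, same shape as `z`.
#' @export
diracEps <- function(z, epsilon) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  epsilon / (pi * (z^2 + epsilon^2))
}

#' Mask-restricted region means of the level-set partition
#'
#' `c1 = sum(I * H_eps(phi) * M) / sum(H_eps(phi) * M)` and
#' `c2 = sum(I * (1 - H_eps(phi)) * M) / sum((1 - H_eps(phi)) * M)`, where
#' `M` is the characteristic mask of the current subregion.
#'
#' @param image 2-D gray matrix.
#' @param state a `LevelSetState` (uses `phi`).
#' @param epsilon Heaviside smoothing width.
#' @param regionMask characteristic function `M` of the active subregion.
#'   The default (`NULL`) is the all-active initial domain, i.e. the means
#'   are taken over the full `phi > 0` / `phi < 0` partition; restricting
#'   `M` to the current interior would collapse the outside mean onto the
#'   thin band just inside the contour and leave the pressure force without
#'   a fixed point at the lesion boundary (the inward restriction enters
#'   through [spfField()] instead).
#' @return List `(c1, c2, collapsed)`; `collapsed = TRUE` flags a vanished
#'   denominator (contour collapse).
#' @export
regionMeans <- function(image, state, epsilon, regionMask = NULL) {
  H <- heavisideEps(state$phi, epsilon)
  M <- if (is.null(regionMask))
    matrix(1, nrow(state$phi), ncol(state$phi)) else regionMask
  d1 <- sum(H * M); d2 <- sum((1 - H) * M)
  if (d1 <= .Machine$double.eps || d2 <= .Machine$double.eps)
    return(list(c1 = NA_real_, c2 = NA_real_, collapsed = TRUE))
  list(c1 = sum(image * H * M) / d1,
       c2 = sum(image * (1 - H) * M) / d2,
       collapsed = FALSE)
}

#' Global fitted image
#'
#' `I_GF = c1 * H_eps(phi) + c2 * (1 - H_eps(phi))` pointwise.
#'
#' @param c1,c2 finite region means.
#' @param state a `LevelSetState` (uses `phi`).
#' @param epsilon Heaviside smoothing width.
#' @return 2-D field, same shape as `phi`.
#' @export
globalFittedImage <- function(c1, c2, state, epsilon) {
  H <- heavisideEps(state$phi, epsilon)
  c1 * H + c2 * (1 - H)
}

#' Mask-restricted signed pressure force
#'
#' `spf = (I - I_GF) * M / max|I - I_GF|` wherever `I != 0`, and `spf = 0`
#' wherever `I = 0`; if `max|I - I_GF| = 0` the whole field is zero. Values
#' lie in \[-1, 1\].
#'
#' @param image 2-D gray matrix.
#' @param fitted the global fitted image ([globalFittedImage()]).
#' @param mask the characteristic mask `M` of the current subregion.
#' @return 2-D field in \[-1, 1\], zero where the image intensity is zero.
#' @export
spfField <- function(image, fitted, mask) {
  if (!identical(dim(image), dim(fitted)) || !identical(dim(image), dim(mask)))
    stop("image, fitted and mask shapes must match", call. = FALSE)
  dev <- image - fitted
  mx <- max(abs(dev))
  # degenerate fit: a vanishing maximum would amplify rounding noise of the
  # region means to full scale, so anything below 1e-9 gray levels is zero
  if (mx < 1e-9) return(matrix(0, nrow(image), ncol(image)))
  spf <- dev * mask / mx
  spf[image == 0] <- 0
  spf
}

# Central-difference gradient with replicate boundary.
gradCentral <- function(f) {
  gr <- (shiftMat(f, 1L, 0L) - shiftMat(f, -1L, 0L)) / 2
  gc <- (shiftMat(f, 0L, 1L) - shiftMat(f, 0L, -1L)) / 2
  list(gr = gr, gc = gc)
}

#' One explicit evolution step of the level set
#'
#' Updates `phi <- phi + dt * (lambda * div(spf * grad(phi)/|grad(phi)|) +
#' nu * spf * dirac_eps(phi))` with central differences (gradient magnitude
#' floored at 1e-10), then regularizes `phi` by Gaussian smoothing of width
#' `regSigma` (in lieu of signed-distance re-initialization), updates the
#' mask history (`prevMask <- mask`, `mask <- (phi > 0)`), and increments
#' the iteration counter. The SPF field is recomputed from the current
#' region means before the update.
#'
#' @param image 2-D gray matrix.
#' @param state a `LevelSetState`.
#' @param cfg a [segmentationConfig()].
#' @return The updated `LevelSetState` (with `c1`, `c2`, `spf` filled in),
#'   or a state with `collapsed = TRUE` attribute if the contour vanished.
#' @export
evolveStep <- function(image, state, cfg = segmentationConfig()) {
  rm <- regionMeans(image, state, cfg$meansEpsilon %||% cfg$epsilon)
  if (rm$collapsed) {
    attr(state, "collapsed") <- TRUE
    return(state)
  }
  fitted <- globalFittedImage(rm$c1, rm$c2, state, cfg$epsilon)
  spf <- spfField(image, fitted, state$mask)

  g <- gradCentral(state$phi)
  mag <- pmax(sqrt(g$gr^2 + g$gc^2), 1e-10)
  nr <- spf * g$gr / mag
  nc <- spf * g$gc / mag
  divr <- (shiftMat(nr, 1L, 0L) - shiftMat(nr, -1L, 0L)) / 2
  divc <- (shiftMat(nc, 0L, 1L) - shiftMat(nc, 0L, -1L)) / 2
  phi <- state$phi + cfg$dt *
    (cfg$lambdaWeight * (divr + divc) +
       cfg$nuWeight * spf * diracEps(state$phi, cfg$epsilon))
  if (cfg$regSigma > 0)
    phi <- smoothImage(phi, gaussianSpec(sigma = cfg$regSigma))
  if (!all(is.finite(phi)))
    stop("non-finite level-set field at iteration ", state$iteration + 1L,
         call. = FALSE)
  levelSetState(phi, iteration = state$iteration + 1L,
                prevMask = state$mask, c1 = rm$c1, c2 = rm$c2, spf = spf)
}

#' Ring between two consecutive interior subregions
#'
#' The outer subregion at step k is the set difference
#' `w_bar_k = w_{k-1} - w_k` (pixels in the previous mask and not in the
#' current one).
#'
#' @param prevMask,mask binary matrices of equal shape.
#' @return Binary ring mask.
#' @export
subregionDifference <- function(prevMask, mask) {
  if (!identical(dim(prevMask), dim(mask)))
    stop("mask shapes must match", call. = FALSE)
  asBinary(prevMask == 1 & mask == 0)
}

#' Pixel-count stopping rule
#'
#' Evolution stops once the current mask retains at least `stopValue`
#' percent of the reference mask's pixels (contour change below tolerance),
#' i.e. when `sum(M_k) < (stopValue/100) * sum(M_old)` is FALSE. When an
#' image is supplied, pixels with intensity below `smallValueThreshold` are
#' eliminated from both counts.
#'
#' @param prevMask,mask binary matrices of equal shape (reference and
#'   current interior masks).
#' @param cfg a [segmentationConfig()].
#' @param image optional gray matrix for the small-value elimination.
#' @return Logical: `TRUE` to stop.
#' @export
checkStop <- function(prevMask, mask, cfg = segmentationConfig(),
                      image = NULL) {
  if (!identical(dim(prevMask), dim(mask)))
    stop("mask shapes must match", call. = FALSE)
  if (!is.null(image) && cfg$smallValueThreshold > 0) {
    keep <- image >= cfg$smallValueThreshold
    prevMask <- prevMask * keep
    mask <- mask * keep
  }
  prevCount <- sum(prevMask)
  if (prevCount == 0) return(TRUE)
  sum(mask) >= (cfg$stopValue / 100) * prevCount
}

#' Segment a lesion with the mask-restricted SPF level set
#'
#' Runs [initializeLevelSet()] and iterates region means, global fitted
#' image, SPF and [evolveStep()] until the stopping rule fires or `maxIter`
#' is reached. The contour starts at the image border and evolves inward;
#' the final interior mask is reduced to its largest 8-connected component.
#'
#' @param image 2-D gray matrix (preprocessed grayscale image).
#' @param cfg a [segmentationConfig()].
#' @return A [SegmentationResult-class].
#' @examples
#' sp <- lesionSpec(center = c(32, 32), semiAxes = c(12, 9))
#' li <- renderLesion(makeLesionMask(sp, c(64, 64), 1), sp, 1)
#' res <- segmentLesion(smoothImage(imgData(li)))
#' sum(roiMask(res))
#' @export
segmentLesion <- function(image, cfg = segmentationConfig()) {
  stopIfNot2D(image)
  state <- initializeLevelSet(dim(image), cfg)
  c1t <- numeric(0); c2t <- numeric(0)
  convergedFlag <- FALSE
  checkpoint <- state$mask
  initialCount <- sum(state$mask)
  # the similarity rule only arms once the contour has moved by more than
  # the stop tolerance since initialization, so the slow early front is not
  # mistaken for convergence
  motionStarted <- FALSE
  for (k in seq_len(cfg$maxIter)) {
    state <- evolveStep(image, state, cfg)
    if (isTRUE(attr(state, "collapsed")) || sum(state$mask) == 0) {
      warning("contour collapsed at iteration ", state$iteration,
              "; returning empty ROI", call. = FALSE)
      return(new("SegmentationResult",
                 roiMask = matrix(0, nrow(image), ncol(image)),
                 iterations = state$iteration, converged = FALSE,
                 c1Trace = c1t, c2Trace = c2t))
    }
    c1t <- c(c1t, state$c1); c2t <- c(c2t, state$c2)
    if (k %% cfg$checkInterval == 0L) {
      if (motionStarted &&
          checkStop(checkpoint, state$mask, cfg, image = image)) {
        convergedFlag <- TRUE
        break
      }
      if (!motionStarted &&
          sum(state$mask) < (cfg$stopValue / 100) * initialCount)
        motionStarted <- TRUE
      checkpoint <- state$mask
    }
  }
  roi <- largestComponent(state$mask)
  new("SegmentationResult", roiMask = roi, iterations = state$iteration,
      converged = convergedFlag, c1Trace = c1t, c2Trace = c2t)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`.
#'
#' @param a,b binary matrices of equal shape.
#' @return Scalar in \[0, 1\] (1 when both masks are empty).
#' @export
diceCoefficient <- function(a, b) {
  a <- asBinary(a); b <- asBinary(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a * b) / s
}
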
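#' Specification of a synthetic lesion
#'
#' Parameter bundle for the synthetic dermoscopy-image generator: a rotated
#' ellipse whose border is perturbed by random-phase radial harmonics, filled
#' with band-limited texture, rendered over a uniform skin background with
#' additive Gaussian noise and optional dark hair strokes.
#'
#' @param center numeric length-2, lesion centre as (row, col) in pixels.
#' @param semiAxes numeric length-2 `(a, b)`, ellipse semi-axes in pixels
#'   (both >= 3).
#' @param rotation ellipse rotation in radians.
#' @param irregularityAmplitude amplitude fraction `A` in \[0, 0.3\] of the
#'   radial border perturbation `r(theta) = r0(theta) * (1 + A * sum_k
#'   sin(k*theta + phi_k))`.
#' @param irregularityHarmonics integer >= 0, number of harmonics `k = 1..H`.
#' @param lesionIntensity mean lesion gray level in \[0, 255\].
#' @param backgroundIntensity mean background gray level in \[0, 255\];
#'   must differ from `lesionIntensity`.
#' @param textureContrast gray-level amplitude of the intra-lesion texture
#'   (texture values are bounded by `+/- textureContrast`).
#' @param textureScale correlation length (pixels) of the intra-lesion
#'   texture: small values give fine granularity, large values coarse
#'   blotches. Default 2.5.
#' @param microContrast standard deviation of pixel-scale intra-lesion
#'   granularity (pigment peppering), independent of the band-limited
#'   texture. Default 0.
#' @param noiseSd standard deviation of additive Gaussian pixel noise.
#' @param hairCount integer >= 0, number of dark hair strokes overlaid.
#'
#' @return A named list of class `"LesionSpec"`.
#' @examples
#' sp <- lesionSpec(center = c(32, 32), semiAxes = c(14, 10))
#' m <- makeLesionMask(sp, shape = c(64, 64), seed = 1)
#' sum(m)
#' @export
lesionSpec <- function(center = c(64, 64), semiAxes = c(25, 18),
                       rotation = 0, irregularityAmplitude = 0,
                       irregularityHarmonics = 0L,
                       lesionIntensity = 70, backgroundIntensity = 175,
                       textureContrast = 0, textureScale = 2.5,
                       microContrast = 0, noiseSd = 0, hairCount = 0L) {
  if (any(semiAxes < 3))
    stop("semiAxes must both be >= 3 pixels", call. = FALSE)
  if (irregularityAmplitude < 0 || irregularityAmplitude > 0.3)
    stop("irregularityAmplitude must lie in [0, 0.3]", call. = FALSE)
  if (lesionIntensity == backgroundIntensity)
    stop("lesionIntensity must differ from backgroundIntensity", call. = FALSE)
  if (lesionIntensity < 0 || lesionIntensity > 255 ||
      backgroundIntensity < 0 || backgroundIntensity > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  if (noiseSd < 0 || textureContrast < 0 || hairCount < 0)
    stop("noiseSd, textureContrast and hairCount must be >= 0", call. = FALSE)
  if (textureScale <= 0) stop("textureScale must be > 0", call. = FALSE)
  if (microContrast < 0) stop("microContrast must be >= 0", call. = FALSE)
  structure(list(center = center, semiAxes = semiAxes, rotation = rotation,
                 irregularityAmplitude = irregularityAmplitude,
                 irregularityHarmonics = as.integer(irregularityHarmonics),
                 lesionIntensity = lesionIntensity,
                 backgroundIntensity = backgroundIntensity,
                 textureContrast = textureContrast,
                 textureScale = textureScale, microContrast = microContrast,
                 noiseSd = noiseSd, hairCount = as.integer(hairCount)),
            class = "LesionSpec")
}

#' Rasterize a synthetic lesion mask
#'
#' Draws a closed region: an ellipse whose polar radius is modulated by a sum
#' of random-phase sinusoids (`irregularityHarmonics` harmonics of amplitude
#' `irregularityAmplitude`). Deterministic given `seed`.
#'
#' @param spec a [lesionSpec()].
#' @param shape integer length-2, image dimensions (rows, cols).
#' @param seed integer RNG seed (fixes the harmonic phases).
#' @return Binary matrix of dimension `shape` (1 = lesion).
#' @export
makeLesionMask <- function(spec, shape, seed = 1L) {
  a <- spec$semiAxes[1]; b <- spec$semiAxes[2]
  rmax <- max(a, b) * (1 + spec$irregularityAmplitude *
                         max(1L, spec$irregularityHarmonics))
  if (spec$center[1] - rmax < 1 || spec$center[1] + rmax > shape[1] ||
      spec$center[2] - rmax < 1 || spec$center[2] + rmax > shape[2])
    stop("lesion does not fit inside the image frame (center ",
         paste(spec$center, collapse = ","), ", max radius ", round(rmax, 1),
         ", shape ", paste(shape, collapse = "x"), ")", call. = FALSE)
  H <- spec$irregularityHarmonics
  set.seed(deriveSeed(seed, 0L))
  phases <- if (H > 0L) stats::runif(H, 0, 2 * pi) else numeric(0)

  rr <- matrix(seq_len(shape[1]), shape[1], shape[2]) - spec$center[1]
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) -
    spec$center[2]
  theta <- atan2(rr, cc)
  # base radius of the rotated ellipse at polar angle theta
  tp <- theta - spec$rotation
  r0 <- (a * b) / sqrt((b * cos(tp))^2 + (a * sin(tp))^2)
  pert <- 0
  if (H > 0L && spec$irregularityAmplitude > 0) {
    for (k in seq_len(H))
      pert <- pert + sin(k * theta + phases[k])
    pert <- spec$irregularityAmplitude * pert
  }
  r <- pmax(r0 * (1 + pert), 1)
  asBinary(sqrt(rr^2 + cc^2) <= r)
}

# Band-limited zero-mean texture field: Gaussian-smoothed white noise,
# rescaled so max|texture| equals the requested amplitude.
banditedTexture <- function(shape, amplitude, smoothSigma = 2.5) {
  z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  z <- smoothImage(z, gaussianSpec(sigma = smoothSigma))
  z <- z - mean(z)
  m <- max(abs(z))
  if (m == 0) return(z)
  z / m * amplitude
}

# Stamp a quadratic Bezier hair stroke (dark, width 1-3 px) onto an image.
drawHair <- function(img, p0, p1, p2, width, intensity) {
  nr <- nrow(img); nc <- ncol(img)
  t <- seq(0, 1, length.out = 4L * max(nr, nc))
  br <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  bc <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  rad <- (width - 1) / 2
  for (dr in seq(-ceiling(rad), ceiling(rad))) {
    for (dc in seq(-ceiling(rad), ceiling(rad))) {
      if (sqrt(dr^2 + dc^2) > rad + 0.5) next
      ri <- round(br) + dr; ci <- round(bc) + dc
      ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
      img[cbind(ri[ok], ci[ok])] <- intensity
    }
  }
  img
}

#' Render a synthetic dermoscopy-like image for a lesion mask
#'
#' Background pixels take `backgroundIntensity`, lesion pixels take
#' `lesionIntensity` plus band-limited texture bounded by
#' `+/- textureContrast`; additive Gaussian noise of `noiseSd` and
#' `hairCount` dark curved strokes are overlaid, and values are clipped to
#' \[0, 255\]. Deterministic given `seed`.
#'
#' @param mask binary lesion mask.
#' @param spec a [lesionSpec()].
#' @param seed integer RNG seed.
#' @param label optional class label carried on the result.
#' @return A [LesionImage-class] with the rendered image, `mask`, and `label`.
#' @export
renderLesion <- function(mask, spec, seed = 1L, label = NA_character_) {
  mask <- asBinary(stopIfNot2D(mask, "mask"))
  shape <- dim(mask)
  img <- matrix(spec$backgroundIntensity, shape[1], shape[2])
  img[mask == 1] <- spec$lesionIntensity
  set.seed(deriveSeed(seed, 1L))
  if (spec$textureContrast > 0) {
    tex <- banditedTexture(shape, spec$textureContrast, spec$textureScale)
    img <- img + tex * mask
  }
  if ((spec$microContrast %||% 0) > 0)
    img <- img + matrix(stats::rnorm(prod(shape), 0, spec$microContrast),
                        shape[1], shape[2]) * mask
  if (spec$hairCount > 0L) {
    dark <- min(spec$lesionIntensity, spec$backgroundIntensity) * 0.4
    for (h in seq_len(spec$hairCount)) {
      p0 <- c(stats::runif(1, 1, shape[1]), stats::runif(1, 1, shape[2]))
      p2 <- c(stats::runif(1, 1, shape[1]), stats::runif(1, 1, shape[2]))
      p1 <- (p0 + p2) / 2 + stats::runif(2, -0.3, 0.3) * shape
      w <- sample(1:3, 1)
      img <- drawHair(img, p0, p1, p2, w, dark)
    }
  }
  if (spec$noiseSd > 0)
    img <- img + matrix(stats::rnorm(prod(shape), 0, spec$noiseSd),
                        shape[1], shape[2])
  img <- pmin(pmax(img, 0), 255)
  lesionImage(img, mask = mask, label = label)
}

#' PH2-style and ISIC-style class schemes
#'
#' @param scheme `"ph2"` (3 classes: common nevus, atypical nevus, melanoma)
#'   or `"isic"` (7 ISIC-style classes).
#' @return Character vector of class names.
#' @export
classScheme <- function(scheme = c("ph2", "isic")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    ph2  = c("common_nevus", "atypical_nevus", "melanoma"),
    isic = c("nv", "mel", "bkl", "bcc", "akiec", "vasc", "df"))
}

# Default per-class generator parameter ranges, emulating the clinical
# gradient from common nevi to melanoma along the axes dermoscopy actually
# discriminates on: pigmentation darkness (lesion intensity, decreasing),
# border irregularity (increasing), intra-lesion texture amplitude
# (disjoint textureContrast ranges), texture granularity (coarsening
# blotches, textureScale) and the fine-to-coarse texture energy ratio
# (fine pigment-network grain fading into structureless areas,
# microContrast relative to textureContrast — the axis LBP measures).
# Noise and background are shared across classes; per-class ranges are
# disjoint with deliberate margins, as in a diagnosable cohort.
defaultClassSpecs <- function(scheme = "ph2", shape = c(128, 128)) {
  classes <- classScheme(scheme)
  K <- length(classes)
  u <- if (K > 1) (seq_len(K) - 1) / (K - 1) else 0  # 0 = benign .. 1 = worst
  # quadratic through anchors at u = 0, 0.5, 1 (the 3-class design points)
  quad <- function(u, y0, y05, y1)
    y0 * 2 * (u - 0.5) * (u - 1) - y05 * 4 * u * (u - 1) +
      y1 * 2 * u * (u - 0.5)
  tcEdges <- seq(4, 62, length.out = 2 * K)
  irEdges <- seq(0.02, 0.17, length.out = 2 * K)
  inEdges <- seq(115, 55, length.out = 2 * K)
  axScale <- min(shape) / 128      # lesion size tracks the image size
  specs <- lapply(seq_len(K), function(k) {
    list(semiAxes = c(20, 32) * axScale, rotation = c(0, pi),
         irregularityAmplitude = c(irEdges[2 * k - 1],
                                   irEdges[2 * k] - diff(irEdges)[1] / 3),
         irregularityHarmonics = 3L,
         lesionIntensity = c(inEdges[2 * k] + abs(diff(inEdges)[1]) / 3,
                             inEdges[2 * k - 1]),
         backgroundIntensity = c(170, 185),
         textureContrast = c(tcEdges[2 * k - 1],
                             tcEdges[2 * k] - diff(tcEdges)[1] / 3),
         textureScale = quad(u[k], 1.0, 2.0, 4.5),
         microContrast = c(quad(u[k], 6, 9, 1), quad(u[k], 9, 12, 3)),
         noiseSd = c(4, 8), hairCount = 0L)
  })
  names(specs) <- classes
  specs
}

drawFromRange <- function(r) {
  if (length(r) == 1L) return(r)
  stats::runif(1, r[1], r[2])
}

#' Generate a balanced synthetic labeled dataset
#'
#' Draws `nPerClass` images per class, with per-class lesion parameters drawn
#' uniformly from the stated ranges. Deterministic given `seed`.
#'
#' @param nPerClass integer >= 1, images per class.
#' @param classSpecs named list (one entry per class) of parameter ranges:
#'   each field of [lesionSpec()] given as a scalar or a length-2 range.
#'   Defaults to [defaultClassSpecs] for `scheme`.
#' @param scheme class scheme used when `classSpecs` is `NULL`.
#' @param shape image dimensions.
#' @param seed integer RNG seed.
#' @return List of [LesionImage-class] objects (length
#'   `nPerClass * nClasses`), each with mask and label.
#' @examples
#' ds <- simulateDataset(2, scheme = "ph2", shape = c(64, 64), seed = 1)
#' table(vapply(ds, imgLabel, ""))
#' @export
simulateDataset <- function(nPerClass, classSpecs = NULL,
                            scheme = c("ph2", "isic"), shape = c(128, 128),
                            seed = 1L) {
  if (is.null(classSpecs)) {
    scheme <- match.arg(scheme)
    classSpecs <- defaultClassSpecs(scheme, shape)
  }
  if (length(classSpecs) < 2L)
    stop("need at least 2 classes in classSpecs", call. = FALSE)
  if (nPerClass < 1L) stop("nPerClass must be >= 1", call. = FALSE)
  classes <- names(classSpecs)
  out <- vector("list", nPerClass * length(classes))
  i <- 0L
  for (k in seq_along(classes)) {
    rg <- classSpecs[[k]]
    for (j in seq_len(nPerClass)) {
      i <- i + 1L
      imgSeed <- deriveSeed(seed, 100L * k + j)
      set.seed(imgSeed)
      a <- drawFromRange(rg$semiAxes)
      b <- a * stats::runif(1, 0.6, 0.9)
      margin <- max(a, b) * 1.45 + 4
      if (2 * margin >= min(shape))
        stop("semiAxes range too large for shape ",
             paste(shape, collapse = "x"), call. = FALSE)
      ctr <- c(stats::runif(1, margin, shape[1] - margin),
               stats::runif(1, margin, shape[2] - margin))
      sp <- lesionSpec(
        center = ctr, semiAxes = c(a, b),
        rotation = drawFromRange(rg$rotation %||% 0),
        irregularityAmplitude = drawFromRange(rg$irregularityAmplitude %||% 0),
        irregularityHarmonics = rg$irregularityHarmonics %||% 0L,
        lesionIntensity = drawFromRange(rg$lesionIntensity),
        backgroundIntensity = drawFromRange(rg$backgroundIntensity),
        textureContrast = drawFromRange(rg$textureContrast %||% 0),
        textureScale = drawFromRange(rg$textureScale %||% 2.5),
        microContrast = drawFromRange(rg$microContrast %||% 0),
        noiseSd = drawFromRange(rg$noiseSd %||% 0),
        hairCount = if (length(rg$hairCount %||% 0L) > 1L)
          sample(rg$hairCount[1]:rg$hairCount[2], 1) else rg$hairCount %||% 0L)
      m <- makeLesionMask(sp, shape, seed = imgSeed)
      out[[i]] <- renderLesion(m, sp, seed = imgSeed, label = classes[k])
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset to disk as PNGs plus a CSV manifest
#'
#' Images are written as 8-bit grayscale PNG, masks as 0/255 PNG, and a
#' manifest CSV with columns `filename, mask_filename, label`.
#'
#' @param dataset list of [LesionImage-class] objects.
#' @param dir output directory (created if absent).
#' @return Invisibly, the manifest `data.frame`.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset), function(i) {
    li <- dataset[[i]]
    fn <- sprintf("img_%04d.png", i)
    mf <- sprintf("mask_%04d.png", i)
    writeGrayPNG(imgData(li), file.path(dir, fn))
    writeGrayPNG(maskData(li) * 255, file.path(dir, mf))
    data.frame(filename = fn, mask_filename = mf, label = imgLabel(li),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
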
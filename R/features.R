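#' LBP configuration
#'
#' @param neighbors number of sampling points `P` on the circle (default 8).
#' @param radii strictly increasing positive radii `R` (default `c(1, 2, 3)`).
#' @param uniform logical, map codes to the 59-bin uniform-pattern
#'   histogram (58 uniform codes + 1 catch-all) for `P = 8` (default TRUE).
#' @return List of class `"LBPConfig"`.
#' @export
lbpConfig <- function(neighbors = 8L, radii = c(1, 2, 3), uniform = TRUE) {
  if (neighbors < 4L) stop("neighbors must be >= 4", call. = FALSE)
  if (any(radii <= 0) || any(diff(radii) <= 0))
    stop("radii must be positive and strictly increasing", call. = FALSE)
  structure(list(neighbors = as.integer(neighbors), radii = radii,
                 uniform = uniform),
            class = "LBPConfig")
}

#' GLCM configuration
#'
#' @param levels gray-level quantization (>= 2, default 8): gray values in
#'   \[0, 255\] are binned into `levels` equal-width levels `0..levels-1`.
#' @param distances positive integer offsets (default `c(1, 2, 3)`).
#' @param angles offsets directions in degrees (default
#'   `c(0, 45, 90, 135)`, averaged).
#' @param symmetric logical, symmetrize the matrix (default TRUE).
#' @param normalized logical, normalize to sum 1 (default TRUE).
#' @return List of class `"GLCMConfig"`.
#' @export
glcmConfig <- function(levels = 8L, distances = c(1L, 2L, 3L),
                       angles = c(0, 45, 90, 135), symmetric = TRUE,
                       normalized = TRUE) {
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  if (any(distances < 1) || any(distances != round(distances)))
    stop("distances must be positive integers", call. = FALSE)
  structure(list(levels = as.integer(levels),
                 distances = as.integer(distances), angles = angles,
                 symmetric = symmetric, normalized = normalized),
            class = "GLCMConfig")
}

# Circular sampling offsets (row, col) for P points at radius R; p = 0
# starts on the positive column axis and proceeds counterclockwise.
lbpOffsets <- function(P, R) {
  a <- 2 * pi * (0:(P - 1)) / P
  dr <- -R * sin(a)
  dc <- R * cos(a)
  # snap near-integer offsets so exact-grid samples need no interpolation
  dr <- ifelse(abs(dr - round(dr)) < 1e-9, round(dr), dr)
  dc <- ifelse(abs(dc - round(dc)) < 1e-9, round(dc), dc)
  cbind(dr = dr, dc = dc)
}

bilinearAt <- function(image, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, nrow(image)); c1 <- pmin(c0 + 1, ncol(image))
  (1 - fr) * (1 - fc) * image[cbind(r0, c0)] +
    (1 - fr) * fc * image[cbind(r0, c1)] +
    fr * (1 - fc) * image[cbind(r1, c0)] +
    fr * fc * image[cbind(r1, c1)]
}

#' LBP code of a single patch
#'
#' The code is `sum_p s(g_p - g_c) * 2^p` over the `P` circular neighbours
#' at radius `R` (bilinear interpolation at non-integer coordinates), with
#' `s(x) = 1` if `x >= 0` and `0` otherwise.
#'
#' @param window `(2R+1) x (2R+1)` gray patch centred on the pixel.
#' @param P number of sampling points.
#' @param R circle radius.
#' @return Integer code in `[0, 2^P - 1]`.
#' @examples
#' lbpCode(matrix(5, 3, 3), P = 8, R = 1)   # flat patch -> 255
#' @export
lbpCode <- function(window, P = 8L, R = 1) {
  need <- 2 * ceiling(R) + 1
  if (nrow(window) < need || ncol(window) < need)
    stop("window must be at least ", need, " x ", need, " for R = ", R,
         call. = FALSE)
  ctr <- (dim(window) + 1) / 2
  off <- lbpOffsets(P, R)
  g <- bilinearAt(window, ctr[1] + off[, "dr"], ctr[2] + off[, "dc"])
  gc <- window[ctr[1], ctr[2]]
  # s(0) = 1: a small tolerance keeps exact ties robust to the rounding of
  # the bilinear weights
  sum(as.numeric(g >= gc - 1e-7) * 2^(0:(P - 1)))
}

# Number of 0/1 transitions around the circular 8-bit code.
circularTransitions <- function(code, P) {
  bits <- as.integer(intToBits(code))[seq_len(P)]
  sum(bits != c(bits[-1], bits[1]))
}

# Map each code 0..2^P-1 to its uniform-pattern bin: uniform codes
# (<= 2 transitions) get bins 1..(P*(P-1)+2) in ascending code order,
# everything else falls into the final catch-all bin.
uniformMapping <- function(P) {
  codes <- 0:(2^P - 1)
  tr <- vapply(codes, circularTransitions, integer(1), P = P)
  uni <- codes[tr <= 2L]
  nBins <- length(uni) + 1L
  map <- rep.int(nBins, 2^P)
  map[uni + 1L] <- seq_along(uni)
  list(map = map, nBins = nBins)
}

# Vectorized LBP code image over the region where the window fits;
# returns a matrix with NA outside the valid interior.
lbpCodeImage <- function(image, P, R) {
  nr <- nrow(image); nc <- ncol(image)
  h <- ceiling(R)
  if (nr < 2 * h + 1 || nc < 2 * h + 1)
    stop("image too small for LBP radius ", R, call. = FALSE)
  rows <- (h + 1):(nr - h); cols <- (h + 1):(nc - h)
  ctr <- image[rows, cols, drop = FALSE]
  off <- lbpOffsets(P, R)
  code <- matrix(0, length(rows), length(cols))
  for (p in seq_len(P)) {
    dr <- off[p, "dr"]; dc <- off[p, "dc"]
    r0 <- floor(dr); c0 <- floor(dc)
    fr <- dr - r0; fc <- dc - c0
    # upper interpolation neighbours clamped: their weight is 0 whenever
    # the offset is integral, but the subscript must stay in range
    ru <- pmin(rows + r0 + 1, nr); cu <- pmin(cols + c0 + 1, nc)
    gp <- (1 - fr) * (1 - fc) * image[rows + r0, cols + c0, drop = FALSE] +
      (1 - fr) * fc * image[rows + r0, cu, drop = FALSE] +
      fr * (1 - fc) * image[ru, cols + c0, drop = FALSE] +
      fr * fc * image[ru, cu, drop = FALSE]
    code <- code + (gp >= ctr - 1e-7) * 2^(p - 1)
  }
  out <- matrix(NA_real_, nr, nc)
  out[rows, cols] <- code
  out
}

#' Uniform LBP histograms of an ROI, one per radius
#'
#' Codes are computed at every ROI pixel whose sampling window fits inside
#' the image, mapped to the 59 uniform-pattern bins (for `P = 8`), and the
#' histogram is normalized to sum to 1.
#'
#' @param image 2-D gray matrix.
#' @param roi binary mask (1 = lesion); must be nonempty.
#' @param cfg an [lbpConfig()].
#' @return Named list of normalized histograms, one per radius
#'   (`r1`, `r2`, ...).
#' @export
lbpHistogram <- function(image, roi, cfg = lbpConfig()) {
  roi <- asBinary(roi)
  if (sum(roi) == 0) stop("ROI is empty", call. = FALSE)
  P <- cfg$neighbors
  um <- if (cfg$uniform) uniformMapping(P) else
    list(map = seq_len(2^P), nBins = 2^P)
  out <- lapply(cfg$radii, function(R) {
    codes <- lbpCodeImage(image, P, R)
    sel <- roi == 1 & !is.na(codes)
    if (!any(sel))
      stop("ROI too small for LBP radius ", R,
           " (no pixel with a full sampling window)", call. = FALSE)
    bins <- um$map[codes[sel] + 1L]
    h <- tabulate(bins, nbins = um$nBins)
    h / sum(h)
  })
  names(out) <- paste0("r", cfg$radii)
  out
}

glcmAngleOffset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported GLCM angle ", angle, call. = FALSE))
}

quantizeGray <- function(image, levels) {
  q <- floor(image * levels / 256)
  pmin(pmax(q, 0), levels - 1)
}

#' Gray-level co-occurrence matrix of an ROI
#'
#' Counts co-occurrences of quantized gray pairs at the stated offset, both
#' pixels inside the ROI; symmetrized (matrix + transpose) and normalized to
#' sum to 1 when the config flags are set.
#'
#' @param image 2-D gray matrix in \[0, 255\].
#' @param roi binary mask.
#' @param distance positive integer offset length.
#' @param angle offset direction in degrees (0, 45, 90 or 135).
#' @param cfg a [glcmConfig()].
#' @return `levels x levels` matrix.
#' @export
glcmMatrix <- function(image, roi, distance, angle, cfg = glcmConfig()) {
  roi <- asBinary(roi)
  L <- cfg$levels
  q <- quantizeGray(image, L)
  off <- glcmAngleOffset(angle, as.integer(distance))
  nr <- nrow(image); nc <- ncol(image)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rsrc <- rs[rs + off[1] >= 1 & rs + off[1] <= nr]
  csrc <- cs[cs + off[2] >= 1 & cs + off[2] <= nc]
  if (length(rsrc) == 0 || length(csrc) == 0)
    stop("no valid pixel pairs for distance ", distance, " at angle ", angle,
         call. = FALSE)
  ok <- roi[rsrc, csrc, drop = FALSE] == 1 &
    roi[rsrc + off[1], csrc + off[2], drop = FALSE] == 1
  if (!any(ok))
    stop("empty co-occurrence set: ROI has no pixel pairs at distance ",
         distance, ", angle ", angle, call. = FALSE)
  qi <- q[rsrc, csrc, drop = FALSE][ok]
  qj <- q[rsrc + off[1], csrc + off[2], drop = FALSE][ok]
  cm <- matrix(tabulate(qi * L + qj + 1L, nbins = L * L), L, L, byrow = TRUE)
  if (cfg$symmetric) cm <- cm + t(cm)
  if (cfg$normalized) cm <- cm / sum(cm)
  cm
}

#' The 13 GLCM texture statistics
#'
#' All statistics are defined on the normalized co-occurrence matrix
#' `p(i, j)` over gray levels `i, j = 0..levels-1` and its gray-level
#' marginal `p_x(i) = sum_j p(i, j)`: contrast, correlation, energy,
#' homogeneity, dissimilarity, mean, standard deviation, variance, entropy
#' (bits), RMS, smoothness, skewness and kurtosis. Degenerate cases
#' (`sigma_x = 0`) return 0 for correlation, skewness and kurtosis.
#'
#' @param matrix normalized GLCM (sums to 1).
#' @param tol tolerance for the normalization check.
#' @return Named numeric vector of length 13.
#' @export
glcmFeatures <- function(matrix, tol = 1e-8) {
  if (abs(sum(matrix) - 1) > tol)
    stop("glcmFeatures expects a normalized matrix (sum = 1)", call. = FALSE)
  L <- nrow(matrix)
  v <- 0:(L - 1)
  I <- base::matrix(v, L, L)
  J <- t(I)
  p <- matrix
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(v * px); muy <- sum(v * py)
  sx <- sqrt(sum((v - mux)^2 * px)); sy <- sqrt(sum((v - muy)^2 * py))
  pe <- p[p > 0]
  corr <- if (sx > 0 && sy > 0)
    sum((I - mux) * (J - muy) * p) / (sx * sy) else 0
  c(contrast      = sum((I - J)^2 * p),
    correlation   = corr,
    energy        = sum(p^2),
    homogeneity   = sum(p / (1 + (I - J)^2)),
    dissimilarity = sum(abs(I - J) * p),
    mean          = mux,
    sd            = sx,
    variance      = sx^2,
    entropy       = -sum(pe * log2(pe)),
    rms           = sqrt(sum(v^2 * px)),
    smoothness    = 1 - 1 / (1 + sx^2),
    skewness      = if (sx > 0) sum(((v - mux) / sx)^3 * px) else 0,
    kurtosis      = if (sx > 0) sum(((v - mux) / sx)^4 * px) else 0)
}

# Angle-averaged normalized GLCM for one distance.
glcmAveraged <- function(image, roi, distance, cfg = glcmConfig()) {
  mats <- lapply(cfg$angles, function(a)
    glcmMatrix(image, roi, distance, a, cfg))
  Reduce(`+`, mats) / length(mats)
}

#' Fuse LBP and GLCM blocks into the 216-dimensional descriptor
#'
#' Concatenation in fixed order: `[lbp_r1 (59), lbp_r2 (59), lbp_r3 (59),
#' glcm_d1 (13), glcm_d2 (13), glcm_d3 (13)]`, 216 named values. Errors if
#' the component counts do not total 216.
#'
#' @param lbp per-radius histogram list from [lbpHistogram()].
#' @param glcmStats per-distance list of 13-vectors from [glcmFeatures()].
#' @return Named numeric vector of length 216.
#' @export
fuseFeatures <- function(lbp, glcmStats) {
  lbpVals <- unlist(lapply(names(lbp), function(r) {
    h <- lbp[[r]]
    stats::setNames(h, sprintf("lbp_%s_bin%02d", r, seq_along(h)))
  }))
  glcmVals <- unlist(lapply(names(glcmStats), function(d) {
    s <- glcmStats[[d]]
    stats::setNames(s, sprintf("glcm_%s_%s", d, names(s)))
  }))
  out <- c(lbpVals, glcmVals)
  if (length(out) != 216L)
    stop("feature fusion expected 216 values, found ", length(out),
         " (LBP ", length(lbpVals), " + GLCM ", length(glcmVals), ")",
         call. = FALSE)
  if (anyDuplicated(names(out)))
    stop("duplicate feature names after fusion", call. = FALSE)
  if (!all(is.finite(out)))
    stop("non-finite feature values", call. = FALSE)
  out
}

#' Extract the hybrid 216-dimensional LBP + GLCM descriptor of an ROI
#'
#' Uniform LBP histograms (P = 8, radii 1, 2, 3; 59 bins each) and
#' angle-averaged GLCM statistics (13 statistics at distances 1, 2, 3)
#' computed on the segmented lesion region and fused into one ordered,
#' named 216-vector.
#'
#' @param image 2-D gray matrix in \[0, 255\].
#' @param roi binary lesion mask from segmentation.
#' @param lbpCfg an [lbpConfig()].
#' @param glcmCfg a [glcmConfig()].
#' @return Named numeric vector of length 216.
#' @examples
#' img <- matrix(runif(32 * 32, 0, 255), 32, 32)
#' roi <- matrix(1, 32, 32)
#' length(extractFeatures(img, roi))
#' @export
extractFeatures <- function(image, roi, lbpCfg = lbpConfig(),
                            glcmCfg = glcmConfig()) {
  stopIfNot2D(image)
  roi <- asBinary(roi)
  lbp <- lbpHistogram(image, roi, lbpCfg)
  gs <- lapply(glcmCfg$distances, function(d)
    glcmFeatures(glcmAveraged(image, roi, d, glcmCfg)))
  names(gs) <- paste0("d", glcmCfg$distances)
  fuseFeatures(lbp, gs)
}

#' Feature matrix for a list of images
#'
#' Segmented masks are taken from each image's own mask slot unless a list
#' of ROI masks is supplied.
#'
#' @param dataset list of [LesionImage-class] objects.
#' @param rois optional list of binary masks (e.g. from [segmentLesion()]).
#' @param lbpCfg,glcmCfg feature configurations.
#' @return Numeric matrix (samples x 216) with feature column names and a
#'   `labels` attribute.
#' @export
extractFeatureMatrix <- function(dataset, rois = NULL,
                                 lbpCfg = lbpConfig(),
                                 glcmCfg = glcmConfig()) {
  rows <- lapply(seq_along(dataset), function(i) {
    li <- dataset[[i]]
    roi <- if (is.null(rois)) maskData(li) else rois[[i]]
    extractFeatures(imgData(li), roi, lbpCfg, glcmCfg)
  })
  X <- do.call(rbind, rows)
  attr(X, "labels") <- vapply(dataset, imgLabel, character(1))
  X
}
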
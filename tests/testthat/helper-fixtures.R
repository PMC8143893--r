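# Shared fixtures: all test data is generated in code.

# One synthetic lesion with known ground truth; returns the raw render,
# the Gaussian-smoothed image and the true mask.
makeTestLesion <- function(seed = 1, noiseSd = 0, irregularity = 0,
                           textureContrast = 0, shape = c(128, 128),
                           semiAxes = c(25, 18), lesion = 60,
                           background = 180, hairCount = 0L) {
  sp <- lesionSpec(center = shape / 2, semiAxes = semiAxes, rotation = 0.4,
                   irregularityAmplitude = irregularity,
                   irregularityHarmonics = if (irregularity > 0) 3L else 0L,
                   lesionIntensity = lesion, backgroundIntensity = background,
                   textureContrast = textureContrast, noiseSd = noiseSd,
                   hairCount = hairCount)
  m <- makeLesionMask(sp, shape, seed = seed)
  li <- renderLesion(m, sp, seed = seed)
  list(spec = sp, mask = m, raw = imgData(li),
       smooth = smoothImage(imgData(li)))
}

# Independent brute-force oracles (simple double loops, no shared code with
# the implementation paths they check).

oracleRegionMeans <- function(image, phi, M, epsilon) {
  num1 <- den1 <- num2 <- den2 <- 0
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    H <- 0.5 * (1 + (2 / pi) * atan(phi[i, j] / epsilon))
    num1 <- num1 + image[i, j] * H * M[i, j]
    den1 <- den1 + H * M[i, j]
    num2 <- num2 + image[i, j] * (1 - H) * M[i, j]
    den2 <- den2 + (1 - H) * M[i, j]
  }
  c(c1 = num1 / den1, c2 = num2 / den2)
}

oracleFittedImage <- function(c1, c2, phi, epsilon) {
  out <- phi * 0
  for (i in seq_len(nrow(phi))) for (j in seq_len(ncol(phi))) {
    H <- 0.5 * (1 + (2 / pi) * atan(phi[i, j] / epsilon))
    out[i, j] <- c1 * H + c2 * (1 - H)
  }
  out
}

oracleSpf <- function(image, fitted, mask) {
  dev <- image - fitted
  mx <- max(abs(dev))
  out <- image * 0
  if (mx == 0) return(out)
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    out[i, j] <- if (image[i, j] == 0) 0 else
      dev[i, j] * mask[i, j] / mx
  }
  out
}

# single explicit evolution step, loops + naive reflective convolution
oracleEvolveStep <- function(image, phi, mask, cfg) {
  eps <- cfg$meansEpsilon
  rm <- oracleRegionMeans(image, phi, matrix(1, nrow(phi), ncol(phi)), eps)
  fitted <- oracleFittedImage(rm["c1"], rm["c2"], phi, cfg$epsilon)
  spf <- oracleSpf(image, fitted, mask)
  nr <- nrow(phi); nc <- ncol(phi)
  cl <- function(i, n) min(max(i, 1), n)
  gr <- gc <- phi * 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    gr[i, j] <- (phi[cl(i + 1, nr), j] - phi[cl(i - 1, nr), j]) / 2
    gc[i, j] <- (phi[i, cl(j + 1, nc)] - phi[i, cl(j - 1, nc)]) / 2
  }
  mag <- pmax(sqrt(gr^2 + gc^2), 1e-10)
  fr <- spf * gr / mag; fc <- spf * gc / mag
  div <- phi * 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    div[i, j] <- (fr[cl(i + 1, nr), j] - fr[cl(i - 1, nr), j]) / 2 +
      (fc[i, cl(j + 1, nc)] - fc[i, cl(j - 1, nc)]) / 2
  }
  dirac <- cfg$epsilon / (pi * (phi^2 + cfg$epsilon^2))
  out <- phi + cfg$dt * (cfg$lambdaWeight * div + cfg$nuWeight * spf * dirac)
  if (cfg$regSigma > 0) {
    h <- ceiling(3 * cfg$regSigma)
    x <- -h:h
    k1 <- exp(-x^2 / (2 * cfg$regSigma^2)); k1 <- k1 / sum(k1)
    refl <- function(i, n) {
      while (i < 1 || i > n) {
        if (i < 1) i <- 1 - i
        if (i > n) i <- 2 * n + 1 - i
      }
      i
    }
    sm <- out * 0
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      acc <- 0
      for (a in x) for (b in x)
        acc <- acc + k1[a + h + 1] * k1[b + h + 1] *
          out[refl(i + a, nr), refl(j + b, nc)]
      sm[i, j] <- acc
    }
    out <- sm
  }
  out
}

# LBP code with explicit loops and bilinear interpolation
oracleLbpCode <- function(image, r, c, P, R) {
  gc <- image[r, c]
  code <- 0
  for (p in 0:(P - 1)) {
    a <- 2 * pi * p / P
    dr <- -R * sin(a); dc <- R * cos(a)
    if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
    if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
    rr <- r + dr; cc <- c + dc
    r0 <- floor(rr); c0 <- floor(cc)
    fr <- rr - r0; fc <- cc - c0
    r1 <- min(r0 + 1, nrow(image)); c1 <- min(c0 + 1, ncol(image))
    g <- (1 - fr) * (1 - fc) * image[r0, c0] + (1 - fr) * fc * image[r0, c1] +
      fr * (1 - fc) * image[r1, c0] + fr * fc * image[r1, c1]
    if (g >= gc - 1e-7) code <- code + 2^p
  }
  code
}

# number of circular 0/1 transitions of an 8-bit code, via string rotation
oracleTransitions <- function(code, P = 8) {
  bits <- rev(as.integer(intToBits(code))[1:P])
  rot <- c(bits[-1], bits[1])
  sum(bits != rot)
}

# GLCM by explicit pair enumeration
oracleGlcm <- function(image, roi, distance, angle, levels,
                       symmetric = TRUE, normalized = TRUE) {
  q <- pmin(pmax(floor(image * levels / 256), 0), levels - 1)
  off <- switch(as.character(angle),
                "0" = c(0, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0), "135" = c(-distance, -distance))
  cm <- matrix(0, levels, levels)
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 < 1 || i2 > nrow(image) || j2 < 1 || j2 > ncol(image)) next
    if (roi[i, j] != 1 || roi[i2, j2] != 1) next
    cm[q[i, j] + 1, q[i2, j2] + 1] <- cm[q[i, j] + 1, q[i2, j2] + 1] + 1
  }
  if (symmetric) cm <- cm + t(cm)
  if (normalized) cm <- cm / sum(cm)
  cm
}

# AUC as the concordance probability over all positive/negative pairs,
# ties counted one half
oracleAuc <- function(scores, actual) {
  pos <- scores[actual == 1]; neg <- scores[actual == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
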
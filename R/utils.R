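## Internal helpers shared across modules.

# Derive a per-stage RNG seed from the pipeline's single global seed.
# Stages are numbered; the derivation is seed + stageIndex (kept < 2^31).
deriveSeed <- function(seed, stageIndex) {
  s <- (as.numeric(seed) + as.numeric(stageIndex)) %% 2147483647
  as.integer(s)
}

stopIfNot2D <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a 2-D numeric matrix", call. = FALSE)
  invisible(x)
}

asBinary <- function(mask) {
  matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
}

# Shift a matrix by (dr, dc) with replicate (clamped-index) boundary.
shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Largest 8-connected component of a binary mask, by iterative label
# propagation (each foreground pixel takes the max label among itself and
# its 8 neighbours until a fixed point).
largestComponent <- function(mask) {
  mask <- asBinary(mask)
  if (sum(mask) == 0) return(mask)
  lab <- matrix(seq_along(mask), nrow(mask), ncol(mask)) * mask
  repeat {
    nb <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- pmax(nb, shiftMat(lab, dr, dc))
    }
    nb <- nb * mask
    if (identical(nb, lab)) break
    lab <- nb
  }
  ids <- lab[lab > 0]
  tab <- table(ids)
  keep <- as.numeric(names(tab)[which.max(tab)])
  asBinary(lab == keep)
}
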
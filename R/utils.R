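# Internal helpers shared across modules: seeded evaluation, grid geometry,
# separable Gaussian smoothing and 3D connected-component labelling.

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed; keeps values in 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 99991) %% 2147483629)
}

checkMask <- function(mask, dims, what = "mask") {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!identical(dim(mask), as.integer(dims)))
    stop("'", what, "' must share the volume grid (dim mismatch)",
         call. = FALSE)
  mask
}

# World (mm) coordinates of voxel centres for 0-based indices.
voxelCenters <- function(idx, spacing, origin = c(0, 0, 0)) {
  sweep(sweep(idx, 2, spacing, "*"), 2, origin, "+")
}

# 0-based (x, y, z) voxel indices of the TRUE entries of a 3D mask.
maskIndices <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  storage.mode(w) <- "double"
  w - 1
}

gaussianKernel1d <- function(sigmaVox) {
  if (sigmaVox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigmaVox))
  k <- exp(-((-r:r)^2) / (2 * sigmaVox^2))
  k / sum(k)
}

# Convolve a 3D array along one axis with a 1D kernel (replicate-padding at
# the boundary so flat fields stay flat).
convolveAxis <- function(a, kernel, axis) {
  if (length(kernel) == 1L) return(a)
  d <- dim(a)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  r <- (length(kernel) - 1L) %/% 2L
  padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                  m[rep(dp[1], r), , drop = FALSE])
  out <- matrix(0, nrow = dp[1], ncol = ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * padded[j:(j + dp[1] - 1L), , drop = FALSE]
  }
  aperm(array(out, dp), order(perm))
}

# Separable Gaussian blur with a physically specified sigma (mm) on an
# anisotropic grid.
gaussianSmooth <- function(a, sigmaMm, spacing) {
  if (sigmaMm <= 0) return(a)
  for (ax in 1:3) {
    a <- convolveAxis(a, gaussianKernel1d(sigmaMm / spacing[ax]), ax)
  }
  a
}

# Offsets of the 26- or 6-neighbourhood in 3D.
neighborOffsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- rowSums(abs(g)) > 0
  g <- g[keep, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  else if (connectivity != 26L) stop("connectivity must be 6 or 26")
  g
}

# Label connected components of a 3D logical array by iterative minimum-label
# propagation over the chosen neighbourhood. Component labels are then
# renumbered 1..n in first-voxel order (column-major), which is deterministic.
labelComponents <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0, dim = d)
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(list(labels = lab, n = 0L))
  offs <- neighborOffsets(connectivity)
  dp <- d + 2L
  pad <- array(0, dim = dp)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- lab
  core <- list(2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L))
  repeat {
    cur <- pad[core[[1]], core[[2]], core[[3]]]
    best <- cur
    for (i in seq_len(nrow(offs))) {
      o <- offs[i, ]
      nb <- pad[core[[1]] + o[1], core[[2]] + o[2], core[[3]] + o[3]]
      upd <- nb > 0 & cur > 0 & nb < best
      best[upd] <- nb[upd]
    }
    if (all(best == cur)) break
    pad[core[[1]], core[[2]], core[[3]]] <- best
  }
  lab <- pad[core[[1]], core[[2]], core[[3]]]
  ids <- unique(lab[lab > 0])            # column-major first-voxel order
  relabel <- integer(max(ids))
  relabel[ids] <- seq_along(ids)
  lab[lab > 0] <- relabel[lab[lab > 0]]
  list(labels = lab, n = length(ids))
}
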
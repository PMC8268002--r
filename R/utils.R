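# shared internal helpers

# run code under a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Reproducible per-case seed derived from a master seed and an index.
# Exact in double arithmetic (products stay far below 2^53) and always
# below 2^31 so the result is a valid R integer seed.
deriveSeed <- function(master, index) {
  m <- 2147483647
  x <- (abs(as.numeric(master)) %% m) * 48271 + as.numeric(index) * 104729
  as.integer(x %% m)
}

# Separable Gaussian smoothing of a 3D array; sigma in mm, per-axis kernels
# built from the voxel spacing. Border handling: replicate (adequate here
# because callers smooth zero-padded or interior sub-volumes).
gaussianSmooth3d <- function(a, sigmaMm, spacingMm = c(1, 1, 1)) {
  d <- dim(a)
  for (ax in 1:3) {
    sig <- sigmaMm / spacingMm[ax]
    if (sig <= 0) next
    r <- max(1L, as.integer(ceiling(3 * sig)))
    k <- dnorm(-r:r, sd = sig)
    k <- k / sum(k)
    out <- array(0, d)
    n <- d[ax]
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    for (s in -r:r) {
      w <- k[s + r + 1L]
      src <- idx
      src[[ax]] <- pmin(pmax(seq_len(n) - s, 1L), n)
      out <- out + w * a[src[[1]], src[[2]], src[[3]], drop = FALSE]
    }
    a <- out
  }
  a
}

# voxel-centre physical coordinates along one axis (1-based index -> mm)
axisCoords <- function(n, sp) (seq_len(n) - 1) * sp

# 0.5-level iso-surface area and volume of a binary mask. The mask is
# padded, converted to an indicator field, Gaussian-smoothed (sigma in
# voxels) for an anti-aliased surface, and meshed by marching tetrahedra.
# Thin structures that a smoothed field would erase fall back to the
# midpoint binary mesh.
maskMesh <- function(mask, spacing, sigmaVox = 0.8) {
  mask <- cropToBoundingBox(mask)
  d <- dim(mask)
  pad <- 4L
  f <- array(0, d + 2L * pad)
  f[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask)
  sm <- gaussianSmooth3d(f, sigmaVox, c(1, 1, 1))
  if (max(sm) < 0.7) sm <- f  # thin object: mesh the raw indicator
  .mesh_area_volume(sm, dim(sm), spacing, 0.5)
}

# smallest sub-array containing all TRUE voxels (plain logical array in/out)
cropToBoundingBox <- function(mask, growBy = 0L) {
  d <- dim(mask)
  w <- which(mask)
  if (!length(w)) return(mask)
  i <- (w - 1L) %% d[1] + 1L
  j <- ((w - 1L) %/% d[1]) %% d[2] + 1L
  k <- (w - 1L) %/% (d[1] * d[2]) + 1L
  lo <- pmax(c(min(i), min(j), min(k)) - growBy, 1L)
  hi <- pmin(c(max(i), max(j), max(k)) + growBy, d)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
}

# index ranges of the bounding box, optionally grown, clamped to the grid
boundingBoxRanges <- function(mask, growBy = 0L) {
  d <- dim(mask)
  w <- which(mask)
  i <- (w - 1L) %% d[1] + 1L
  j <- ((w - 1L) %/% d[1]) %% d[2] + 1L
  k <- (w - 1L) %/% (d[1] * d[2]) + 1L
  lo <- pmax(c(min(i), min(j), min(k)) - growBy, 1L)
  hi <- pmin(c(max(i), max(j), max(k)) + growBy, d)
  list(lo = lo, hi = hi)
}
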
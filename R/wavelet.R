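# Single-level 3D discrete wavelet transform (Coiflet-1, periodized).
# The transform is applied as an explicit orthogonal matrix per axis, so
# orthogonality -- and hence exact energy conservation across the eight
# sub-bands -- holds by construction. Each band can be reconstructed at
# the original resolution (band-limited inverse with the other bands
# zeroed), which keeps masks applicable unchanged; the eight
# reconstructions sum to the original image.

# Coiflet-1 analysis filters (orthonormal)
.coif1_lo <- c(-0.015655728135791993, -0.07273261951252645,
               0.3848648468648578, 0.8525720202116004,
               0.3378976624574818, -0.07273261951252645)
.coif1_hi <- c(0.07273261951252645, 0.3378976624574818,
               -0.8525720202116004, 0.3848648468648578,
               0.07273261951252645, -0.015655728135791993)

# n x n orthogonal single-level analysis matrix for even n >= filter length
dwtMatrix <- function(n) {
  if (n %% 2L != 0L) stop("dwtMatrix needs an even length")
  if (n < length(.coif1_lo))
    stop(sprintf("axis of length %d is shorter than the wavelet filter (%d)",
                 n, length(.coif1_lo)))
  W <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    pos <- ((2L * (k - 1L) + seq_along(.coif1_lo) - 1L) %% n) + 1L
    for (m in seq_along(.coif1_lo)) {
      W[k, pos[m]] <- W[k, pos[m]] + .coif1_lo[m]
      W[n / 2 + k, pos[m]] <- W[n / 2 + k, pos[m]] + .coif1_hi[m]
    }
  }
  W
}

# multiply M (n x n) along axis ax of 3D array a
applyAxis <- function(a, M, ax) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  y <- M %*% matrix(ap, d[ax])
  dim(y) <- d[perm]
  aperm(y, order(perm))
}

padEven <- function(a) {
  d <- dim(a)
  padded <- d %% 2L
  if (!any(padded == 1L)) return(list(a = a, orig = d))
  nd <- d + padded
  out <- array(0, nd)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
  # replicate the last slice along odd axes
  if (padded[1]) out[nd[1], , ] <- out[d[1], , ]
  if (padded[2]) out[, nd[2], ] <- out[, d[2], ]
  if (padded[3]) out[, , nd[3]] <- out[, , d[3]]
  list(a = out, orig = d)
}

.bandNames <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

#' Single-level 3D wavelet decomposition
#'
#' Returns the eight coefficient sub-arrays (all low/high-pass axis
#' combinations, decimated) of a periodized orthogonal Coiflet-1
#' transform. Because the basis is orthonormal, total coefficient energy
#' equals the input energy exactly.
#'
#' @param image a [CtVolume] or 3D numeric array with even dimensions of
#'   at least the filter length (6) per axis.
#' @return Named list of eight arrays (`LLL` ... `HHH`); band letters
#'   follow the axis order (1, 2, 3).
#' @export
waveletDecompose <- function(image) {
  a <- if (is(image, "CtVolume")) image@data else image
  d <- dim(a)
  if (any(d %% 2L != 0L))
    stop("waveletDecompose requires even dimensions; use waveletBands() for padding")
  Ws <- lapply(d, dwtMatrix)
  t3 <- applyAxis(applyAxis(applyAxis(a, Ws[[1]], 1), Ws[[2]], 2), Ws[[3]], 3)
  half <- d %/% 2L
  sel <- function(n, hi) if (hi) (n %/% 2L + 1L):n else seq_len(n %/% 2L)
  out <- vector("list", 8)
  for (b in 0:7) {
    h <- c(bitwAnd(b, 4L) > 0, bitwAnd(b, 2L) > 0, bitwAnd(b, 1L) > 0)
    out[[b + 1]] <- t3[sel(d[1], h[1]), sel(d[2], h[2]), sel(d[3], h[3]),
                       drop = FALSE]
  }
  names(out) <- .bandNames
  out
}

#' Eight wavelet band volumes at original resolution
#'
#' Decomposes the image (padding odd axes by edge replication, cropped
#' away afterwards) and reconstructs each of the eight sub-bands
#' separately at the input resolution, so VOI masks apply unchanged. The
#' reconstructions of the eight bands sum to the original image.
#'
#' @param image a [CtVolume] or 3D numeric array; every axis must be at
#'   least the filter length (6).
#' @return Named list of eight [CtVolume]s (or arrays, matching the
#'   input type).
#' @export
waveletBands <- function(image) {
  isVol <- is(image, "CtVolume")
  a <- if (isVol) image@data else image
  short <- which(dim(a) < length(.coif1_lo))
  if (length(short))
    stop(sprintf("volume too small for the wavelet filter along axis %s",
                 paste(short, collapse = ", ")))
  p <- padEven(a)
  d <- dim(p$a)
  Ws <- lapply(d, dwtMatrix)
  t3 <- applyAxis(applyAxis(applyAxis(p$a, Ws[[1]], 1), Ws[[2]], 2),
                  Ws[[3]], 3)
  sel <- function(n, hi) if (hi) (n %/% 2L + 1L):n else seq_len(n %/% 2L)
  out <- vector("list", 8)
  for (b in 0:7) {
    h <- c(bitwAnd(b, 4L) > 0, bitwAnd(b, 2L) > 0, bitwAnd(b, 1L) > 0)
    masked <- array(0, d)
    masked[sel(d[1], h[1]), sel(d[2], h[2]), sel(d[3], h[3])] <-
      t3[sel(d[1], h[1]), sel(d[2], h[2]), sel(d[3], h[3])]
    rec <- applyAxis(applyAxis(applyAxis(masked, t(Ws[[1]]), 1),
                               t(Ws[[2]]), 2), t(Ws[[3]]), 3)
    rec <- rec[seq_len(p$orig[1]), seq_len(p$orig[2]), seq_len(p$orig[3]),
               drop = FALSE]
    out[[b + 1]] <- if (isVol) ctVolume(rec, image@spacing, image@origin)
                    else rec
  }
  names(out) <- .bandNames
  out
}
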
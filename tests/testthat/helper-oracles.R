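# Brute-force oracles, written directly from the definitions and kept
# independent of the implementation paths they check.

# distance (mm) from every voxel to the nearest TRUE voxel: O(n * m) scan
oracleDistance <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  w <- which(mask)
  out <- array(Inf, d)
  if (!length(w)) return(out)
  coords <- function(idx) cbind(((idx - 1L) %% d[1]) * spacing[1],
                                (((idx - 1L) %/% d[1]) %% d[2]) * spacing[2],
                                ((idx - 1L) %/% (d[1] * d[2])) * spacing[3])
  src <- coords(w)
  all <- coords(seq_len(prod(d)))
  for (v in seq_len(nrow(all))) {
    dd <- sqrt(colSums((t(src) - all[v, ])^2))
    out[v] <- min(dd)
  }
  out
}

# same inclusive-boundary tolerance convention as the package: voxels at
# exactly d mm are included, robust to floating-point spacing arithmetic
oracleDilate <- function(mask, d, spacing = c(1, 1, 1)) {
  oracleDistance(mask, spacing) <= d + 1e-9 * (d + 1)
}

oracleErode <- function(mask, d, spacing = c(1, 1, 1)) {
  mask & !(oracleDistance(!mask, spacing) <= d + 1e-9 * (d + 1))
}

# the 13 unique 3D directions (first non-zero component positive)
oracleDirections <- function() {
  out <- NULL
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dx > 0 || (dx == 0 && dy > 0) || (dx == 0 && dy == 0 && dz > 0))
      out <- rbind(out, c(dx, dy, dz))
  }
  out
}

inGrid <- function(p, d) all(p >= 1L) && all(p <= d)

# symmetric co-occurrence counts by exhaustive pair enumeration
oracleGlcm <- function(grid, ng) {
  d <- dim(grid)
  dirs <- oracleDirections()
  out <- array(0, c(ng, ng, nrow(dirs)))
  for (a in seq_len(nrow(dirs)))
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      li <- grid[i, j, k]
      if (li == 0) next
      p2 <- c(i, j, k) + dirs[a, ]
      if (!inGrid(p2, d)) next
      lj <- grid[p2[1], p2[2], p2[3]]
      if (lj == 0) next
      out[li, lj, a] <- out[li, lj, a] + 1
      out[lj, li, a] <- out[lj, li, a] + 1
    }
  out
}

# run counts by walking every line in every direction
oracleGlrlm <- function(grid, ng) {
  d <- dim(grid)
  dirs <- oracleDirections()
  maxlen <- max(d)
  out <- array(0, c(ng, maxlen, nrow(dirs)))
  for (a in seq_len(nrow(dirs))) {
    dir <- dirs[a, ]
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      prev <- c(i, j, k) - dir
      if (inGrid(prev, d)) next  # not a line start
      pos <- c(i, j, k)
      cur <- 0L
      len <- 0L
      while (inGrid(pos, d)) {
        l <- grid[pos[1], pos[2], pos[3]]
        if (l == cur && l != 0) len <- len + 1L
        else {
          if (cur != 0) out[cur, len, a] <- out[cur, len, a] + 1
          cur <- l
          len <- if (l != 0) 1L else 0L
        }
        pos <- pos + dir
      }
      if (cur != 0) out[cur, len, a] <- out[cur, len, a] + 1
    }
  }
  out
}

# size zones by flood fill over the 26-neighbourhood
oracleGlszm <- function(grid) {
  d <- dim(grid)
  seen <- array(FALSE, d)
  zones <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (s in which(grid != 0)) {
    if (seen[s]) next
    lev <- grid[s]
    stack <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(stack)) {
      c0 <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      ci <- (c0 - 1L) %% d[1] + 1L
      cj <- ((c0 - 1L) %/% d[1]) %% d[2] + 1L
      ck <- (c0 - 1L) %/% (d[1] * d[2]) + 1L
      for (o in seq_len(nrow(offs))) {
        p <- c(ci, cj, ck) + offs[o, ]
        if (!inGrid(p, d)) next
        q <- (p[3] - 1L) * d[1] * d[2] + (p[2] - 1L) * d[1] + p[1]
        if (!seen[q] && grid[q] == lev) {
          seen[q] <- TRUE
          stack <- c(stack, q)
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(lev, size)
  }
  if (!length(zones)) return(data.frame(level = integer(), size = numeric(),
                                        count = numeric()))
  zz <- do.call(rbind, zones)
  agg <- aggregate(list(count = rep(1, nrow(zz))),
                   by = list(level = zz[, 1], size = zz[, 2]), FUN = sum)
  agg[order(agg$level, agg$size), ]
}

# dependence counts (alpha = 0, centre included)
oracleGldm <- function(grid, ng) {
  d <- dim(grid)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  out <- matrix(0, ng, 27)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    l <- grid[i, j, k]
    if (l == 0) next
    dep <- 0L
    for (o in seq_len(nrow(offs))) {
      p <- c(i, j, k) + offs[o, ]
      if (inGrid(p, d) && grid[p[1], p[2], p[3]] == l) dep <- dep + 1L
    }
    out[l, dep + 1L] <- out[l, dep + 1L] + 1
  }
  out
}

# neighbourhood gray-tone counts and difference sums
oracleNgtdm <- function(grid, ng) {
  d <- dim(grid)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  out <- matrix(0, ng, 2)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    l <- grid[i, j, k]
    if (l == 0) next
    vals <- c()
    for (o in seq_len(nrow(offs))) {
      p <- c(i, j, k) + offs[o, ]
      if (inGrid(p, d) && grid[p[1], p[2], p[3]] != 0)
        vals <- c(vals, grid[p[1], p[2], p[3]])
    }
    out[l, 1] <- out[l, 1] + 1
    if (length(vals)) out[l, 2] <- out[l, 2] + abs(l - mean(vals))
  }
  out
}

# AUC by exhaustive positive-negative pair counting (ties half credit)
oracleAuc <- function(scores, labels) {
  x <- scores[labels == "positive"]
  y <- scores[labels == "negative"]
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot / (length(x) * length(y))
}

# small random discretized grid (levels 0 = outside mask)
randomGrid <- function(seed, maxDim = 4L, maxLev = 4L) {
  withr::with_seed(seed, {
    d <- sample(2:maxDim, 3, replace = TRUE)
    g <- array(sample(0:maxLev, prod(d), replace = TRUE), d)
    if (all(g == 0)) g[1] <- 1L
    g
  })
}

# discretizedGrid wrapper around a bare level array
asDisc <- function(grid) {
  structure(list(grid = grid, nLevels = max(grid), dims = dim(grid)),
            class = "discretizedGrid")
}

# a small, quick labeled case shared by several tests
smallSpec <- function(...) {
  phantomSpec(gridShape = c(64L, 64L, 64L), noduleDiameterMm = 10,
              diameterSdMm = 1.5, ...)
}
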
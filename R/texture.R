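# The five gray-level texture families. Matrices are assembled in C++
# over the 26-neighbourhood (13 unique directions, Chebyshev distance 1);
# scalar features follow the standard definitions with 0*log(0) = 0 limit
# conventions so degenerate (single-level) regions yield finite values.
# GLCM and GLRLM features are computed per direction and averaged; GLSZM,
# GLDM and NGTDM are direction-free.

#' Build a texture matrix from a discretized VOI
#'
#' @param disc a `discretizedGrid` from [discretize()].
#' @param kind one of `"glcm"`, `"glrlm"`, `"glszm"`, `"gldm"`, `"ngtdm"`.
#' @return A `textureMatrix` object; the `data` element holds, per kind:
#'   GLCM `ng x ng x 13` symmetric co-occurrence counts; GLRLM
#'   `ng x maxRun x 13` run counts; GLSZM a (level, size, count) table;
#'   GLDM `ng x 27` dependence counts (alpha = 0, dependence size
#'   includes the centre voxel); NGTDM an `ng x 2` matrix of voxel counts
#'   and absolute neighbourhood-difference sums.
#' @export
textureMatrix <- function(disc, kind = c("glcm", "glrlm", "glszm", "gldm",
                                         "ngtdm")) {
  kind <- match.arg(kind)
  stopifnot(inherits(disc, "discretizedGrid"))
  g <- disc$grid
  ng <- disc$nLevels
  data <- switch(kind,
    glcm = .glcm_counts(g, dim(g), ng),
    glrlm = .glrlm_counts(g, dim(g), ng),
    glszm = .glszm_zones(g, dim(g)),
    gldm = .gldm_counts(g, dim(g), ng),
    ngtdm = .ngtdm_sums(g, dim(g), ng))
  structure(list(kind = kind, data = data, nLevels = ng),
            class = "textureMatrix")
}

#' Scalar features of a texture matrix
#'
#' Returns the standard feature set of the family: 24 (GLCM), 16 (GLRLM),
#' 16 (GLSZM), 14 (GLDM) or 5 (NGTDM) named values.
#'
#' @param tm a `textureMatrix`.
#' @return Named numeric vector.
#' @export
textureFeatures <- function(tm) {
  stopifnot(inherits(tm, "textureMatrix"))
  switch(tm$kind,
    glcm = glcmFeatures(tm$data, tm$nLevels),
    glrlm = glrlmFeatures(tm$data, tm$nLevels),
    glszm = glszmFeatures(tm$data, tm$nLevels),
    gldm = gldmFeatures(tm$data, tm$nLevels),
    ngtdm = ngtdmFeatures(tm$data, tm$nLevels))
}

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

# ---- GLCM -----------------------------------------------------------------

glcmFeaturesOne <- function(C, ng) {
  s <- sum(C)
  if (s == 0) return(NULL)
  p <- C / s
  i <- row(p)
  j <- col(p)
  px <- rowSums(p)
  mux <- sum(seq_len(ng) * px)
  sigx2 <- sum((seq_len(ng) - mux)^2 * px)
  sigx <- sqrt(sigx2)
  dif <- abs(i - j)
  pxmy <- vapply(0:(ng - 1), function(k) sum(p[dif == k]), 0)
  smm <- i + j
  pxpy <- vapply(2:(2 * ng), function(k) sum(p[smm == k]), 0)
  DA <- sum((0:(ng - 1)) * pxmy)
  HX <- -sum(xlog2(px))
  HXY <- -sum(xlog2(p))
  ppxy <- outer(px, px)
  HXY1 <- -sum(p * ifelse(ppxy > 0, log2(ppxy), 0))
  HXY2 <- -sum(xlog2(ppxy))
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  corr <- if (sigx2 > 0) (sum(i * j * p) - mux^2) / sigx2 else 1
  # MCC: second largest eigenvalue of the transition-style matrix Q
  keep <- px > 0
  mcc <- if (sum(keep) > 1) {
    pk <- p[keep, keep, drop = FALSE]
    pxk <- px[keep]
    # Q(a,b) = sum_k p(a,k) p(b,k) / (px(a) py(k)); py = px by symmetry
    Q <- matrix(0, sum(keep), sum(keep))
    for (kk in seq_len(sum(keep)))
      Q <- Q + outer(pk[, kk], pk[, kk]) / pxk[kk]
    Q <- sweep(Q, 1, pxk, "/")
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  } else 1
  c(Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - 2 * mux)^4 * p),
    ClusterShade = sum((i + j - 2 * mux)^3 * p),
    ClusterTendency = sum((i + j - 2 * mux)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = DA,
    DifferenceEntropy = -sum(xlog2(pxmy)),
    DifferenceVariance = sum(((0:(ng - 1)) - DA)^2 * pxmy),
    Id = sum(p / (1 + dif)),
    Idm = sum(p / (1 + dif^2)),
    Idmn = sum(p / (1 + dif^2 / ng^2)),
    Idn = sum(p / (1 + dif / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[dif > 0] / dif[dif > 0]^2),
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = HXY,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum((2:(2 * ng)) * pxpy),
    SumEntropy = -sum(xlog2(pxpy)),
    SumSquares = sigx2)
}

glcmFeatures <- function(counts, ng) {
  per <- lapply(seq_len(dim(counts)[3]), function(a)
    glcmFeaturesOne(matrix(counts[, , a], ng, ng), ng))
  per <- Filter(Negate(is.null), per)
  if (!length(per)) stop("GLCM is empty (no in-mask voxel pairs)")
  colMeans(do.call(rbind, per))
}

# ---- GLRLM ----------------------------------------------------------------

glrlmFeaturesOne <- function(P, ng) {
  Nr <- sum(P)
  if (Nr == 0) return(NULL)
  nl <- ncol(P)
  Np <- sum(P * rep(seq_len(nl), each = ng)) # total voxels in runs
  i <- row(P)
  l <- col(P)
  p <- P / Nr
  ri <- rowSums(P)
  rl <- colSums(P)
  mui <- sum(i * p)
  mul <- sum(l * p)
  c(ShortRunEmphasis = sum(P / l^2) / Nr,
    LongRunEmphasis = sum(P * l^2) / Nr,
    GrayLevelNonUniformity = sum(ri^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / Nr^2,
    RunLengthNonUniformity = sum(rl^2) / Nr,
    RunLengthNonUniformityNormalized = sum(rl^2) / Nr^2,
    RunPercentage = Nr / Np,
    GrayLevelVariance = sum((i - mui)^2 * p),
    RunVariance = sum((l - mul)^2 * p),
    RunEntropy = -sum(xlog2(p)),
    LowGrayLevelRunEmphasis = sum(P / i^2) / Nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * l^2)) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / l^2) / Nr,
    LongRunLowGrayLevelEmphasis = sum(P * l^2 / i^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * l^2) / Nr)
}

glrlmFeatures <- function(counts, ng) {
  per <- lapply(seq_len(dim(counts)[3]), function(a)
    glrlmFeaturesOne(matrix(counts[, , a], ng, dim(counts)[2]), ng))
  per <- Filter(Negate(is.null), per)
  if (!length(per)) stop("GLRLM is empty")
  colMeans(do.call(rbind, per))
}

# ---- GLSZM ----------------------------------------------------------------

glszmFeatures <- function(zones, ng) {
  Nz <- sum(zones$count)
  if (Nz == 0) stop("GLSZM is empty")
  Np <- sum(zones$count * zones$size)
  i <- zones$level
  s <- zones$size
  cnt <- zones$count
  p <- cnt / Nz
  zi <- vapply(seq_len(ng), function(g) sum(cnt[i == g]), 0)
  zs <- tapply(cnt, s, sum)
  mui <- sum(i * p)
  mus <- sum(s * p)
  c(SmallAreaEmphasis = sum(cnt / s^2) / Nz,
    LargeAreaEmphasis = sum(cnt * s^2) / Nz,
    GrayLevelNonUniformity = sum(zi^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(zi^2) / Nz^2,
    SizeZoneNonUniformity = sum(zs^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(zs^2) / Nz^2,
    ZonePercentage = Nz / Np,
    GrayLevelVariance = sum((i - mui)^2 * p),
    ZoneVariance = sum((s - mus)^2 * p),
    ZoneEntropy = -sum(xlog2(p)),
    LowGrayLevelZoneEmphasis = sum(cnt / i^2) / Nz,
    HighGrayLevelZoneEmphasis = sum(cnt * i^2) / Nz,
    SmallAreaLowGrayLevelEmphasis = sum(cnt / (i^2 * s^2)) / Nz,
    SmallAreaHighGrayLevelEmphasis = sum(cnt * i^2 / s^2) / Nz,
    LargeAreaLowGrayLevelEmphasis = sum(cnt * s^2 / i^2) / Nz,
    LargeAreaHighGrayLevelEmphasis = sum(cnt * i^2 * s^2) / Nz)
}

# ---- GLDM -----------------------------------------------------------------

gldmFeatures <- function(P, ng) {
  Nz <- sum(P)
  if (Nz == 0) stop("GLDM is empty")
  i <- row(P)
  j <- col(P) # dependence size (centre voxel included)
  p <- P / Nz
  gi <- rowSums(P)
  dj <- colSums(P)
  mui <- sum(i * p)
  muj <- sum(j * p)
  c(SmallDependenceEmphasis = sum(P / j^2) / Nz,
    LargeDependenceEmphasis = sum(P * j^2) / Nz,
    GrayLevelNonUniformity = sum(gi^2) / Nz,
    DependenceNonUniformity = sum(dj^2) / Nz,
    DependenceNonUniformityNormalized = sum(dj^2) / Nz^2,
    GrayLevelVariance = sum((i - mui)^2 * p),
    DependenceVariance = sum((j - muj)^2 * p),
    DependenceEntropy = -sum(xlog2(p)),
    LowGrayLevelEmphasis = sum(P / i^2) / Nz,
    HighGrayLevelEmphasis = sum(P * i^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / Nz)
}

# ---- NGTDM ----------------------------------------------------------------

ngtdmFeatures <- function(ns, ng) {
  nvec <- ns[, 1]
  svec <- ns[, 2]
  Nvp <- sum(nvec)
  if (Nvp == 0) stop("NGTDM is empty")
  p <- nvec / Nvp
  present <- which(p > 0)
  Ngp <- length(present)
  ii <- present
  pi_ <- p[present]
  si <- svec[present]
  coarse <- sum(pi_ * si)
  contrast <- if (Ngp > 1) {
    (sum(outer(pi_, pi_) * outer(ii, ii, "-")^2) / (Ngp * (Ngp - 1))) *
      (sum(svec) / Nvp)
  } else 0
  busyDen <- sum(abs(outer(ii * pi_, ii * pi_, "-")))
  busy <- if (busyDen > 0) coarse / busyDen else 0
  comp <- if (Ngp > 1) {
    num <- outer(pi_ * si, pi_ * si, "+")
    den <- outer(pi_, pi_, "+")
    sum(abs(outer(ii, ii, "-")) * num / den) / Nvp
  } else 0
  strength <- if (sum(svec) > 0)
    sum(outer(pi_, pi_, "+") * outer(ii, ii, "-")^2) / sum(svec)
  else 0
  c(Busyness = busy,
    Coarseness = if (coarse > 0) 1 / coarse else 1e6,
    Complexity = comp,
    Contrast = contrast,
    Strength = strength)
}
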
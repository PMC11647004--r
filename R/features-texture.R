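# Texture features of a discretized dose volume. Matrix construction lives
# in src/textures.cpp; all families use distance 1, 26-connectivity (13
# unique directions), and direction-averaged aggregation where directed.

plog2p <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Gray-level co-occurrence features
#'
#' Builds symmetric co-occurrence matrices over the 13 unique 3D direction
#' vectors at distance 1 (in-mask voxel pairs only), computes the 24 standard
#' GLCM features per direction and averages them over directions. Constant
#' (single-level) regions use the conventions: correlation-type features
#' (Correlation, MCC) are 1, information measures are 0, so all values stay
#' finite.
#'
#' @param disc A [discretize()] result.
#' @return Named numeric vector of length 24.
#' @export
glcm_features <- function(disc) {
  stopifnot(inherits(disc, "discretized_volume"))
  mats <- cpp_glcm(disc$levels, dim(disc$levels), disc$n_levels)
  feats <- lapply(mats, function(M) {
    if (sum(M) > 0) glcm_features_one(M) else NULL
  })
  feats <- feats[!vapply(feats, is.null, logical(1))]
  if (!length(feats)) { # isolated voxels only: no pairs in any direction
    feats <- list(glcm_features_one(matrix(1, 1, 1) * 0 + 1))
  }
  colMeans(do.call(rbind, feats))
}

glcm_features_one <- function(M) {
  ng <- nrow(M)
  p <- M / sum(M)
  i <- row(p); j <- col(p)
  px <- rowSums(p)                    # symmetric: px == py
  mu <- sum(px * seq_len(ng))
  sig2 <- sum(px * (seq_len(ng) - mu)^2)

  # diagonal (difference) and cross-diagonal (sum) marginals
  dk <- 0:(ng - 1)
  pdiff <- as.numeric(rowsum(as.vector(p), as.vector(abs(i - j))))
  sk <- 2:(2 * ng)
  psum <- as.numeric(rowsum(as.vector(p), as.vector(i + j)))

  autocorr <- sum(p * i * j)
  contrast <- sum(p * (i - j)^2)
  corr <- if (sig2 > 1e-12) (autocorr - mu^2) / sig2 else 1
  da <- sum(dk * pdiff)

  hxy <- plog2p(p)
  hx <- plog2p(px)
  pxy_ind <- outer(px, px)
  pos <- p > 0 & pxy_ind > 0
  hxy1 <- -sum(p[pos] * log2(pxy_ind[pos]))
  hxy2 <- plog2p(pxy_ind)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0

  mcc <- {
    keep <- px > 0
    if (sum(keep) < 2) 1 else {
      pk <- p[keep, keep, drop = FALSE]
      pxk <- px[keep]
      # Q(i,j) = sum_k p(i,k) p(j,k) / (px_i * px_k) is similar to the
      # symmetric B B' with B = diag(px^-1/2) P diag(px^-1/2)
      b <- pk / sqrt(outer(pxk, pxk))
      ev <- sort(eigen(tcrossprod(b), symmetric = TRUE,
                       only.values = TRUE)$values, decreasing = TRUE)
      sqrt(max(ev[2], 0))
    }
  }

  c(Autocorrelation = autocorr,
    ClusterProminence = sum(p * (i + j - 2 * mu)^4),
    ClusterShade = sum(p * (i + j - 2 * mu)^3),
    ClusterTendency = sum(p * (i + j - 2 * mu)^2),
    Contrast = contrast,
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = plog2p(pdiff),
    DifferenceVariance = sum(pdiff * (dk - da)^2),
    Id = sum(pdiff / (1 + dk)),
    Idm = sum(pdiff / (1 + dk^2)),
    Idmn = sum(pdiff / (1 + (dk / ng)^2)),
    Idn = sum(pdiff / (1 + dk / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = if (ng > 1) sum(pdiff[-1] / dk[-1]^2) else 0,
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(sk * psum),
    SumEntropy = plog2p(psum),
    SumSquares = sig2)
}

glrlm_features_one <- function(M) {
  # trim trailing empty run lengths only: column position is the run length
  last <- max(which(colSums(M) > 0), 1)
  M <- M[, seq_len(last), drop = FALSE]
  nr <- sum(M)
  p <- M / nr
  i <- row(p); j <- col(p)
  gl <- rowSums(p); rl <- colSums(p)
  mug <- sum(gl * seq_len(nrow(p)))
  mur <- sum(rl * seq_len(ncol(p)))
  c(GrayLevelNonUniformity = sum(rowSums(M)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(M)^2) / nr^2,
    GrayLevelVariance = sum(p * (i - mug)^2),
    HighGrayLevelRunEmphasis = sum(p * i^2),
    LongRunEmphasis = sum(p * j^2),
    LongRunHighGrayLevelEmphasis = sum(p * i^2 * j^2),
    LongRunLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LowGrayLevelRunEmphasis = sum(p / i^2),
    RunEntropy = plog2p(p),
    RunLengthNonUniformity = sum(colSums(M)^2) / nr,
    RunLengthNonUniformityNormalized = sum(colSums(M)^2) / nr^2,
    RunPercentage = nr / sum(M * col(M)),
    RunVariance = sum(p * (j - mur)^2),
    ShortRunEmphasis = sum(p / j^2),
    ShortRunHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    ShortRunLowGrayLevelEmphasis = sum(p / (i^2 * j^2)))
}

glszm_features <- function(disc) {
  z <- cpp_glszm(disc$levels, dim(disc$levels))
  lev <- z$level; size <- z$size
  nz <- length(lev)
  np <- sum(size)
  p <- rep(1 / nz, nz)               # one entry per zone
  mug <- sum(p * lev)
  mus <- sum(p * size)
  tab <- table(paste(lev, size))     # collapse equal (level, size) cells
  pcell <- as.numeric(tab) / nz
  c(GrayLevelNonUniformity = sum(table(lev)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(table(lev)^2) / nz^2,
    GrayLevelVariance = sum(p * (lev - mug)^2),
    HighGrayLevelZoneEmphasis = sum(p * lev^2),
    LargeAreaEmphasis = sum(p * size^2),
    LargeAreaHighGrayLevelEmphasis = sum(p * lev^2 * size^2),
    LargeAreaLowGrayLevelEmphasis = sum(p * size^2 / lev^2),
    LowGrayLevelZoneEmphasis = sum(p / lev^2),
    SizeZoneNonUniformity = sum(table(size)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(table(size)^2) / nz^2,
    SmallAreaEmphasis = sum(p / size^2),
    SmallAreaHighGrayLevelEmphasis = sum(p * lev^2 / size^2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (lev^2 * size^2)),
    ZoneEntropy = plog2p(pcell),
    ZonePercentage = nz / np,
    ZoneVariance = sum(p * (size - mus)^2))
}

ngtdm_features <- function(disc) {
  r <- cpp_ngtdm(disc$levels, dim(disc$levels), disc$n_levels)
  n_i <- r$n; s_i <- r$s
  nv <- sum(n_i)
  p_i <- n_i / nv
  act <- which(p_i > 0)
  ngp <- length(act)
  iv <- act                          # gray values = level indices
  pv <- p_i[act]; sv <- s_i[act]
  denom_c <- sum(pv * sv)
  coarse <- if (denom_c > 0) 1 / denom_c else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(pv, pv) * outer(iv, iv, "-")^2) / (ngp * (ngp - 1))) *
      (sum(sv) / nv)
  } else 0
  # denominator runs over all ordered level pairs with non-zero probability
  busy_den <- sum(abs(outer(iv * pv, iv * pv, "-")))
  busy <- if (busy_den > 0) denom_c / busy_den else 0
  cplx <- sum(outer(iv, iv, function(a, b) abs(a - b)) *
                (outer(pv * sv, pv * sv, "+")) /
                outer(pv, pv, "+")) / nv
  strength <- if (sum(sv) > 0)
    sum(outer(pv, pv, "+") * outer(iv, iv, "-")^2) / sum(sv) else 0
  c(Busyness = busy,
    Coarseness = coarse,
    Complexity = cplx,
    Contrast = contrast,
    Strength = strength)
}

gldm_features <- function(disc, alpha = 0L) {
  M <- cpp_gldm(disc$levels, dim(disc$levels), disc$n_levels, alpha)
  last <- max(which(colSums(M) > 0), 1)
  M <- M[, seq_len(last), drop = FALSE]
  nz <- sum(M)
  p <- M / nz
  i <- row(p); j <- col(p)
  gl <- rowSums(p); dp <- colSums(p)
  mug <- sum(gl * seq_len(nrow(p)))
  mud <- sum(dp * seq_len(ncol(p)))
  c(DependenceEntropy = plog2p(p),
    DependenceNonUniformity = sum(colSums(M)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(M)^2) / nz^2,
    DependenceVariance = sum(p * (j - mud)^2),
    GrayLevelNonUniformity = sum(rowSums(M)^2) / nz,
    GrayLevelVariance = sum(p * (i - mug)^2),
    HighGrayLevelEmphasis = sum(p * i^2),
    LargeDependenceEmphasis = sum(p * j^2),
    LargeDependenceHighGrayLevelEmphasis = sum(p * i^2 * j^2),
    LargeDependenceLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LowGrayLevelEmphasis = sum(p / i^2),
    SmallDependenceEmphasis = sum(p / j^2),
    SmallDependenceHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * j^2)))
}

#' Gray-level texture-matrix features
#'
#' Builds the requested family's matrix and returns its standard feature set:
#' run-length matrices along the 13 unique directions with features averaged
#' over directions (GLRLM, 16 features); 26-connected constant-level zones
#' (GLSZM, 16); 26-neighbourhood gray-tone differences (NGTDM, 5); and
#' 26-neighbourhood dependence counts at tolerance 0 (GLDM, 14).
#'
#' @param disc A [discretize()] result.
#' @param family One of `"GLRLM"`, `"GLSZM"`, `"NGTDM"`, `"GLDM"`.
#' @return Named numeric vector of the family's features.
#' @export
texture_matrix_features <- function(disc,
                                    family = c("GLRLM", "GLSZM", "NGTDM",
                                               "GLDM")) {
  stopifnot(inherits(disc, "discretized_volume"))
  family <- match.arg(family)
  switch(family,
    GLRLM = {
      mats <- cpp_glrlm(disc$levels, dim(disc$levels), disc$n_levels)
      colMeans(do.call(rbind, lapply(mats, glrlm_features_one)))
    },
    GLSZM = glszm_features(disc),
    NGTDM = ngtdm_features(disc),
    GLDM = gldm_features(disc))
}
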
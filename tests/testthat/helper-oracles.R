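# Independent brute-force oracles used to cross-check the implementation.
# Everything here is written as a direct, loop-based transcription of the
# defining formulas: matrices by exhaustive pair/run/zone enumeration over
# voxel coordinates, metrics by exhaustive pair enumeration with explicit
# Kaplan-Meier weights. Nothing below calls the package's fast paths.

oracle_dirs <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1),
  c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

ok_idx <- function(v, d) all(v >= 1) && all(v <= d)

# symmetric co-occurrence matrix for one direction, by pair enumeration
oracle_glcm_matrix <- function(lev, dir) {
  d <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  M <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    v2 <- c(x, y, z) + dir
    if (!ok_idx(v2, d)) next
    b <- lev[v2[1], v2[2], v2[3]]
    if (is.na(b)) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

oracle_glcm_matrix_padded <- function(lev, dir_index, n_levels) {
  M <- oracle_glcm_matrix(lev, oracle_dirs[dir_index, ])
  out <- matrix(0, n_levels, n_levels)
  out[seq_len(nrow(M)), seq_len(ncol(M))] <- M
  out
}

oracle_glcm_features <- function(lev, n_levels) {
  feats <- NULL
  for (k in seq_len(nrow(oracle_dirs))) {
    M <- oracle_glcm_matrix(lev, oracle_dirs[k, ])
    if (nrow(M) < n_levels) {
      M2 <- matrix(0, n_levels, n_levels)
      M2[seq_len(nrow(M)), seq_len(ncol(M))] <- M
      M <- M2
    }
    if (sum(M) == 0) next
    feats <- rbind(feats, oracle_glcm_features_one(M))
  }
  if (is.null(feats)) feats <- rbind(oracle_glcm_features_one(matrix(1)))
  colMeans(feats)
}

oracle_glcm_features_one <- function(M) {
  ng <- nrow(M)
  p <- M / sum(M)
  px <- rowSums(p)
  mu <- 0
  for (i in 1:ng) mu <- mu + i * px[i]
  sig2 <- 0
  for (i in 1:ng) sig2 <- sig2 + px[i] * (i - mu)^2
  auto <- contrast <- cp <- cs <- ct <- je <- hxy <- maxp <- 0
  pd <- numeric(ng)        # |i-j| in 0..ng-1
  ps <- numeric(2 * ng - 1) # i+j in 2..2ng
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    auto <- auto + pij * i * j
    contrast <- contrast + pij * (i - j)^2
    cp <- cp + pij * (i + j - 2 * mu)^4
    cs <- cs + pij * (i + j - 2 * mu)^3
    ct <- ct + pij * (i + j - 2 * mu)^2
    je <- je + pij^2
    if (pij > 0) hxy <- hxy - pij * log2(pij)
    maxp <- max(maxp, pij)
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + pij
    ps[i + j - 1] <- ps[i + j - 1] + pij
  }
  da <- sum((0:(ng - 1)) * pd)
  dvar <- sum(pd * ((0:(ng - 1)) - da)^2)
  dent <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  sent <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  savg <- sum((2:(2 * ng)) * ps)
  id <- sum(pd / (1 + 0:(ng - 1)))
  idm <- sum(pd / (1 + (0:(ng - 1))^2))
  idmn <- sum(pd / (1 + ((0:(ng - 1)) / ng)^2))
  idn <- sum(pd / (1 + (0:(ng - 1)) / ng))
  iv <- if (ng > 1) sum(pd[-1] / (1:(ng - 1))^2) else 0
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hxy1 <- hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pp <- px[i] * px[j]
    if (pp > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(pp)
      hxy2 <- hxy2 - pp * log2(pp)
    }
  }
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  corr <- if (sig2 > 1e-12) (auto - mu^2) / sig2 else 1
  keep <- which(px > 0)
  mcc <- if (length(keep) < 2) 1 else {
    q <- matrix(0, length(keep), length(keep))
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      s <- 0
      for (k in seq_along(keep))
        s <- s + p[keep[a], keep[k]] * p[keep[b], keep[k]] /
          (px[keep[a]] * px[keep[k]])
      q[a, b] <- s
    }
    ev <- sort(Re(eigen(q)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  c(Autocorrelation = auto, ClusterProminence = cp, ClusterShade = cs,
    ClusterTendency = ct, Contrast = contrast, Correlation = corr,
    DifferenceAverage = da, DifferenceEntropy = dent,
    DifferenceVariance = dvar, Id = id, Idm = idm, Idmn = idmn, Idn = idn,
    Imc1 = imc1, Imc2 = imc2, InverseVariance = iv, JointAverage = mu,
    JointEnergy = je, JointEntropy = hxy, MCC = mcc,
    MaximumProbability = maxp, SumAverage = savg, SumEntropy = sent,
    SumSquares = sig2)
}

# run enumeration for one direction: walk every maximal constant-level run
oracle_glrlm_matrix <- function(lev, dir, n_levels) {
  d <- dim(lev)
  M <- matrix(0, n_levels, max(d))
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    vp <- c(x, y, z) - dir
    if (ok_idx(vp, d)) {
      prev <- lev[vp[1], vp[2], vp[3]]
      if (!is.na(prev) && prev == a) next
    }
    len <- 1
    v <- c(x, y, z) + dir
    while (ok_idx(v, d)) {
      b <- lev[v[1], v[2], v[3]]
      if (is.na(b) || b != a) break
      len <- len + 1
      v <- v + dir
    }
    M[a, len] <- M[a, len] + 1
  }
  M
}

oracle_rlm_features_one <- function(M) {
  M <- M[, seq_len(max(which(colSums(M) > 0), 1)), drop = FALSE]
  nr <- sum(M)
  np <- 0
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M)))
    np <- np + M[i, j] * j
  p <- M / nr
  gl <- rowSums(p); rl <- colSums(p)
  mug <- sum(gl * seq_len(nrow(p)))
  mur <- sum(rl * seq_len(ncol(p)))
  f <- c(GrayLevelNonUniformity = 0, GrayLevelNonUniformityNormalized = 0,
         GrayLevelVariance = 0, HighGrayLevelRunEmphasis = 0,
         LongRunEmphasis = 0, LongRunHighGrayLevelEmphasis = 0,
         LongRunLowGrayLevelEmphasis = 0, LowGrayLevelRunEmphasis = 0,
         RunEntropy = 0, RunLengthNonUniformity = 0,
         RunLengthNonUniformityNormalized = 0, RunPercentage = nr / np,
         RunVariance = 0, ShortRunEmphasis = 0,
         ShortRunHighGrayLevelEmphasis = 0, ShortRunLowGrayLevelEmphasis = 0)
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    pij <- p[i, j]
    f["GrayLevelVariance"] <- f["GrayLevelVariance"] + pij * (i - mug)^2
    f["RunVariance"] <- f["RunVariance"] + pij * (j - mur)^2
    f["HighGrayLevelRunEmphasis"] <-
      f["HighGrayLevelRunEmphasis"] + pij * i^2
    f["LowGrayLevelRunEmphasis"] <-
      f["LowGrayLevelRunEmphasis"] + pij / i^2
    f["LongRunEmphasis"] <- f["LongRunEmphasis"] + pij * j^2
    f["ShortRunEmphasis"] <- f["ShortRunEmphasis"] + pij / j^2
    f["LongRunHighGrayLevelEmphasis"] <-
      f["LongRunHighGrayLevelEmphasis"] + pij * i^2 * j^2
    f["LongRunLowGrayLevelEmphasis"] <-
      f["LongRunLowGrayLevelEmphasis"] + pij * j^2 / i^2
    f["ShortRunHighGrayLevelEmphasis"] <-
      f["ShortRunHighGrayLevelEmphasis"] + pij * i^2 / j^2
    f["ShortRunLowGrayLevelEmphasis"] <-
      f["ShortRunLowGrayLevelEmphasis"] + pij / (i^2 * j^2)
    if (pij > 0) f["RunEntropy"] <- f["RunEntropy"] - pij * log2(pij)
  }
  f["GrayLevelNonUniformity"] <- sum(rowSums(M)^2) / nr
  f["GrayLevelNonUniformityNormalized"] <- sum(rowSums(M)^2) / nr^2
  f["RunLengthNonUniformity"] <- sum(colSums(M)^2) / nr
  f["RunLengthNonUniformityNormalized"] <- sum(colSums(M)^2) / nr^2
  f
}

oracle_glrlm_features <- function(lev, n_levels) {
  feats <- NULL
  for (k in seq_len(nrow(oracle_dirs)))
    feats <- rbind(feats, oracle_rlm_features_one(
      oracle_glrlm_matrix(lev, oracle_dirs[k, ], n_levels)))
  colMeans(feats)
}

# zones by repeated flood fill over the 26-neighbourhood
oracle_glszm_zones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (seen[x, y, z] || is.na(lev[x, y, z])) next
    a <- lev[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        w <- v + c(dx, dy, dz)
        if (!ok_idx(w, d)) next
        if (seen[w[1], w[2], w[3]]) next
        b <- lev[w[1], w[2], w[3]]
        if (!is.na(b) && b == a) {
          seen[w[1], w[2], w[3]] <- TRUE
          stack[[length(stack) + 1]] <- w
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = a, size = size)
  }
  do.call(rbind, zones)
}

oracle_glszm_features <- function(lev) {
  zn <- oracle_glszm_zones(lev)
  nz <- nrow(zn)
  np <- sum(zn[, "size"])
  i <- zn[, "level"]; s <- zn[, "size"]
  pcell <- table(paste(i, s)) / nz
  mug <- mean(i); mus <- mean(s)
  c(GrayLevelNonUniformity = sum(table(i)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(table(i)^2) / nz^2,
    GrayLevelVariance = mean((i - mug)^2),
    HighGrayLevelZoneEmphasis = mean(i^2),
    LargeAreaEmphasis = mean(s^2),
    LargeAreaHighGrayLevelEmphasis = mean(i^2 * s^2),
    LargeAreaLowGrayLevelEmphasis = mean(s^2 / i^2),
    LowGrayLevelZoneEmphasis = mean(1 / i^2),
    SizeZoneNonUniformity = sum(table(s)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(table(s)^2) / nz^2,
    SmallAreaEmphasis = mean(1 / s^2),
    SmallAreaHighGrayLevelEmphasis = mean(i^2 / s^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (i^2 * s^2)),
    ZoneEntropy = -sum(pcell * log2(pcell)),
    ZonePercentage = nz / np,
    ZoneVariance = mean((s - mus)^2))
}

oracle_ngtdm_features <- function(lev, n_levels) {
  d <- dim(lev)
  ncnt <- numeric(n_levels)
  ssum <- numeric(n_levels)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      w <- c(x + dx, y + dy, z + dz)
      if (!ok_idx(w, d)) next
      b <- lev[w[1], w[2], w[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (!length(nb)) next
    ncnt[a] <- ncnt[a] + 1
    ssum[a] <- ssum[a] + abs(a - mean(nb))
  }
  nv <- sum(ncnt)
  pi_ <- ncnt / nv
  act <- which(pi_ > 0)
  ngp <- length(act)
  den <- sum(pi_[act] * ssum[act])
  coarse <- if (den > 0) 1 / den else 1e6
  contr <- 0; busy_den <- 0; cplx <- 0; stren <- 0
  for (a in act) for (b in act) {
    contr <- contr + pi_[a] * pi_[b] * (a - b)^2
    busy_den <- busy_den + abs(a * pi_[a] - b * pi_[b])
    cplx <- cplx + abs(a - b) * (pi_[a] * ssum[a] + pi_[b] * ssum[b]) /
      (pi_[a] + pi_[b])
    stren <- stren + (pi_[a] + pi_[b]) * (a - b)^2
  }
  contrast <- if (ngp > 1)
    contr / (ngp * (ngp - 1)) * sum(ssum[act]) / nv else 0
  c(Busyness = if (busy_den > 0) den / busy_den else 0,
    Coarseness = coarse,
    Complexity = cplx / nv,
    Contrast = contrast,
    Strength = if (sum(ssum[act]) > 0) stren / sum(ssum[act]) else 0)
}

oracle_gldm_features <- function(lev, n_levels, alpha = 0) {
  d <- dim(lev)
  M <- matrix(0, n_levels, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    dep <- 1
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      w <- c(x + dx, y + dy, z + dz)
      if (!ok_idx(w, d)) next
      b <- lev[w[1], w[2], w[3]]
      if (!is.na(b) && abs(a - b) <= alpha) dep <- dep + 1
    }
    M[a, dep] <- M[a, dep] + 1
  }
  M <- M[, seq_len(max(which(colSums(M) > 0), 1)), drop = FALSE]
  nz <- sum(M)
  p <- M / nz
  mug <- sum(rowSums(p) * seq_len(nrow(p)))
  mud <- sum(colSums(p) * seq_len(ncol(p)))
  f <- c(DependenceEntropy = 0, DependenceNonUniformity = 0,
         DependenceNonUniformityNormalized = 0, DependenceVariance = 0,
         GrayLevelNonUniformity = 0, GrayLevelVariance = 0,
         HighGrayLevelEmphasis = 0, LargeDependenceEmphasis = 0,
         LargeDependenceHighGrayLevelEmphasis = 0,
         LargeDependenceLowGrayLevelEmphasis = 0, LowGrayLevelEmphasis = 0,
         SmallDependenceEmphasis = 0,
         SmallDependenceHighGrayLevelEmphasis = 0,
         SmallDependenceLowGrayLevelEmphasis = 0)
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    pij <- p[i, j]
    if (pij > 0)
      f["DependenceEntropy"] <- f["DependenceEntropy"] - pij * log2(pij)
    f["DependenceVariance"] <- f["DependenceVariance"] + pij * (j - mud)^2
    f["GrayLevelVariance"] <- f["GrayLevelVariance"] + pij * (i - mug)^2
    f["HighGrayLevelEmphasis"] <- f["HighGrayLevelEmphasis"] + pij * i^2
    f["LowGrayLevelEmphasis"] <- f["LowGrayLevelEmphasis"] + pij / i^2
    f["LargeDependenceEmphasis"] <-
      f["LargeDependenceEmphasis"] + pij * j^2
    f["SmallDependenceEmphasis"] <-
      f["SmallDependenceEmphasis"] + pij / j^2
    f["LargeDependenceHighGrayLevelEmphasis"] <-
      f["LargeDependenceHighGrayLevelEmphasis"] + pij * i^2 * j^2
    f["LargeDependenceLowGrayLevelEmphasis"] <-
      f["LargeDependenceLowGrayLevelEmphasis"] + pij * j^2 / i^2
    f["SmallDependenceHighGrayLevelEmphasis"] <-
      f["SmallDependenceHighGrayLevelEmphasis"] + pij * i^2 / j^2
    f["SmallDependenceLowGrayLevelEmphasis"] <-
      f["SmallDependenceLowGrayLevelEmphasis"] + pij / (i^2 * j^2)
  }
  f["DependenceNonUniformity"] <- sum(colSums(M)^2) / nz
  f["DependenceNonUniformityNormalized"] <- sum(colSums(M)^2) / nz^2
  f["GrayLevelNonUniformity"] <- sum(rowSums(M)^2) / nz
  f
}

# first-order statistics straight from the definitions
oracle_firstorder <- function(x, lev_in_mask, n_levels, voxvol) {
  n <- length(x)
  p <- as.numeric(table(factor(lev_in_mask, levels = 1:n_levels))) / n
  p <- p[p > 0]
  q <- unname(quantile(x, c(.1, .25, .5, .75, .9), type = 7))
  inner <- x[x >= q[1] & x <= q[5]]
  m2 <- mean((x - mean(x))^2)
  c(Energy = sum(x^2), TotalEnergy = voxvol * sum(x^2),
    Entropy = -sum(p * log2(p)), Minimum = min(x),
    `10Percentile` = q[1], `90Percentile` = q[5], Maximum = max(x),
    Mean = mean(x), Median = q[3], InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mean(x))),
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - mean(x))^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - mean(x))^4) / m2^2 else 0,
    Variance = m2, Uniformity = sum(p^2))
}

# ---- survival-metric oracles -------------------------------------------

oracle_harrell <- function(risk, time, event) {
  num <- den <- 0
  n <- length(risk)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    comparable <- event[i] == 1 &&
      (time[i] < time[j] || (time[i] == time[j] && event[j] == 0))
    if (!comparable) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  num / den
}

# Kaplan-Meier of the censoring distribution, left limit G(t-)
oracle_km_censor <- function(time, event) {
  ut <- sort(unique(time))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 0)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  function(t, left = FALSE) {
    if (left) idx <- sum(ut < t) else idx <- sum(ut <= t)
    if (idx == 0) 1 else surv[idx]
  }
}

oracle_ipcw_c <- function(risk, time, event, tau = Inf) {
  G <- oracle_km_censor(time, event)
  num <- den <- 0
  n <- length(risk)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    comparable <- event[i] == 1 &&
      (time[i] < time[j] || (time[i] == time[j] && event[j] == 0))
    if (!comparable || time[i] > tau) next
    w <- 1 / G(time[i], left = TRUE)^2
    den <- den + w
    if (risk[i] > risk[j]) num <- num + w
    else if (risk[i] == risk[j]) num <- num + w / 2
  }
  num / den
}

oracle_brier <- function(surv_tau, time, event, tau) {
  G <- oracle_km_censor(time, event)
  n <- length(time)
  tot <- 0
  for (i in 1:n) {
    if (time[i] <= tau && event[i] == 1)
      tot <- tot + surv_tau[i]^2 / G(time[i], left = TRUE)
    else if (time[i] > tau)
      tot <- tot + (1 - surv_tau[i])^2 / G(tau)
  }
  tot / n
}

oracle_ibs <- function(surv_mat, time, event, grid) {
  bs <- vapply(seq_along(grid), function(k)
    oracle_brier(surv_mat[, k], time, event, grid[k]), numeric(1))
  total <- 0
  for (k in seq_len(length(grid) - 1))
    total <- total + (grid[k + 1] - grid[k]) * (bs[k] + bs[k + 1]) / 2
  total / (max(grid) - min(grid))
}

# ---- small random fixtures ---------------------------------------------

random_masked_volume <- function(dims = c(6, 6, 6), n_levels = 4,
                                 mask_frac = 0.8) {
  vals <- array(runif(prod(dims), 0, n_levels * 0.5 - 0.01), dims)
  m <- array(runif(prod(dims)) < mask_frac, dims)
  if (!any(m)) m[1] <- TRUE
  dose_volume(vals, spacing = 2, masks = list(whole_heart = m))
}

random_censored_data <- function(n = 100, cens_frac = 0.5) {
  time <- round(rexp(n, 0.05) + 0.5, 1)
  event <- as.integer(runif(n) > cens_frac)
  risk <- rnorm(n)
  list(time = time, event = event, risk = risk)
}

# tiny ready-made volume shared by several tests
tiny_volume <- function(vals, mask = NULL) {
  vals <- as.array(vals)
  if (is.null(mask)) mask <- array(TRUE, dim(vals))
  dose_volume(vals, spacing = 2, masks = list(whole_heart = mask))
}
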
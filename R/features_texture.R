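# Texture matrices (GLCM, GLRLM, GLSZM, GLDM, NGTDM) and their 74 features.
#
# All matrices are computed on the discretized gray levels of one region
# (integer array, 0 outside the region). GLCM and GLRLM are computed per
# 3-D direction (the 13 unique offsets) and their features averaged across
# directions; GLSZM, GLDM and NGTDM use the full 26-neighbourhood. The
# standard five families total 75 features; GLCM SumAverage (redundant with
# twice the joint average on a symmetric matrix) is excluded to give the
# 74-feature texture block.

GLCM_NAMES <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
  "MaximumProbability", "SumEntropy", "SumSquares")
GLRLM_NAMES <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis")
GLSZM_NAMES <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance")
GLDM_NAMES <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis")
NGTDM_NAMES <- c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")

#' Texture matrices of a discretized region
#'
#' Computes the gray-level co-occurrence (GLCM, distance 1, symmetric, per
#' direction), run-length (GLRLM, per direction), size-zone (GLSZM,
#' 26-connected zones), dependence (GLDM, 26-neighbourhood, dependence
#' criterion: equal level) and neighbourhood gray-tone difference (NGTDM,
#' 26-neighbourhood) matrices.
#'
#' @param disc integer 3-D array of gray levels, 0 outside the region.
#' @param n_levels the discretization level count.
#' @return list with elements `glcm` (list of 13 count matrices), `glrlm`
#'   (list of 13 level-by-runlength count matrices), `glszm`, `gldm`
#'   (count matrices), `ngtdm` (list with `levels`, `n`, `p`, `s`) and
#'   `n_voxels`.
#' @export
texture_matrices <- function(disc, n_levels) {
  stopifnot(length(dim(disc)) == 3)
  region <- disc > 0
  np <- sum(region)
  if (np < 2) stop("region must have at least 2 voxels")
  disc <- crop_to_mask(disc, region)
  d <- dim(disc)
  region <- disc > 0

  # ---- GLCM: one symmetric count matrix per direction
  glcm <- vector("list", nrow(DIRECTIONS_13))
  for (k in seq_len(nrow(DIRECTIONS_13))) {
    s <- shift3d(disc, -DIRECTIONS_13[k, ], 0L)   # s[x] = disc[x + offset]
    ok <- disc > 0 & s > 0
    a <- disc[ok]; b <- s[ok]
    counts <- tabulate(a + (b - 1L) * n_levels, nbins = n_levels * n_levels)
    P <- matrix(counts, n_levels, n_levels)
    glcm[[k]] <- P + t(P)
  }

  # ---- GLRLM: runs of equal level along each direction
  coords <- arrayInd(seq_len(prod(d)), d)
  glrlm <- vector("list", nrow(DIRECTIONS_13))
  for (k in seq_len(nrow(DIRECTIONS_13))) {
    off <- DIRECTIONS_13[k, ]
    cc <- sum(off^2)
    t_proj <- as.vector(coords %*% off)
    line_id <- cc * coords - outer(t_proj, off)   # constant along each line
    hash <- (line_id[, 1] + 400L) + 4096 * ((line_id[, 2] + 400L) +
             4096 * (line_id[, 3] + 400L))
    ord <- order(hash, t_proj)
    v <- disc[ord]; h <- hash[ord]
    n <- length(v)
    new_run <- c(TRUE, v[-1] != v[-n] | h[-1] != h[-n])
    run_id <- cumsum(new_run)
    lens <- tabulate(run_id)
    levs <- v[new_run]
    keep <- levs > 0
    lens <- lens[keep]; levs <- levs[keep]
    maxr <- max(lens)
    glrlm[[k]] <- matrix(tabulate(levs + (lens - 1L) * n_levels,
                                  nbins = n_levels * maxr), n_levels, maxr)
  }

  # ---- GLSZM: 26-connected zones of equal level
  pd <- d + 2L
  padded <- array(0L, pd)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- disc
  noff <- as.integer(OFFSETS_26[, 1] + OFFSETS_26[, 2] * pd[1] +
                     OFFSETS_26[, 3] * pd[1] * pd[2])
  visited <- logical(prod(pd))
  zone_lev <- integer(0); zone_size <- integer(0)
  vox <- which(padded > 0L)
  for (v0 in vox) {
    if (visited[v0]) next
    lvl <- padded[v0]
    stack <- v0
    visited[v0] <- TRUE
    size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      nb <- cur + noff
      nb <- nb[padded[nb] == lvl & !visited[nb]]
      visited[nb] <- TRUE
      stack <- c(stack, nb)
    }
    zone_lev <- c(zone_lev, lvl)
    zone_size <- c(zone_size, size)
  }
  maxz <- max(zone_size)
  glszm <- matrix(tabulate(zone_lev + (zone_size - 1L) * n_levels,
                           nbins = n_levels * maxz), n_levels, maxz)

  # ---- GLDM: dependence = number of 26-neighbours with the same level (+1)
  dep <- array(0L, d)
  for (k in seq_len(nrow(OFFSETS_26))) {
    s <- shift3d(disc, OFFSETS_26[k, ], 0L)
    dep <- dep + (s == disc & s > 0L)
  }
  j <- dep[region] + 1L
  i <- disc[region]
  gldm <- matrix(tabulate(i + (j - 1L) * n_levels, nbins = n_levels * 27L),
                 n_levels, 27L)
  gldm <- gldm[, seq_len(max(j)), drop = FALSE]

  # ---- NGTDM: difference from the mean of valid neighbours
  nsum <- array(0, d); ncnt <- array(0L, d)
  for (k in seq_len(nrow(OFFSETS_26))) {
    s <- shift3d(disc, OFFSETS_26[k, ], 0L)
    nsum <- nsum + s
    ncnt <- ncnt + (s > 0L)
  }
  has_nb <- region & ncnt > 0
  lev_v <- disc[has_nb]
  diffs <- abs(lev_v - nsum[has_nb] / ncnt[has_nb])
  levels_p <- sort(unique(lev_v))
  n_i <- vapply(levels_p, function(l) sum(lev_v == l), numeric(1))
  s_i <- vapply(levels_p, function(l) sum(diffs[lev_v == l]), numeric(1))
  ngtdm <- list(levels = levels_p, n = n_i, p = n_i / sum(n_i), s = s_i)

  list(glcm = glcm, glrlm = glrlm, glszm = glszm, gldm = gldm, ngtdm = ngtdm,
       n_voxels = np)
}

# ---- feature computations ---------------------------------------------------

glcm_features_one <- function(counts) {
  occ <- which(rowSums(counts) + colSums(counts) > 0)
  if (length(occ) == 0) return(stats::setNames(rep(0, 23), GLCM_NAMES))
  P <- counts[occ, occ, drop = FALSE]
  p <- P / sum(P)
  iv <- occ
  ng <- length(iv)
  px <- rowSums(p); py <- colSums(p)
  ux <- sum(iv * px); uy <- sum(iv * py)
  sx <- sqrt(sum((iv - ux)^2 * px)); sy <- sqrt(sum((iv - uy)^2 * py))
  I <- matrix(iv, ng, ng); J <- t(I)
  k_diff <- 0:(max(iv) - min(iv))
  pxmy <- vapply(k_diff, function(k) sum(p[abs(I - J) == k]), numeric(1))
  k_sum <- (2 * min(iv)):(2 * max(iv))
  pxpy <- vapply(k_sum, function(k) sum(p[(I + J) == k]), numeric(1))
  da <- sum(k_diff * pxmy)
  ent0 <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  HX <- ent0(px); HY <- ent0(py); HXY <- ent0(p)
  pxy_outer <- outer(px, py)
  pos <- p > 0 & pxy_outer > 0
  HXY1 <- -sum(p[pos] * log2(pxy_outer[pos]))
  HXY2 <- ent0(pxy_outer)
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0
  corr <- if (sx > 0 && sy > 0) (sum(I * J * p) - ux * uy) / (sx * sy) else 0
  mcc <- if (ng > 1) {
    Q <- matrix(0, ng, ng)
    for (kk in seq_len(ng)) {
      denom <- px * py[kk]
      ok <- denom > 0
      Q[ok, ] <- Q[ok, ] + outer(p[ok, kk] / denom[ok], p[, kk])
    }
    evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, evq[2]))
  } else 0
  offdiag <- abs(I - J) > 0
  c(Autocorrelation = sum(I * J * p),
    ClusterProminence = sum((I + J - ux - uy)^4 * p),
    ClusterShade = sum((I + J - ux - uy)^3 * p),
    ClusterTendency = sum((I + J - ux - uy)^2 * p),
    Contrast = sum((I - J)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent0(pxmy),
    DifferenceVariance = sum((k_diff - da)^2 * pxmy),
    Id = sum(p / (1 + abs(I - J))),
    Idm = sum(p / (1 + (I - J)^2)),
    Idmn = sum(p / (1 + ((I - J) / ng)^2)),
    Idn = sum(p / (1 + abs(I - J) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[offdiag] / (I - J)[offdiag]^2),
    JointAverage = ux,
    JointEnergy = sum(p^2),
    JointEntropy = HXY,
    MCC = mcc,
    MaximumProbability = max(p),
    SumEntropy = ent0(pxpy),
    SumSquares = sum((I - ux)^2 * p))[GLCM_NAMES]
}

rlm_style_features <- function(counts, np, prefix = c("run", "zone")) {
  prefix <- match.arg(prefix)
  occ_i <- which(rowSums(counts) > 0)
  P <- counts[occ_i, , drop = FALSE]
  iv <- occ_i
  rv <- seq_len(ncol(P))
  Nr <- sum(P)
  p <- P / Nr
  pi_m <- matrix(iv, nrow(P), ncol(P))
  pr_m <- matrix(rv, nrow(P), ncol(P), byrow = TRUE)
  mu_i <- sum(pi_m * p); mu_r <- sum(pr_m * p)
  ent0 <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  vals <- c(
    GrayLevelNonUniformity = sum(rowSums(P)^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / Nr^2,
    GrayLevelVariance = sum((pi_m - mu_i)^2 * p),
    HighGrayLevel = sum(pi_m^2 * p),
    Long = sum(pr_m^2 * p),
    LongHigh = sum(pr_m^2 * pi_m^2 * p),
    LongLow = sum(pr_m^2 * p / pi_m^2),
    LowGrayLevel = sum(p / pi_m^2),
    Entropy = ent0(p),
    LengthNonUniformity = sum(colSums(P)^2) / Nr,
    LengthNonUniformityNormalized = sum(colSums(P)^2) / Nr^2,
    Percentage = Nr / np,
    Variance = sum((pr_m - mu_r)^2 * p),
    Short = sum(p / pr_m^2),
    ShortHigh = sum(pi_m^2 * p / pr_m^2),
    ShortLow = sum(p / (pi_m^2 * pr_m^2)))
  if (prefix == "run") {
    stats::setNames(vals, c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
      "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
      "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
      "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
      "ShortRunLowGrayLevelEmphasis"))[GLRLM_NAMES]
  } else {
    stats::setNames(vals, c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
      "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
      "LowGrayLevelZoneEmphasis", "ZoneEntropy", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage", "ZoneVariance",
      "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "SmallAreaLowGrayLevelEmphasis"))[GLSZM_NAMES]
  }
}

gldm_features <- function(counts) {
  occ_i <- which(rowSums(counts) > 0)
  P <- counts[occ_i, , drop = FALSE]
  iv <- occ_i
  jv <- seq_len(ncol(P))
  Nz <- sum(P)
  p <- P / Nz
  pi_m <- matrix(iv, nrow(P), ncol(P))
  pj_m <- matrix(jv, nrow(P), ncol(P), byrow = TRUE)
  mu_i <- sum(pi_m * p); mu_j <- sum(pj_m * p)
  ent0 <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  stats::setNames(c(
    ent0(p),
    sum(colSums(P)^2) / Nz,
    sum(colSums(P)^2) / Nz^2,
    sum((pj_m - mu_j)^2 * p),
    sum(rowSums(P)^2) / Nz,
    sum((pi_m - mu_i)^2 * p),
    sum(pi_m^2 * p),
    sum(pj_m^2 * p),
    sum(pj_m^2 * pi_m^2 * p),
    sum(pj_m^2 * p / pi_m^2),
    sum(p / pi_m^2),
    sum(p / pj_m^2),
    sum(pi_m^2 * p / pj_m^2),
    sum(p / (pi_m^2 * pj_m^2))), GLDM_NAMES)
}

ngtdm_features <- function(ng) {
  iv <- ng$levels; p <- ng$p; s <- ng$s
  nvp <- sum(ng$n)
  ngp <- length(iv)
  ps <- sum(p * s)
  coarseness <- if (ps > 0) 1 / ps else 1e6  # conventional cap for flat regions
  contrast <- if (ngp > 1) {
    (sum(outer(p, p) * outer(iv, iv, "-")^2) / (ngp * (ngp - 1))) * (sum(s) / nvp)
  } else 0
  busy_den <- sum(abs(outer(iv * p, iv * p, "-")))
  busyness <- if (busy_den > 0) ps / busy_den else 0
  pp <- outer(p, p, "+")
  complexity <- sum(abs(outer(iv, iv, "-")) * outer(p * s, p * s, "+") / pp) / nvp
  strength <- if (sum(s) > 0) sum(pp * outer(iv, iv, "-")^2) / sum(s) else 0
  stats::setNames(c(busyness, coarseness, complexity, contrast, strength),
                  NGTDM_NAMES)
}

#' The 74 texture features
#'
#' Computes the texture feature block from [texture_matrices()]: 23 GLCM
#' features (SumAverage excluded), 16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM
#' features. GLCM and GLRLM features are computed per direction and averaged
#' over the 13 directions. Features that are undefined on a degenerate
#' matrix (for instance GLCM correlation of a single-level region) are 0 by
#' convention; NGTDM coarseness of a perfectly flat region is capped at 1e6.
#'
#' @param mats output of [texture_matrices()].
#' @return named numeric vector of length 74 with names
#'   `glcm_*`, `glrlm_*`, `glszm_*`, `gldm_*`, `ngtdm_*`.
#' @export
texture_features <- function(mats) {
  glcm <- rowMeans(vapply(mats$glcm, glcm_features_one, numeric(23)))
  glrlm <- rowMeans(vapply(mats$glrlm, rlm_style_features, numeric(16),
                           np = mats$n_voxels, prefix = "run"))
  glszm <- rlm_style_features(mats$glszm, np = mats$n_voxels, prefix = "zone")
  gldm <- gldm_features(mats$gldm)
  ngtdm <- ngtdm_features(mats$ngtdm)
  c(stats::setNames(glcm, paste0("glcm_", GLCM_NAMES)),
    stats::setNames(glrlm, paste0("glrlm_", GLRLM_NAMES)),
    stats::setNames(glszm, paste0("glszm_", GLSZM_NAMES)),
    stats::setNames(gldm, paste0("gldm_", GLDM_NAMES)),
    stats::setNames(ngtdm, paste0("ngtdm_", NGTDM_NAMES)))
}
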
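#' Precompute ROI geometry for texture extraction
#'
#' Builds, once per mask, everything the texture-matrix families need:
#' linear indices and coordinates of ROI voxels, the in-ROI 26-neighbour
#' list, and in-ROI voxel-pair lists for the 13 unique 3D direction offsets
#' at distance 1. Reuse the returned object across subjects and wavelet
#' sub-bands sharing the same mask.
#'
#' @param roi_mask 3D logical array.
#' @return A `roi_geometry` list.
#' @export
roi_geometry <- function(roi_mask) {
  d <- dim(roi_mask)
  idx <- which(roi_mask)
  nvox <- length(idx)
  if (nvox < 1L) stop("empty ROI")
  lookup <- array(0L, dim = d)
  lookup[idx] <- seq_len(nvox)
  coords <- arrayInd(idx, d)

  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  neigh_of <- function(off) {
    nc <- cbind(coords[, 1L] + off[1L], coords[, 2L] + off[2L],
                coords[, 3L] + off[3L])
    ok <- nc[, 1L] >= 1L & nc[, 1L] <= d[1L] &
          nc[, 2L] >= 1L & nc[, 2L] <= d[2L] &
          nc[, 3L] >= 1L & nc[, 3L] <= d[3L]
    j <- integer(nvox)
    j[ok] <- lookup[nc[ok, , drop = FALSE]]
    j                                               # 0 = outside ROI/grid
  }
  neigh_mat <- vapply(seq_len(nrow(offs)),
                      function(k) neigh_of(as.integer(offs[k, ])),
                      integer(nvox))                # nvox x 26, 0-padded

  # 13 unique positive directions (lexicographic > 0)
  dir13 <- offs[offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
                (offs$dz == 0 & offs$dy == 0 & offs$dx > 0), ]
  dir13 <- as.matrix(dir13)
  pairs <- lapply(seq_len(nrow(dir13)), function(k) {
    j <- neigh_of(dir13[k, ])
    i <- which(j > 0L)
    cbind(i = i, j = j[i])
  })
  structure(list(dim = d, idx = idx, coords = coords, lookup = lookup,
                 neigh_mat = neigh_mat, dir13 = dir13, pairs = pairs),
            class = "roi_geometry")
}

#' Discretize ROI intensities into equal-width bins
#'
#' Bins span the in-ROI min-max range; the maximum value is assigned to the
#' top bin. A constant ROI maps every voxel to level 1 (with a warning when
#' more than one bin was requested).
#'
#' @param values Numeric vector of in-ROI intensities.
#' @param n_bins Number of gray levels (>= 1).
#' @return List with `levels` (integer vector in 1..n_bins) and `n_levels`.
#' @export
discretize <- function(values, n_bins = 32L) {
  if (n_bins < 1L) stop("n_bins must be >= 1")
  rng <- range(values)
  if (rng[1L] == rng[2L]) {
    if (n_bins > 1L) warning("constant ROI; all voxels assigned level 1")
    return(list(levels = rep(1L, length(values)), n_levels = as.integer(n_bins)))
  }
  w <- (rng[2L] - rng[1L]) / n_bins
  lv <- pmin(as.integer(floor((values - rng[1L]) / w)) + 1L, as.integer(n_bins))
  list(levels = lv, n_levels = as.integer(n_bins))
}

#' First-order statistics of the ROI intensities
#'
#' The 18-feature roster: Energy, TotalEnergy (= Energy times voxel volume),
#' Entropy and Uniformity (on the discretized histogram), Minimum,
#' 10Percentile, 90Percentile, Maximum, Mean, Median, InterquartileRange,
#' Range, MeanAbsoluteDeviation, RobustMeanAbsoluteDeviation (mean absolute
#' deviation of the values inside \[P10, P90\] from their own mean),
#' RootMeanSquared, Skewness, Kurtosis (non-excess; 3 for a Gaussian),
#' Variance (population). Percentiles interpolate linearly between order
#' statistics. Zero-variance input returns Skewness and Kurtosis 0 with a
#' warning.
#'
#' @param values Numeric vector of in-ROI intensities.
#' @param voxel_volume Voxel volume in mm^3 (for TotalEnergy).
#' @param n_bins Histogram bins for Entropy/Uniformity.
#' @return Named numeric vector of length 18.
#' @export
firstorder_features <- function(values, voxel_volume = 27, n_bins = 32L) {
  if (length(values) < 1L) stop("empty ROI")
  n <- length(values)
  q <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       names = FALSE, type = 7)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  if (m2 == 0) {
    warning("zero variance; Skewness and Kurtosis set to 0")
    skew <- kurt <- 0
  } else {
    skew <- mean((values - mu)^3) / m2^1.5
    kurt <- mean((values - mu)^4) / m2^2
  }
  dsc <- suppressWarnings(discretize(values, n_bins))
  p <- tabulate(dsc$levels, dsc$n_levels) / n
  p <- p[p > 0]
  mid <- values[values >= q[1L] & values <= q[5L]]
  c(firstorder_Energy = sum(values^2),
    firstorder_TotalEnergy = voxel_volume * sum(values^2),
    firstorder_Entropy = -sum(p * log2(p)),
    firstorder_Minimum = min(values),
    firstorder_10Percentile = q[1L],
    firstorder_90Percentile = q[5L],
    firstorder_Maximum = max(values),
    firstorder_Mean = mu,
    firstorder_Median = q[3L],
    firstorder_InterquartileRange = q[4L] - q[2L],
    firstorder_Range = diff(range(values)),
    firstorder_MeanAbsoluteDeviation = mean(abs(values - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(mid)) mean(abs(mid - mean(mid))) else 0,
    firstorder_RootMeanSquared = sqrt(mean(values^2)),
    firstorder_Skewness = skew,
    firstorder_Kurtosis = kurt,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2))
}

# ---- gray-level co-occurrence matrix -------------------------------------

# Accumulate the symmetric GLCM over the 13 directions of a geometry.
glcm_matrix <- function(levels, geom, n_levels) {
  P <- matrix(0, n_levels, n_levels)
  for (pr in geom$pairs) {
    if (nrow(pr) == 0L) next
    li <- levels[pr[, 1L]]; lj <- levels[pr[, 2L]]
    tab <- table(factor(li, levels = seq_len(n_levels)),
                 factor(lj, levels = seq_len(n_levels)))
    P <- P + tab + t(tab)
  }
  P
}

#' Gray-level co-occurrence features
#'
#' The GLCM is accumulated over all 13 unique distance-1 3D offsets
#' restricted to in-ROI pairs, symmetrised and normalised; the 22-feature
#' roster drops the degenerate duplicates of the classical list
#' (Dissimilarity, SumVariance, SumAverage). A single-level matrix returns
#' Correlation 1 by convention; a pairless ROI returns all zeros with a
#' warning.
#'
#' @param d Output of [discretize()] (`levels`, `n_levels`).
#' @param geom A [roi_geometry()].
#' @return Named numeric vector of length 22.
#' @export
glcm_features <- function(d, geom) {
  names22 <- paste0("glcm_", c(
    "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
    "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
    "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
    "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy",
    "MaximumProbability", "SumEntropy", "SumSquares"))
  ng <- d$n_levels
  P <- glcm_matrix(d$levels, geom, ng)
  tot <- sum(P)
  if (tot == 0) {
    warning("no in-ROI voxel pairs; GLCM features set to 0")
    return(stats::setNames(numeric(22L), names22))
  }
  p <- P / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(i * p)
  sigma2 <- sum((i - mu)^2 * p)
  sigma <- sqrt(sigma2)
  corr <- if (sigma2 > 0) (sum(i * j * p) - mu^2) / sigma2 else 1

  kdiff <- 0:(ng - 1L)
  pdiff <- vapply(kdiff, function(k) sum(p[abs(i - j) == k]), numeric(1L))
  ksum <- 2:(2L * ng)
  psum <- vapply(ksum, function(k) sum(p[(i + j) == k]), numeric(1L))
  da <- sum(kdiff * pdiff)
  nz <- function(x) x[x > 0]
  ent <- function(q) { q <- nz(q); if (length(q)) -sum(q * log2(q)) else 0 }

  hx <- ent(px)
  hxy <- ent(p)
  pxpy <- outer(px, px)
  m <- p > 0
  hxy1 <- -sum(p[m] * log2(pmax(pxpy[m], .Machine$double.xmin)))
  m2 <- pxpy > 0
  hxy2 <- -sum(pxpy[m2] * log2(pxpy[m2]))
  imc1 <- if (max(hx, hx) > 0) (hxy - hxy1) / max(hx, hx) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))

  offd <- i != j
  stats::setNames(c(
    sum(i * j * p),
    sum((i + j - 2 * mu)^4 * p),
    sum((i + j - 2 * mu)^3 * p),
    sum((i + j - 2 * mu)^2 * p),
    sum((i - j)^2 * p),
    corr,
    da,
    ent(pdiff),
    sum((kdiff - da)^2 * pdiff),
    sum(p / (1 + abs(i - j))),
    sum(p / (1 + (i - j)^2)),
    sum(p / (1 + (i - j)^2 / ng^2)),
    sum(p / (1 + abs(i - j) / ng)),
    imc1,
    imc2,
    sum(p[offd] / (i[offd] - j[offd])^2),
    mu,
    sum(p^2),
    hxy,
    max(p),
    ent(psum),
    sigma2
  ), names22)
}

# ---- run-length matrix ----------------------------------------------------

# P(i, r): maximal runs of equal level along each of the 13 directions.
glrlm_matrix <- function(levels, geom, n_levels) {
  d <- geom$dim
  lookup <- geom$lookup
  coords <- geom$coords
  maxrun <- max(d)
  P <- matrix(0, n_levels, maxrun)
  inroi <- function(x, y, z) {
    x >= 1L && x <= d[1L] && y >= 1L && y <= d[2L] && z >= 1L && z <= d[3L] &&
      lookup[x, y, z] > 0L
  }
  for (k in seq_len(nrow(geom$dir13))) {
    dd <- geom$dir13[k, ]
    for (v in seq_len(nrow(coords))) {
      x <- coords[v, 1L]; y <- coords[v, 2L]; z <- coords[v, 3L]
      lv <- levels[v]
      px <- x - dd[1L]; py <- y - dd[2L]; pz <- z - dd[3L]
      if (inroi(px, py, pz) && levels[lookup[px, py, pz]] == lv) next  # not a start
      len <- 1L
      nx <- x + dd[1L]; ny <- y + dd[2L]; nz <- z + dd[3L]
      while (inroi(nx, ny, nz) && levels[lookup[nx, ny, nz]] == lv) {
        len <- len + 1L
        nx <- nx + dd[1L]; ny <- ny + dd[2L]; nz <- nz + dd[3L]
      }
      P[lv, len] <- P[lv, len] + 1
    }
  }
  P[, seq_len(max(which(colSums(P) > 0), 1L)), drop = FALSE]
}

#' Gray-level run-length features
#'
#' Runs are maximal sequences of equal-level in-ROI voxels along each of the
#' 13 directions; the matrices are summed over directions before the
#' standard 16-feature roster is computed. RunPercentage divides the number
#' of runs by `13 * Nvoxels` (the voxel count per direction).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16.
#' @export
glrlm_features <- function(d, geom) {
  P <- glrlm_matrix(d$levels, geom, d$n_levels)
  nr <- sum(P)
  np <- nrow(geom$coords) * nrow(geom$dir13)
  i <- seq_len(nrow(P)); r <- seq_len(ncol(P))
  pg <- rowSums(P); pr <- colSums(P)
  p <- P / nr
  pgn <- pg / nr; prn <- pr / nr
  mug <- sum(i * pgn); mur <- sum(r * prn)
  pnz <- p[p > 0]
  stats::setNames(c(
    sum(pr / r^2) / nr,
    sum(pr * r^2) / nr,
    sum(pg^2) / nr,
    sum(pg^2) / nr^2,
    sum(pr^2) / nr,
    sum(pr^2) / nr^2,
    nr / np,
    sum((i - mug)^2 * pgn),
    sum((r - mur)^2 * prn),
    -sum(pnz * log2(pnz)),
    sum(pg / i^2) / nr,
    sum(pg * i^2) / nr,
    sum(P / outer(i^2, r^2)) / nr,
    sum(P * outer(i^2, 1 / r^2)) / nr,
    sum(P * outer(1 / i^2, r^2)) / nr,
    sum(P * outer(i^2, r^2)) / nr
  ), paste0("glrlm_", c(
    "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage",
    "GrayLevelVariance", "RunVariance", "RunEntropy",
    "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
    "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
    "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")))
}

# ---- size-zone matrix -----------------------------------------------------

# Zones: 26-connected components of equal gray level within the ROI.
glszm_zones <- function(levels, geom) {
  n <- length(levels)
  visited <- logical(n)
  zones <- list()
  for (s in seq_len(n)) {
    if (visited[s]) next
    lv <- levels[s]
    comp <- integer(0)
    stack <- s
    visited[s] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      comp <- c(comp, v)
      nb <- geom$neigh_mat[v, ]
      nb <- nb[nb > 0L]
      nb <- nb[!visited[nb] & levels[nb] == lv]
      if (length(nb)) {
        visited[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
    zones[[length(zones) + 1L]] <- c(level = lv, size = length(comp))
  }
  do.call(rbind, zones)
}

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal gray level within the ROI;
#' the (level, size) count matrix feeds the standard 16-feature roster.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16.
#' @export
glszm_features <- function(d, geom) {
  z <- glszm_zones(d$levels, geom)
  np <- nrow(geom$coords)
  smax <- max(z[, "size"])
  P <- matrix(0, d$n_levels, smax)
  for (k in seq_len(nrow(z))) P[z[k, 1L], z[k, 2L]] <- P[z[k, 1L], z[k, 2L]] + 1
  nz <- sum(P)
  i <- seq_len(nrow(P)); s <- seq_len(ncol(P))
  pg <- rowSums(P); ps <- colSums(P)
  p <- P / nz
  pgn <- pg / nz; psn <- ps / nz
  mug <- sum(i * pgn); mus <- sum(s * psn)
  pnz <- p[p > 0]
  stats::setNames(c(
    sum(ps / s^2) / nz,
    sum(ps * s^2) / nz,
    sum(pg^2) / nz,
    sum(pg^2) / nz^2,
    sum(ps^2) / nz,
    sum(ps^2) / nz^2,
    nz / np,
    sum((i - mug)^2 * pgn),
    sum((s - mus)^2 * psn),
    -sum(pnz * log2(pnz)),
    sum(pg / i^2) / nz,
    sum(pg * i^2) / nz,
    sum(P / outer(i^2, s^2)) / nz,
    sum(P * outer(i^2, 1 / s^2)) / nz,
    sum(P * outer(1 / i^2, s^2)) / nz,
    sum(P * outer(i^2, s^2)) / nz
  ), paste0("glszm_", c(
    "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "ZonePercentage",
    "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
    "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
    "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
    "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")))
}

# ---- neighbourhood gray-tone difference matrix ----------------------------

#' Neighbourhood gray-tone difference features
#'
#' For each level i present in the ROI, `s_i` sums, over ROI voxels of level
#' i having at least one in-ROI 26-neighbour, the absolute difference
#' between i and the mean level of those neighbours. The five standard
#' features follow. A uniform ROI has all `s_i = 0`; Coarseness then
#' returns the documented sentinel 1e6.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 5.
#' @export
ngtdm_features <- function(d, geom) {
  lv <- d$levels
  ng <- d$n_levels
  nb <- geom$neigh_mat
  nbl <- matrix(0, nrow(nb), ncol(nb))
  has <- nb > 0L
  nbl[has] <- lv[nb[has]]
  cnt <- rowSums(has)
  valid <- cnt > 0L
  nbar <- rowSums(nbl)[valid] / cnt[valid]
  lvv <- lv[valid]
  nv <- sum(valid)
  s <- vapply(seq_len(ng), function(i) sum(abs(i - nbar)[lvv == i]),
              numeric(1L))
  n_i <- tabulate(lvv, ng)
  p <- n_i / nv
  present <- which(p > 0)
  ngp <- length(present)
  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(p[present], p[present]) *
           outer(present, present, function(a, b) (a - b)^2)) /
       (ngp * (ngp - 1))) * (sum(s) / nv)
  } else 0
  ip <- present
  busy_den <- sum(abs(outer(ip * p[ip], ip * p[ip], "-")))
  busyness <- if (busy_den > 0) coarse_den / busy_den else 0
  pij_i <- outer(p[ip], rep(1, ngp)); pij_j <- t(pij_i)
  sij_i <- outer(s[ip], rep(1, ngp)); sij_j <- t(sij_i)
  dij <- abs(outer(ip, ip, "-"))
  complexity <- sum(dij * (pij_i * sij_i + pij_j * sij_j) /
                      (pij_i + pij_j)) / nv
  strength_den <- sum(s)
  strength <- if (strength_den > 0)
    sum((pij_i + pij_j) * dij^2) / strength_den else 0
  c(ngtdm_Coarseness = coarseness, ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness, ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}

# ---- gray-level dependence matrix -----------------------------------------

#' Gray-level dependence features
#'
#' The dependence count of a voxel is the number of its in-ROI 26-neighbours
#' whose level differs from its own by at most `alpha`. The (level,
#' dependence) count matrix is indexed by j = dependence + 1 in the
#' standard 14-feature formulas.
#'
#' @inheritParams glcm_features
#' @param alpha Level tolerance (default 0: exact equality).
#' @return Named numeric vector of length 14.
#' @export
gldm_features <- function(d, geom, alpha = 0) {
  lv <- d$levels
  nb <- geom$neigh_mat
  has <- nb > 0L
  dep <- integer(length(lv))
  for (v in seq_along(lv)) {
    nbv <- nb[v, has[v, ]]
    dep[v] <- sum(abs(lv[nbv] - lv[v]) <= alpha)
  }
  jmax <- max(dep) + 1L
  P <- matrix(0, d$n_levels, jmax)
  for (v in seq_along(lv)) P[lv[v], dep[v] + 1L] <- P[lv[v], dep[v] + 1L] + 1
  nz <- sum(P)
  i <- seq_len(nrow(P)); j <- seq_len(ncol(P))
  pg <- rowSums(P); pd <- colSums(P)
  p <- P / nz
  pgn <- pg / nz; pdn <- pd / nz
  mug <- sum(i * pgn); mud <- sum(j * pdn)
  pnz <- p[p > 0]
  stats::setNames(c(
    sum(pd / j^2) / nz,
    sum(pd * j^2) / nz,
    sum(pg^2) / nz,
    sum(pd^2) / nz,
    sum(pd^2) / nz^2,
    sum((i - mug)^2 * pgn),
    sum((j - mud)^2 * pdn),
    -sum(pnz * log2(pnz)),
    sum(pg / i^2) / nz,
    sum(pg * i^2) / nz,
    sum(P / outer(i^2, j^2)) / nz,
    sum(P * outer(1 / i^2, j^2)) / nz,
    sum(P * outer(i^2, 1 / j^2)) / nz,
    sum(P * outer(i^2, j^2)) / nz
  ), paste0("gldm_", c(
    "SmallDependenceEmphasis", "LargeDependenceEmphasis",
    "GrayLevelNonUniformity", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "GrayLevelVariance",
    "DependenceVariance", "DependenceEntropy",
    "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
    "SmallDependenceLowGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis",
    "SmallDependenceHighGrayLevelEmphasis",
    "LargeDependenceHighGrayLevelEmphasis")))
}

# The 91 features (18 first-order + 73 texture) of one image over one ROI.
features_91 <- function(values3d, geom, voxel_volume, n_bins) {
  vals <- values3d[geom$idx]
  dsc <- suppressWarnings(discretize(vals, n_bins))
  c(firstorder_features(vals, voxel_volume, n_bins),
    glcm_features(dsc, geom),
    glrlm_features(dsc, geom),
    glszm_features(dsc, geom),
    ngtdm_features(dsc, geom),
    gldm_features(dsc, geom))
}

#' Extract the full 819-feature radiomics vector
#'
#' 91 features (18 first-order + 73 texture) from the original image plus 91
#' from each of the 8 undecimated wavelet sub-bands (`wavelet-<S>_` prefix),
#' for a total of 819. Discretization is recomputed per sub-band over that
#' sub-band's in-ROI range.
#'
#' @param values 3D numeric map (e.g. a derivative map's final image).
#' @param roi_mask 3D logical ROI (bilateral hippocampus: labels 1 and 2
#'   merged).
#' @param voxel_mm Voxel sizes in mm.
#' @param n_bins Gray levels for discretization.
#' @param wavelet Wavelet basis for the sub-bands.
#' @param geom Optional precomputed [roi_geometry()] for `roi_mask`.
#' @return Named numeric vector of length 819.
#' @export
extract_all <- function(values, roi_mask, voxel_mm = c(3, 3, 3),
                        n_bins = 32L, wavelet = "coif1", geom = NULL) {
  stopifnot(all(dim(values) == dim(roi_mask)))
  if (sum(roi_mask) < 27L) stop("ROI must contain at least 27 voxels")
  if (!all(is.finite(values))) stop("non-finite values in map")
  if (is.null(geom)) geom <- roi_geometry(roi_mask)
  vv <- prod(rep_len(voxel_mm, 3L))
  out <- features_91(values, geom, vv, n_bins)
  sb <- wavelet_subbands(values, wavelet)
  for (nm in names(sb)) {
    f <- features_91(sb[[nm]], geom, vv, n_bins)
    names(f) <- paste0("wavelet-", nm, "_", names(f))
    out <- c(out, f)
  }
  stopifnot(length(out) == 819L, !anyDuplicated(names(out)))
  out
}
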
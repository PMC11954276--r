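#' Construct a 4D BOLD container
#'
#' @param data 4D numeric array ordered (x, y, z, t).
#' @param tr_seconds Repetition time in seconds.
#' @param voxel_mm Voxel edge lengths in mm.
#' @param brain_mask 3D logical array; defaults to the full grid.
#' @return A `bold4d` list.
#' @export
bold4d <- function(data, tr_seconds, voxel_mm = c(3, 3, 3),
                   brain_mask = NULL) {
  stopifnot(length(dim(data)) == 4L, tr_seconds > 0)
  if (dim(data)[4L] < 32L) stop("need at least 32 timepoints")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = dim(data)[1:3])
  stopifnot(all(dim(brain_mask) == dim(data)[1:3]))
  if (!any(brain_mask)) stop("brain mask is empty")
  if (!all(is.finite(data))) stop("non-finite values in BOLD data")
  structure(list(data = data, tr_seconds = tr_seconds,
                 voxel_mm = as.numeric(voxel_mm),
                 brain_mask = brain_mask), class = "bold4d")
}

#' Detrend and band-pass filter time series
#'
#' Removes the least-squares linear trend per series, then applies an ideal
#' (frequency-domain) band-pass: Fourier bins with frequency strictly below
#' `band[1]` or above `band[2]` are zeroed (the DC bin always is). Operates
#' column-wise on a timepoints-by-series matrix or on a single vector.
#'
#' @param ts Numeric vector or matrix (time in rows).
#' @param tr Sampling interval in seconds.
#' @param band Pass band in Hz, `c(low, high)` with 0 < low < high <= Nyquist.
#' @return Filtered series, same shape as the input.
#' @export
detrend_bandpass <- function(ts, tr, band = c(0.01, 0.1)) {
  vec <- is.null(dim(ts))
  x <- if (vec) matrix(ts, ncol = 1L) else ts
  n <- nrow(x)
  if (n < 32L) stop("series length must be >= 32")
  nyq <- 1 / (2 * tr)
  if (!(band[1L] > 0 && band[1L] < band[2L]))
    stop("need 0 < low < high for the pass band")
  if (band[2L] > nyq + 1e-12)
    stop("band upper edge ", band[2L], " Hz exceeds Nyquist ", nyq, " Hz")
  t_idx <- seq_len(n)
  X <- cbind(1, t_idx - mean(t_idx))
  x <- x - X %*% qr.solve(X, x)                     # linear detrend
  freqs <- (seq_len(n) - 1L) / (n * tr)             # bin k-1 -> (k-1)/(n*tr)
  freqs <- pmin(freqs, 1 / tr - freqs)              # fold negative freqs
  keep <- freqs >= band[1L] - 1e-12 & freqs <= band[2L] + 1e-12
  keep[1L] <- FALSE                                 # DC
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  out <- Re(stats::mvfft(xf, inverse = TRUE)) / n
  if (vec) drop(out) else out
}

# Flatten bold data to a timepoints x voxels matrix restricted to a mask.
bold_matrix <- function(bold, mask = bold$brain_mask) {
  d <- dim(bold$data)
  m <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4L])
  t(m[as.vector(mask), , drop = FALSE])
}

derivative_map <- function(kind, raw, bold, params, smooth_after_z = FALSE) {
  v <- raw[bold$brain_mask]
  z <- if (sqrt(mean((v - mean(v))^2)) == 0) {
    warning(kind, " map is constant over the mask; z map set to 0")
    array(0, dim = dim(raw))
  } else ztransform(raw, bold$brain_mask)
  final <- if (smooth_after_z) {
    smooth_gaussian(z, params$fwhm_mm, bold$voxel_mm)
  } else z
  structure(list(kind = kind, raw = raw, z = z, final = final,
                 params = params), class = "derivative_map")
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Per voxel, the mean over in-band frequency bins of the square root of the
#' raw periodogram `|X_k|^2 / N` of the (already detrended and filtered)
#' series. The map is then z-transformed over the brain mask.
#'
#' @param bold A [bold4d()], already preprocessed.
#' @param band Frequency band in Hz.
#' @return A `derivative_map` with fields `raw`, `z`, `final`.
#' @export
compute_alff <- function(bold, band = c(0.01, 0.1)) {
  d <- dim(bold$data); n <- d[4L]
  freqs <- (seq_len(n) - 1L) / (n * bold$tr_seconds)
  half <- 2:(floor(n / 2) + 1L)                # positive-frequency bins
  inband <- half[freqs[half] >= band[1L] - 1e-12 &
                 freqs[half] <= band[2L] + 1e-12]
  if (length(inband) == 0L) stop("no frequency bins inside the band")
  ts <- bold_matrix(bold)
  amp <- sqrt(Mod(stats::mvfft(ts)[inband, , drop = FALSE])^2 / n)
  raw <- array(0, dim = d[1:3])
  raw[bold$brain_mask] <- colMeans(amp)
  derivative_map("ALFF", raw, bold, list(band = band))
}

#' Kendall's coefficient of concordance (W)
#'
#' Concordance of m rankings of n timepoints, with midranks for ties and the
#' standard tie correction in the denominator:
#' `W = 12 S / (m^2 (n^3 - n) - m sum_j T_j)` where S is the sum of squared
#' deviations of the per-timepoint rank sums from their mean and
#' `T_j = sum(t^3 - t)` over tie groups of series j.
#'
#' @param series_set Numeric matrix, one series per column (n x m).
#' @return W in \[0, 1\]; 0 with a warning when the denominator vanishes
#'   (all series constant).
#' @export
kendall_w <- function(series_set) {
  x <- as.matrix(series_set)
  n <- nrow(x); m <- ncol(x)
  if (m < 2L || n < 2L) stop("need at least 2 series of length >= 2")
  r <- apply(x, 2L, rank)
  tie_term <- sum(apply(x, 2L, function(col) {
    t <- table(col); sum(t^3 - t)
  }))
  rs <- rowSums(r)
  s <- sum((rs - mean(rs))^2)
  denom <- m^2 * (n^3 - n) - m * tie_term
  if (denom <= 0) {
    warning("all series constant; Kendall W undefined, returning 0")
    return(0)
  }
  min(1, max(0, 12 * s / denom))
}

# Sum a 4D array (and a count volume) over shifted copies of itself across
# the 26-neighbourhood + self, respecting a mask: out-of-mask voxels
# contribute nothing.
masked_neighborhood_sums <- function(arr4d, extra3d, mask) {
  d <- dim(arr4d)
  acc <- array(0, dim = d)
  acc3 <- array(0, dim = d[1:3])
  cnt <- array(0, dim = d[1:3])
  mnum <- array(as.numeric(mask), dim = d[1:3])
  arr4d <- arr4d * as.vector(mnum)
  extra3d <- extra3d * mnum
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- max(1, 1 + dx):min(d[1L], d[1L] + dx)
    ys <- max(1, 1 + dy):min(d[2L], d[2L] + dy)
    zs <- max(1, 1 + dz):min(d[3L], d[3L] + dz)
    xd <- xs - dx; yd <- ys - dy; zd <- zs - dz
    acc[xd, yd, zd, ] <- acc[xd, yd, zd, ] + arr4d[xs, ys, zs, , drop = FALSE]
    acc3[xd, yd, zd] <- acc3[xd, yd, zd] + extra3d[xs, ys, zs]
    cnt[xd, yd, zd] <- cnt[xd, yd, zd] + mnum[xs, ys, zs]
  }
  list(sum4 = acc, sum3 = acc3, count = cnt)
}

#' Regional homogeneity (ReHo)
#'
#' Kendall's W over each in-mask voxel and its in-mask 26-neighbours,
#' computed on unsmoothed band-passed data, then z-transformed and finally
#' smoothed (compute -> z -> smooth). A voxel with no in-mask neighbours
#' gets ReHo 0 with a warning.
#'
#' @param bold A [bold4d()] (unsmoothed, band-passed).
#' @param fwhm_mm Smoothing kernel applied to the z map.
#' @return A `derivative_map`; `raw` lies in \[0, 1\].
#' @export
compute_reho <- function(bold, fwhm_mm = 6) {
  d <- dim(bold$data); n <- d[4L]
  mask <- bold$brain_mask
  flat <- matrix(bold$data, nrow = prod(d[1:3]))
  ranks <- matrix(0, nrow = prod(d[1:3]), ncol = n)
  idx <- which(as.vector(mask))
  ranks[idx, ] <- t(apply(flat[idx, , drop = FALSE], 1L, rank))
  tie3 <- numeric(prod(d[1:3]))
  tie3[idx] <- apply(flat[idx, , drop = FALSE], 1L, function(v) {
    if (anyDuplicated(v) == 0L) return(0)
    t <- table(v); sum(t^3 - t)
  })
  r4 <- array(ranks, dim = c(d[1:3], n))
  sums <- masked_neighborhood_sums(r4, array(tie3, dim = d[1:3]), mask)
  m <- sums$count                                    # in-mask m per voxel
  rs <- matrix(sums$sum4, nrow = prod(d[1:3]))
  s <- rowSums(rs^2) - n * (as.vector(m) * (n + 1) / 2)^2
  denom <- as.vector(m)^2 * (n^3 - n) - as.vector(m) * as.vector(sums$sum3)
  w <- numeric(prod(d[1:3]))
  ok <- as.vector(mask) & denom > 0 & as.vector(m) >= 2
  w[ok] <- pmin(1, pmax(0, 12 * s[ok] / denom[ok]))
  lone <- as.vector(mask) & as.vector(m) < 2
  if (any(lone))
    warning(sum(lone), " voxel(s) with no in-mask neighbours; ReHo set to 0")
  raw <- array(w, dim = d[1:3])
  derivative_map("ReHo", raw, bold,
                 list(fwhm_mm = fwhm_mm), smooth_after_z = TRUE)
}

#' Voxel-mirrored homotopic connectivity (VMHC)
#'
#' Pearson correlation between each in-mask voxel's time series and that of
#' its mirror voxel across the x mid-plane. Requires an even x dimension and
#' an x-symmetric brain mask. Zero-variance voxels get 0 with a warning.
#'
#' @param bold A [bold4d()] (smoothed, band-passed input).
#' @return A `derivative_map`; `raw` lies in \[-1, 1\] and is x-symmetric.
#' @export
compute_vmhc <- function(bold) {
  d <- dim(bold$data)
  if (d[1L] %% 2L != 0L) stop("grid x-dimension must be even")
  mask <- bold$brain_mask
  flipped_mask <- mask[d[1L]:1, , , drop = FALSE]
  bad <- sum(mask != flipped_mask)
  if (bad > 0)
    stop("brain mask is not x-symmetric: ", bad, " offending voxel(s)")
  x <- bold$data
  y <- x[d[1L]:1, , , , drop = FALSE]
  xm <- matrix(x, nrow = prod(d[1:3])); ym <- matrix(y, nrow = prod(d[1:3]))
  xm <- xm - rowMeans(xm); ym <- ym - rowMeans(ym)
  num <- rowSums(xm * ym)
  den <- sqrt(rowSums(xm^2) * rowSums(ym^2))
  r <- numeric(prod(d[1:3]))
  ok <- as.vector(mask) & den > 0
  r[ok] <- pmin(1, pmax(-1, num[ok] / den[ok]))
  if (any(as.vector(mask) & den == 0))
    warning("zero-variance voxel(s) in VMHC; set to 0")
  raw <- array(r, dim = d[1:3])
  derivative_map("VMHC", raw, bold, list())
}

#' Weighted degree centrality (DC)
#'
#' For each in-mask voxel, the sum of its Pearson correlations with every
#' other in-mask voxel that exceed `r_threshold` (positive side only, self
#' excluded). Computed on unsmoothed data; the map is z-transformed and then
#' smoothed, as for ReHo. Constant-series voxels contribute 0 with a warning.
#'
#' @param bold A [bold4d()] (unsmoothed, band-passed).
#' @param r_threshold Correlation threshold (default 0.25).
#' @param fwhm_mm Smoothing applied to the z map.
#' @return A `derivative_map`; `raw` is non-negative.
#' @export
compute_dc <- function(bold, r_threshold = 0.25, fwhm_mm = 6) {
  mask <- bold$brain_mask
  if (sum(mask) < 2L) stop("need at least 2 in-mask voxels")
  ts <- bold_matrix(bold)
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " constant voxel series; contribute 0 to DC")
  ts[, sds == 0] <- stats::rnorm(nrow(ts)) * 0      # keep dims; r stays NA-free
  cm <- suppressWarnings(stats::cor(ts))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  cm[cm <= r_threshold] <- 0
  dcv <- colSums(cm)
  raw <- array(0, dim = dim(bold$data)[1:3])
  raw[mask] <- dcv
  derivative_map("DC", raw, bold,
                 list(r_threshold = r_threshold, fwhm_mm = fwhm_mm),
                 smooth_after_z = TRUE)
}

#' Separable Gaussian smoothing of a 3D map
#'
#' Per-axis sigma is `fwhm_mm / (2 sqrt(2 log 2))` converted to voxel units;
#' boundaries are handled by reflection; the kernel is normalised to sum 1,
#' so a constant map is unchanged and total mass is conserved. `fwhm_mm = 0`
#' is the identity.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm Full width at half maximum in mm.
#' @param voxel_mm Voxel sizes in mm (length 3 or scalar).
#' @return Smoothed array of the same shape.
#' @export
smooth_gaussian <- function(vol, fwhm_mm, voxel_mm = c(3, 3, 3)) {
  if (fwhm_mm < 0) stop("fwhm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  voxel_mm <- rep_len(voxel_mm, 3L)
  for (ax in 1:3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm[ax]
    rad <- max(1L, ceiling(4 * sigma))
    k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
    k <- k / sum(k)
    vol <- convolve_axis_reflect(vol, k, ax)
  }
  vol
}

# 1D convolution along one spatial axis of a 3D or 4D array with reflective
# ("symmetric") boundary handling: index -i maps to i+1, index n+i to n-i+1.
# For 4D input the time axis rides along untouched.
convolve_axis_reflect <- function(vol, kernel, axis) {
  d <- dim(vol)
  n <- d[axis]
  rad <- (length(kernel) - 1L) %/% 2L
  reflect <- function(i) {
    i <- abs(i - 1L) + 1L
    over <- i > n
    i[over] <- 2L * n - i[over] + 1L
    i
  }
  four <- length(d) == 4L
  out <- array(0, dim = d)
  for (j in seq_along(kernel)) {
    src <- reflect(seq_len(n) + (j - 1L - rad))
    out <- out + kernel[j] * if (four) switch(axis,
      vol[src, , , , drop = FALSE],
      vol[, src, , , drop = FALSE],
      vol[, , src, , drop = FALSE]) else switch(axis,
      vol[src, , , drop = FALSE],
      vol[, src, , drop = FALSE],
      vol[, , src, drop = FALSE])
  }
  out
}

#' Z-transform a map over a mask
#'
#' Centres and scales to mean 0 and population (divide-by-N) standard
#' deviation 1 over the mask; voxels outside the mask are set to 0.
#'
#' @param map 3D numeric array.
#' @param mask 3D logical array.
#' @return Z-scored array.
#' @export
ztransform <- function(map, mask) {
  v <- map[mask]
  mu <- mean(v)
  sdp <- sqrt(mean((v - mu)^2))
  if (sdp == 0) stop("zero variance inside the mask; cannot z-transform")
  out <- array(0, dim = dim(map))
  out[mask] <- (v - mu) / sdp
  out
}

#' Compute all requested derivative maps from one BOLD volume
#'
#' Applies the fixed preprocessing order: linear detrend, then 6 mm Gaussian
#' smoothing for the ALFF/VMHC branch only (ReHo and DC are computed on
#' unsmoothed data), then the 0.01-0.1 Hz band-pass; each metric is computed,
#' z-transformed, and the ReHo/DC z maps are smoothed afterwards.
#'
#' @param bold A raw [bold4d()].
#' @param metrics Subset of `c("ALFF", "ReHo", "VMHC", "DC")`.
#' @param band Pass band in Hz.
#' @param fwhm_mm Smoothing kernel FWHM in mm.
#' @param r_threshold DC correlation threshold.
#' @return Named list of `derivative_map` objects.
#' @export
derive_maps <- function(bold, metrics = c("ALFF", "ReHo", "VMHC", "DC"),
                        band = c(0.01, 0.1), fwhm_mm = 6,
                        r_threshold = 0.25) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  d <- dim(bold$data)
  filt_raw <- filt_smooth <- NULL
  flat <- matrix(bold$data, nrow = prod(d[1:3]))
  if (any(metrics %in% c("ReHo", "DC"))) {
    fr <- t(detrend_bandpass(t(flat), bold$tr_seconds, band))
    filt_raw <- bold4d(array(fr, dim = d), bold$tr_seconds, bold$voxel_mm,
                       bold$brain_mask)
  }
  if (any(metrics %in% c("ALFF", "VMHC"))) {
    dt <- t(detrend_only(t(flat)))
    sm <- smooth_gaussian(array(dt, dim = d), fwhm_mm, bold$voxel_mm)
    fs <- t(detrend_bandpass(t(matrix(sm, nrow = prod(d[1:3]))),
                             bold$tr_seconds, band))
    filt_smooth <- bold4d(array(fs, dim = d), bold$tr_seconds, bold$voxel_mm,
                          bold$brain_mask)
  }
  out <- list()
  if ("ALFF" %in% metrics) out$ALFF <- compute_alff(filt_smooth, band)
  if ("ReHo" %in% metrics) out$ReHo <- compute_reho(filt_raw, fwhm_mm)
  if ("VMHC" %in% metrics) out$VMHC <- compute_vmhc(filt_smooth)
  if ("DC" %in% metrics) out$DC <- compute_dc(filt_raw, r_threshold, fwhm_mm)
  out
}

detrend_only <- function(x) {
  n <- nrow(x)
  t_idx <- seq_len(n)
  X <- cbind(1, t_idx - mean(t_idx))
  x - X %*% qr.solve(X, x)
}
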
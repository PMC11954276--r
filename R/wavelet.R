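#' One-level undecimated 3D wavelet decomposition
#'
#' Applies the low-pass (L) or high-pass (H) analysis filter of the chosen
#' wavelet along each of the three axes in turn, producing the 8 sub-bands
#' labelled by the letter applied along (x, y, z), e.g. `"HLL"` = high-pass
#' along x, low-pass along y and z. The transform is stationary (no
#' decimation) with symmetric (half-sample reflection) signal extension, so
#' every sub-band has the shape of the input and an ROI mask applies
#' unchanged.
#'
#' @param values 3D numeric array; every dimension must be at least the
#'   filter length.
#' @param wavelet Wavelet name; `"coif1"` (default) or `"haar"`.
#' @return Named list of 8 arrays (`LLL`, `LLH`, ..., `HHH`).
#' @export
wavelet_subbands <- function(values, wavelet = "coif1") {
  f <- wavelet_filters(wavelet)
  d <- dim(values)
  if (any(d < length(f$lo)))
    stop("grid dimension smaller than the wavelet filter length (",
         length(f$lo), ")")
  bx <- list(L = filter_axis_sym(values, f$lo, 1L),
             H = filter_axis_sym(values, f$hi, 1L))
  out <- list()
  for (lx in c("L", "H")) {
    by <- list(L = filter_axis_sym(bx[[lx]], f$lo, 2L),
               H = filter_axis_sym(bx[[lx]], f$hi, 2L))
    for (ly in c("L", "H")) for (lz in c("L", "H")) {
      out[[paste0(lx, ly, lz)]] <-
        filter_axis_sym(by[[ly]], if (lz == "L") f$lo else f$hi, 3L)
    }
  }
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

# Analysis filter pairs. High-pass by the quadrature-mirror rule
# hi[k] = (-1)^k lo[L-1-k] (0-based k).
wavelet_filters <- function(wavelet = c("coif1", "haar")) {
  wavelet <- match.arg(wavelet)
  lo <- switch(wavelet,
    coif1 = c(-0.01565572813546454, -0.0727326195128539,
              0.38486484686420286, 0.8525720202122554,
              0.3378976624578092, -0.0727326195128539),
    haar = c(1, 1) / sqrt(2))
  k <- seq_along(lo) - 1L
  hi <- (-1)^k * rev(lo)
  list(lo = lo, hi = hi)
}

# Undecimated 1D filtering along one axis of a 3D array with symmetric
# (half-sample) extension: index 0 -> 1, -1 -> 2, n+1 -> n, n+2 -> n-1.
# Output sample i takes sum_k f[k] * x[i - offset + k - 1] with the filter
# centred at offset = floor(L/2).
filter_axis_sym <- function(vol, f, axis) {
  d <- dim(vol)
  n <- d[axis]
  L <- length(f)
  offset <- L %/% 2L
  ext <- function(i) {
    i <- ifelse(i < 1L, 1L - i, i)
    while (any(i > n)) {
      i <- ifelse(i > n, 2L * n + 1L - i, i)
      i <- ifelse(i < 1L, 1L - i, i)
    }
    i
  }
  out <- array(0, dim = d)
  for (k in seq_len(L)) {
    src <- ext(seq_len(n) + (k - 1L) - offset)
    out <- out + f[k] * switch(axis,
      vol[src, , , drop = FALSE],
      vol[, src, , drop = FALSE],
      vol[, , src, drop = FALSE])
  }
  out
}
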
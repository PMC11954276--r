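#' Specify a synthetic two-group cohort
#'
#' Bundles every knob of the synthetic BOLD generator into one validated
#' object. The defaults emulate a typical resting-state acquisition after
#' volume dropping: 230 retained timepoints at TR = 2 s on a 3 mm isotropic
#' grid. Group effects are expressed as fractional attenuations, in the
#' cognitively impaired (CI) hippocampus only, of the two shared signal
#' components that regional homogeneity and homotopic connectivity measure.
#'
#' @param n_ci,n_cp Number of cognitively impaired / preserved subjects.
#' @param grid_shape Integer triple (x, y, z); x must be even so the grid has
#'   an exact left-right mirror plane.
#' @param n_timepoints Retained timepoints (>= 32).
#' @param tr_seconds Repetition time in seconds.
#' @param voxel_mm Voxel edge lengths in mm (length-3).
#' @param effect_synchrony Fraction in \[0, 1\] by which the locally shared
#'   (27-neighbourhood) component is attenuated inside the CI hippocampus.
#' @param effect_homotopy Fraction in \[0, 1\] by which the mirrored
#'   (homotopic) component is attenuated inside the CI hippocampus.
#' @param noise_sd Standard deviation of the white voxel noise.
#' @param seed Integer seed; fans out to per-subject child seeds.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_ci, n_cp,
                        grid_shape = c(16L, 16L, 12L),
                        n_timepoints = 230L,
                        tr_seconds = 2,
                        voxel_mm = c(3, 3, 3),
                        effect_synchrony = 0,
                        effect_homotopy = 0,
                        noise_sd = 1,
                        seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L))
  if (grid_shape[1L] %% 2L != 0L)
    stop("grid x-dimension must be even (mirror plane required)")
  if (n_ci + n_cp < 4L)
    stop("cohort must contain at least 4 subjects")
  if (n_timepoints < 32L)
    stop("n_timepoints must be at least 32")
  if (effect_synchrony < 0 || effect_synchrony > 1 ||
      effect_homotopy < 0 || effect_homotopy > 1)
    stop("effects must lie in [0, 1]")
  stopifnot(tr_seconds > 0, noise_sd >= 0, length(voxel_mm) == 3L,
            all(voxel_mm > 0))
  structure(list(
    n_ci = as.integer(n_ci), n_cp = as.integer(n_cp),
    grid_shape = grid_shape, n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, voxel_mm = as.numeric(voxel_mm),
    effect_synchrony = effect_synchrony, effect_homotopy = effect_homotopy,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a mirrored bilateral hippocampus label mask
#'
#' Places a discrete Euclidean ball of the given radius in the left half of
#' the grid (label 1) and its exact mirror across the x mid-plane in the
#' right half (label 2). The mirror of 1-based index `i` along x is
#' `nx + 1 - i`.
#'
#' @param grid_shape Integer triple; x even.
#' @param blob_radius Ball radius in voxels (>= 0). Radius 0 gives a single
#'   voxel per side.
#' @return Integer 3D array with values 0 (background), 1 (left), 2 (right).
#' @export
generate_atlas_mask <- function(grid_shape, blob_radius = 2) {
  grid_shape <- as.integer(grid_shape)
  if (grid_shape[1L] %% 2L != 0L) stop("grid x-dimension must be even")
  nx <- grid_shape[1L]; ny <- grid_shape[2L]; nz <- grid_shape[3L]
  cx <- max(1L, round(nx / 4)); cy <- ceiling(ny / 2); cz <- ceiling(nz / 2)
  r <- blob_radius
  if (cx - r < 1 || cx + r > nx / 2 || cy - r < 1 || cy + r > ny ||
      cz - r < 1 || cz + r > nz)
    stop("blob of radius ", r, " does not fit inside the grid")
  mask <- array(0L, dim = grid_shape)
  off <- seq(-floor(r), floor(r))
  for (dx in off) for (dy in off) for (dz in off) {
    if (dx * dx + dy * dy + dz * dz <= r * r) {
      mask[cx + dx, cy + dy, cz + dz] <- 1L
      mask[nx + 1L - (cx + dx), cy + dy, cz + dz] <- 2L
    }
  }
  mask
}

# Band-limited unit-variance signals: each row of the result is a sum of K
# sinusoids at frequencies drawn uniformly in `band`, with random phases.
band_limited_signals <- function(n_signals, n_t, tr, band = c(0.01, 0.1),
                                 n_sinusoids = 8L) {
  tvec <- (seq_len(n_t) - 1L) * tr
  out <- matrix(0, n_signals, n_t)
  for (k in seq_len(n_sinusoids)) {
    f <- stats::runif(n_signals, band[1L], band[2L])
    phi <- stats::runif(n_signals, 0, 2 * pi)
    out <- out + sin(outer(2 * pi * f, tvec) + phi)
  }
  out * sqrt(2 / n_sinusoids)
}

# Mirror a (nx/2, ny, nz, t) half-grid array into a full symmetric 4D array.
mirror_half <- function(half, nx) {
  dh <- dim(half)
  full <- array(0, dim = c(nx, dh[2L], dh[3L], dh[4L]))
  full[seq_len(nx / 2L), , , ] <- half
  full[seq(nx, nx / 2L + 1L), , , ] <- half
  full
}

# Sum of a 4D array over the in-grid 27-neighbourhood of each voxel
# (self included), together with the per-voxel neighbour count.
neighborhood_sum_4d <- function(arr) {
  d <- dim(arr)
  acc <- array(0, dim = d)
  cnt <- array(0, dim = d[1:3])
  ones <- array(1, dim = d[1:3])
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- max(1, 1 + dx):min(d[1L], d[1L] + dx)
    ys <- max(1, 1 + dy):min(d[2L], d[2L] + dy)
    zs <- max(1, 1 + dz):min(d[3L], d[3L] + dz)
    xd <- xs - dx; yd <- ys - dy; zd <- zs - dz
    acc[xd, yd, zd, ] <- acc[xd, yd, zd, ] + arr[xs, ys, zs, , drop = FALSE]
    cnt[xd, yd, zd] <- cnt[xd, yd, zd] + ones[xs, ys, zs]
  }
  list(sum = acc, count = cnt)
}

#' Generate one subject's 4D BOLD-like volume
#'
#' Each voxel's time series is the sum of three components, all reproducible
#' from the cohort seed and `subject_index`:
#' \itemize{
#'   \item a locally shared band-limited component: independent band-limited
#'     sources are laid out mirror-symmetrically on the grid and averaged over
#'     each voxel's 27-neighbourhood (normalised to unit variance), so
#'     neighbouring voxels share most of their signal;
#'   \item a homotopic band-limited component, identical at a voxel and its
#'     x-mirror but independent across voxel pairs;
#'   \item white Gaussian noise of sd `noise_sd` (not symmetric).
#' }
#' For CI subjects the two shared components are multiplied by
#' `1 - effect * severity` inside the hippocampus mask, which lowers the
#' local rank concordance (ReHo) and the mirrored correlation (VMHC) there
#' by raising the relative noise share.
#'
#' @param spec A [cohort_spec()].
#' @param mask Label volume from [generate_atlas_mask()] (0/1/2).
#' @param group `"CI"` or `"CP"`.
#' @param subject_index Integer used to derive the per-subject child seed.
#' @param severity Per-subject multiplier in \[0, 1\] applied to both effects.
#' @return A [bold4d()] object whose brain mask is the full grid.
#' @export
generate_bold <- function(spec, mask, group = c("CI", "CP"),
                          subject_index = 1L, severity = 1) {
  group <- match.arg(group)
  if (spec$n_timepoints < 32L) stop("insufficient length: need >= 32 timepoints")
  stopifnot(all(dim(mask) == spec$grid_shape))
  d <- spec$grid_shape; nt <- spec$n_timepoints
  set.seed(child_seed(spec$seed, subject_index))

  n_half <- (d[1L] %/% 2L) * d[2L] * d[3L]
  src <- band_limited_signals(n_half, nt, spec$tr_seconds)
  S <- mirror_half(array(src, dim = c(d[1L] %/% 2L, d[2L], d[3L], nt)), d[1L])
  ns <- neighborhood_sum_4d(S)
  local <- ns$sum / sqrt(as.vector(ns$count))   # unit variance per voxel

  homo_src <- band_limited_signals(n_half, nt, spec$tr_seconds)
  homo <- mirror_half(array(homo_src, dim = c(d[1L] %/% 2L, d[2L], d[3L], nt)),
                      d[1L])

  att_s <- att_h <- array(1, dim = d)
  if (group == "CI") {
    hip <- mask > 0L
    att_s[hip] <- 1 - spec$effect_synchrony * severity
    att_h[hip] <- 1 - spec$effect_homotopy * severity
  }
  data <- as.vector(att_s) * local + as.vector(att_h) * homo
  if (spec$noise_sd > 0)
    data <- data + array(stats::rnorm(prod(d) * nt, sd = spec$noise_sd),
                         dim = c(d, nt))
  bold4d(data, tr_seconds = spec$tr_seconds, voxel_mm = spec$voxel_mm,
         brain_mask = array(TRUE, dim = d))
}

# Deterministic fan-out of the global seed into per-subject child seeds.
child_seed <- function(seed, counter) {
  (as.integer(seed) * 10007L + 131L * as.integer(counter)) %% 2147483629L
}

#' Generate a clinical table with planted effects
#'
#' MoCA respects the diagnostic definition by construction: CI subjects score
#' below 26, CP subjects at or above 26, with `planted_moca_gap` controlling
#' the distance between the groups. The remaining scales are drawn with a
#' target correlation `effect_cor` to the per-subject injected imaging effect
#' (attenuation times severity), clipped to each instrument's range.
#'
#' @param spec A [cohort_spec()].
#' @param group_assignments Character vector of `"CI"` / `"CP"`.
#' @param planted_moca_gap Non-negative MoCA points separating the groups.
#' @param effect_cor Target correlation between each scale score and the
#'   injected effect (0 = unrelated).
#' @param severity Per-subject severity multipliers (recycled; CI only).
#' @param seed Seed for the clinical draws.
#' @return A data.frame with one row per subject.
#' @export
generate_clinical <- function(spec, group_assignments, planted_moca_gap = 8,
                              effect_cor = 0.4, severity = 1,
                              seed = spec$seed + 1L) {
  if (planted_moca_gap < 0) stop("planted_moca_gap must be >= 0")
  stopifnot(all(group_assignments %in% c("CI", "CP")))
  n <- length(group_assignments)
  ci <- group_assignments == "CI"
  severity <- rep_len(severity, n)
  set.seed(as.integer(seed))

  gap <- planted_moca_gap
  moca <- numeric(n)
  moca[ci] <- pmax(0, 26 - gap / 2 - abs(stats::rnorm(sum(ci), 0, 2)) - 0.5)
  moca[!ci] <- pmin(30, 26 + pmin(abs(stats::rnorm(sum(!ci), 1 + gap / 4, 1.5)), 4))

  # injected imaging effect per subject (what the BOLD generator applied)
  injected <- ifelse(ci, pmax(spec$effect_synchrony, spec$effect_homotopy) *
                       severity, 0)
  planted_scale <- function(mean, sd, lo, hi) {
    z <- if (stats::sd(injected) > 0) {
      effect_cor * (injected - mean(injected)) / stats::sd(injected) +
        sqrt(max(0, 1 - effect_cor^2)) * stats::rnorm(n)
    } else stats::rnorm(n)
    pmin(hi, pmax(lo, mean + sd * z))
  }
  data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = group_assignments,
    age = round(pmin(90, pmax(30, ifelse(ci, stats::rnorm(n, 61.6, 7.6),
                                         stats::rnorm(n, 56.7, 10.4)))), 1),
    education = round(pmin(22, pmax(0, ifelse(ci, stats::rnorm(n, 5.5, 2.5),
                                              stats::rnorm(n, 9, 3))))),
    duration = round(pmin(30, abs(stats::rnorm(n, 3, 2))), 1),
    bmi = round(pmin(40, pmax(14, stats::rnorm(n, 22.4, 2.4))), 1),
    moca = round(moca, 1),
    updrs3 = round(planted_scale(38, 13, 0, 132), 1),
    nmss = round(planted_scale(50, 30, 0, 360), 1),
    pdq39 = round(planted_scale(42, 21, 0, 156), 1),
    hama = round(planted_scale(10, 6, 0, 56), 1),
    hamd = round(planted_scale(9, 6, 0, 76), 1),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full cohort
#'
#' Generates the atlas mask, per-subject BOLD volumes (CI subjects carry
#' per-subject severities drawn uniformly in \[0.7, 1\]) and the clinical
#' table. With `out_dir` set, volumes and mask are written as NIfTI-1 and the
#' clinical table as CSV; otherwise volumes are kept in memory.
#'
#' @param spec A [cohort_spec()].
#' @param blob_radius Hippocampus blob radius in voxels.
#' @param out_dir Optional output directory.
#' @param keep_bold Keep the BOLD objects in the returned list (default TRUE
#'   when `out_dir` is NULL).
#' @return List with `spec`, `mask`, `clinical`, `groups`, `severity`, and
#'   (optionally) `bold` (a list) or `paths`.
#' @export
simulate_cohort <- function(spec, blob_radius = 2, out_dir = NULL,
                            keep_bold = is.null(out_dir)) {
  mask <- generate_atlas_mask(spec$grid_shape, blob_radius)
  groups <- c(rep("CI", spec$n_ci), rep("CP", spec$n_cp))
  set.seed(child_seed(spec$seed, 0L))
  severity <- ifelse(groups == "CI", stats::runif(length(groups), 0.7, 1), 0)
  clinical <- generate_clinical(spec, groups, severity = severity)
  out <- list(spec = spec, mask = mask, clinical = clinical, groups = groups,
              severity = severity)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_nifti_vol(mask, file.path(out_dir, "hippocampus_mask.nii.gz"),
                    spec$voxel_mm)
    utils::write.csv(clinical, file.path(out_dir, "clinical.csv"),
                     row.names = FALSE)
    paths <- character(length(groups))
    for (i in seq_along(groups)) {
      b <- generate_bold(spec, mask, groups[i], i, severity[i])
      paths[i] <- file.path(out_dir, sprintf("%s_bold.nii.gz",
                                             clinical$subject_id[i]))
      write_nifti_vol(b$data, paths[i], spec$voxel_mm, tr = spec$tr_seconds)
    }
    out$paths <- paths
  }
  if (keep_bold) {
    out$bold <- lapply(seq_along(groups), function(i)
      generate_bold(spec, mask, groups[i], i, severity[i]))
  }
  out
}
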
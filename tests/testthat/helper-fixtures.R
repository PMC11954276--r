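# Small builders shared across test files. Oracles (independent
# re-implementations) live in the test files that use them.

tiny_spec <- function(..., seed = 7L) {
  cohort_spec(n_ci = 2L, n_cp = 2L, grid_shape = c(12L, 12L, 12L),
              n_timepoints = 64L, seed = seed, ...)
}

# A deterministic random 4D bold object on a small grid.
random_bold <- function(dims = c(8L, 8L, 6L), n_t = 64L, seed = 1L, tr = 2) {
  set.seed(seed)
  bold4d(array(rnorm(prod(dims) * n_t), dim = c(dims, n_t)), tr_seconds = tr)
}

# An irregular small ROI inside a grid, for texture-family tests.
random_roi_levels <- function(dims = c(5L, 5L, 5L), n_levels = 4L,
                              keep = 0.7, seed = 3L) {
  set.seed(seed)
  mask <- array(runif(prod(dims)) < keep, dim = dims)
  if (sum(mask) < 2L) mask[1:2] <- TRUE
  geom <- roi_geometry(mask)
  levels <- sample.int(n_levels, sum(mask), replace = TRUE)
  list(mask = mask, geom = geom,
       d = list(levels = levels, n_levels = n_levels))
}

# Volume of discrete levels -> ROI-ordered level vector for a geometry.
levels_from_volume <- function(vol, geom) vol[geom$idx]
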
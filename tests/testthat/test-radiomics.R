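test_that("discretisation bins equal-width over the ROI range", {
  d <- discretize(c(0, 1, 2, 3), 4)
  expect_identical(d$levels, 1:4)
  expect_warning(dc <- discretize(rep(2, 10), 4), "constant")
  expect_identical(dc$levels, rep(1L, 10))

  set.seed(41)
  v <- runif(1000)
  d32 <- discretize(v, 32)
  # independent histogram oracle with identical edge conventions
  edges <- seq(min(v), max(v), length.out = 33)
  oracle <- pmin(findInterval(v, edges, rightmost.closed = FALSE), 32L)
  expect_identical(tabulate(d32$levels, 32), tabulate(oracle, 32))
})

test_that("first-order features match order-statistics oracles", {
  f <- suppressWarnings(firstorder_features(c(2, 2, 2), voxel_volume = 2))
  expect_equal(unname(f["firstorder_Variance"]), 0)
  expect_equal(unname(f["firstorder_Range"]), 0)
  expect_equal(unname(f["firstorder_Mean"]), 2)
  expect_equal(unname(f["firstorder_Energy"]), 12)
  expect_equal(unname(f["firstorder_TotalEnergy"]), 24)
  expect_identical(length(f), 18L)
  expect_false(anyDuplicated(names(f)) > 0)

  v <- 1:10
  f <- firstorder_features(v, 27)
  # sorting-based linear-interpolation oracle: p-th percentile at rank
  # 1 + p (n - 1)
  pct <- function(p) {
    h <- 1 + p * (length(v) - 1)
    lo <- floor(h); hi <- ceiling(h)
    sort(v)[lo] + (h - lo) * (sort(v)[hi] - sort(v)[lo])
  }
  expect_equal(unname(f["firstorder_10Percentile"]), pct(0.1))
  expect_equal(unname(f["firstorder_Median"]), pct(0.5))
  expect_equal(unname(f["firstorder_InterquartileRange"]),
               pct(0.75) - pct(0.25))
  expect_equal(unname(f["firstorder_RootMeanSquared"]), sqrt(mean(v^2)))
})

test_that("GLCM counts match exhaustive pair enumeration", {
  # printed 3x3 toy embedded as a single slice
  lv2d <- rbind(c(1, 1, 2), c(2, 2, 3), c(3, 3, 3))
  vol <- array(0L, dim = c(3, 3, 1))
  vol[, , 1] <- lv2d
  mask <- array(TRUE, dim = c(3, 3, 1))
  geom <- roi_geometry(mask)
  P <- hipporad:::glcm_matrix(vol[geom$idx], geom, 3L)

  # oracle: enumerate ordered pairs for all 13 offsets over the slice
  offs <- geom$dir13
  cnt <- matrix(0, 3, 3)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    for (x in 1:3) for (y in 1:3) {
      nx <- x + o[1]; ny <- y + o[2]; nz <- 1 + o[3]
      if (nx >= 1 && nx <= 3 && ny >= 1 && ny <= 3 && nz == 1) {
        a <- vol[x, y, 1]; b <- vol[nx, ny, 1]
        cnt[a, b] <- cnt[a, b] + 1
        cnt[b, a] <- cnt[b, a] + 1
      }
    }
  }
  expect_equal(unname(P), unname(cnt))

  # offset (1,0,0) alone, classic co-occurrence counts
  pairs_x <- table(factor(lv2d[1:2, ], levels = 1:3),
                   factor(lv2d[2:3, ], levels = 1:3))
  expect_equal(sum(pairs_x), 6)  # sanity on the slice orientation

  feats <- glcm_features(list(levels = vol[geom$idx], n_levels = 3L), geom)
  expect_identical(length(feats), 22L)
  expect_true(sum(P) > 0 && abs(sum(P / sum(P)) - 1) < 1e-9)
})

test_that("GLCM degenerate conventions hold", {
  mask <- array(TRUE, dim = c(3, 3, 1))
  geom <- roi_geometry(mask)
  f <- glcm_features(list(levels = rep(1L, 9), n_levels = 1L), geom)
  expect_equal(unname(f["glcm_Correlation"]), 1)
  expect_equal(unname(f["glcm_Idmn"]), 1)

  lone <- array(FALSE, dim = c(3, 3, 3)); lone[2, 2, 2] <- TRUE
  g1 <- roi_geometry(lone)
  expect_warning(f0 <- glcm_features(list(levels = 1L, n_levels = 2L), g1),
                 "no in-ROI")
  expect_true(all(f0 == 0))
})

test_that("GLRLM runs match a brute-force maximal-run scanner", {
  # all one level along a 4x1x1 ROI: single run of length 4 per x direction
  mask <- array(FALSE, dim = c(4, 3, 3)); mask[, 2, 2] <- TRUE
  geom <- roi_geometry(mask)
  P <- hipporad:::glrlm_matrix(rep(2L, 4), geom, 3L)
  expect_equal(P[2, 4], 1)          # the x-direction run
  expect_equal(sum(P[2, 1] ), 12 * 4)  # all other 12 directions: runs of 1

  # alternating levels along x: four runs of length 1 in the x direction
  P2 <- hipporad:::glrlm_matrix(c(1L, 2L, 1L, 2L), geom, 3L)
  expect_equal(sum(P2[, 1]), 13 * 4)
  expect_true(all(P2[, -1] == 0))

  # random ROI vs independent scanner oracle
  rr <- random_roi_levels(c(5L, 5L, 5L), 3L, seed = 44L)
  P3 <- hipporad:::glrlm_matrix(rr$d$levels, rr$geom, 3L)
  lookup <- rr$geom$lookup; dims <- dim(rr$mask)
  lv_at <- function(x, y, z) {
    if (x < 1 || y < 1 || z < 1 || x > dims[1] || y > dims[2] || z > dims[3])
      return(NA_integer_)
    i <- lookup[x, y, z]
    if (i == 0) NA_integer_ else rr$d$levels[i]
  }
  oracle <- matrix(0, 3, max(dims))
  for (k in seq_len(nrow(rr$geom$dir13))) {
    o <- rr$geom$dir13[k, ]
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      lv <- lv_at(x, y, z)
      if (is.na(lv)) next
      prev <- lv_at(x - o[1], y - o[2], z - o[3])
      if (!is.na(prev) && prev == lv) next
      len <- 0; cx <- x; cy <- y; cz <- z
      while (!is.na(lv_at(cx, cy, cz)) && lv_at(cx, cy, cz) == lv) {
        len <- len + 1; cx <- cx + o[1]; cy <- cy + o[2]; cz <- cz + o[3]
      }
      oracle[lv, len] <- oracle[lv, len] + 1
    }
  }
  expect_equal(unname(P3), unname(oracle[, seq_len(ncol(P3)), drop = FALSE]))
  f <- glrlm_features(rr$d, rr$geom)
  expect_identical(length(f), 16L)
})

test_that("GLSZM zones match an independent flood-fill oracle", {
  # uniform ROI: one zone covering everything
  mask <- array(TRUE, dim = c(3, 3, 2))
  geom <- roi_geometry(mask)
  z <- hipporad:::glszm_zones(rep(1L, 18), geom)
  expect_identical(nrow(z), 1L)
  expect_identical(unname(z[1, "size"]), 18L)

  # two level-1 blobs separated by level-2: two zones of level 1
  mask <- array(TRUE, dim = c(7, 3, 3))
  geom <- roi_geometry(mask)
  vol <- array(2L, dim = c(7, 3, 3))
  vol[1:2, , ] <- 1L
  vol[6:7, , ] <- 1L
  z <- hipporad:::glszm_zones(vol[geom$idx], geom)
  expect_identical(sum(z[, "level"] == 1L), 2L)

  # random ROI vs recursive flood-fill oracle
  rr <- random_roi_levels(c(5L, 5L, 5L), 3L, seed = 45L)
  z <- hipporad:::glszm_zones(rr$d$levels, rr$geom)
  lab <- integer(length(rr$d$levels))
  nextlab <- 0L
  for (s in seq_along(lab)) {
    if (lab[s] > 0L) next
    nextlab <- nextlab + 1L
    queue <- s; lab[s] <- nextlab
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- rr$geom$neigh_mat[v, ]
      nb <- nb[nb > 0]
      nb <- nb[lab[nb] == 0L & rr$d$levels[nb] == rr$d$levels[v]]
      lab[nb] <- nextlab
      queue <- c(queue, nb)
    }
  }
  oz <- table(lab)
  osz <- sort(as.integer(oz))
  expect_identical(sort(as.integer(z[, "size"])), osz)
  expect_identical(nrow(z), length(oz))
  f <- glszm_features(rr$d, rr$geom)
  expect_identical(length(f), 16L)
})

test_that("NGTDM s_i matches the neighbourhood-average oracle", {
  mask <- array(TRUE, dim = c(3, 3, 1))
  geom <- roi_geometry(mask)
  lv2d <- rbind(c(1, 2, 1), c(3, 1, 2), c(1, 3, 3))
  vol <- array(0L, dim = c(3, 3, 1)); vol[, , 1] <- lv2d
  lv <- vol[geom$idx]
  f <- ngtdm_features(list(levels = lv, n_levels = 3L), geom)
  expect_identical(length(f), 5L)

  # oracle s_i by explicit neighbourhood means
  s <- numeric(3)
  for (x in 1:3) for (y in 1:3) {
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      nx <- x + dx; ny <- y + dy
      if (nx >= 1 && nx <= 3 && ny >= 1 && ny <= 3)
        nb <- c(nb, lv2d[nx, ny])
    }
    i <- lv2d[x, y]
    s[i] <- s[i] + abs(i - mean(nb))
  }
  # reconstruct coarseness from the oracle s and p
  n_i <- tabulate(lv, 3); p <- n_i / 9
  expect_equal(unname(f["ngtdm_Coarseness"]), 1 / sum(p * s),
               tolerance = 1e-12)

  # uniform ROI: sentinel coarseness
  fu <- ngtdm_features(list(levels = rep(2L, 9), n_levels = 3L), geom)
  expect_equal(unname(fu["ngtdm_Coarseness"]), 1e6)
})

test_that("GLDM dependence counts match brute force", {
  mask <- array(TRUE, dim = c(3, 3, 3))
  geom <- roi_geometry(mask)
  lv <- rep(1L, 27)
  f <- gldm_features(list(levels = lv, n_levels = 2L), geom)
  expect_identical(length(f), 14L)
  # uniform 3x3x3: the centre voxel has dependence 26 -> j = 27 occurs once
  dep <- sapply(seq_len(27), function(v) {
    nb <- geom$neigh_mat[v, ]; nb <- nb[nb > 0]
    sum(lv[nb] == lv[v])
  })
  expect_identical(sum(dep == 26L), 1L)

  # isolated differing voxel has dependence 0
  lv2 <- rep(1L, 27); lv2[14] <- 2L  # the centre in column-major order
  dep2 <- sapply(seq_len(27), function(v) {
    nb <- geom$neigh_mat[v, ]; nb <- nb[nb > 0]
    sum(lv2[nb] == lv2[v])
  })
  expect_identical(dep2[14], 0L)

  rr <- random_roi_levels(c(5L, 5L, 5L), 3L, seed = 46L)
  f3 <- gldm_features(rr$d, rr$geom, alpha = 0)
  # brute-force dependence histogram reconstruction of DependenceEntropy
  depo <- sapply(seq_along(rr$d$levels), function(v) {
    nb <- rr$geom$neigh_mat[v, ]; nb <- nb[nb > 0]
    sum(abs(rr$d$levels[nb] - rr$d$levels[v]) <= 0)
  })
  P <- table(factor(rr$d$levels, 1:3), factor(depo, 0:max(depo)))
  p <- as.numeric(P / sum(P)); p <- p[p > 0]
  expect_equal(unname(f3["gldm_DependenceEntropy"]), -sum(p * log2(p)),
               tolerance = 1e-12)
})

test_that("the full extraction yields exactly 819 well-named features", {
  set.seed(47)
  vol <- array(rnorm(16 * 16 * 12), dim = c(16, 16, 12))
  mask <- generate_atlas_mask(c(16L, 16L, 12L), 2) > 0
  fv <- extract_all(vol, mask)
  expect_identical(length(fv), 819L)
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_identical(sum(!grepl("^wavelet-", names(fv))), 91L)
  expect_identical(sum(grepl("^wavelet-", names(fv))), 728L)
  expect_true("wavelet-LLL_firstorder_10Percentile" %in% names(fv))
  expect_true("wavelet-HHL_glcm_Idmn" %in% names(fv))
  expect_identical(sum(grepl("_firstorder_", paste0("_", names(fv)))), 162L)
  expect_true(all(is.finite(fv)))
})

test_that("texture features are invariant to intensity shifts", {
  rr <- random_roi_levels(c(6L, 6L, 6L), 1L, seed = 48L)
  set.seed(48)
  vol <- array(rnorm(216), dim = c(6, 6, 6))
  f1 <- extract_all(vol, rr$mask, n_bins = 8, geom = rr$geom)
  f2 <- extract_all(vol + 100, rr$mask, n_bins = 8, geom = rr$geom)
  tex <- grepl("glcm|glrlm|glszm|ngtdm|gldm", names(f1)) &
    !grepl("^wavelet", names(f1))
  expect_equal(f1[tex], f2[tex], tolerance = 1e-8)
})
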
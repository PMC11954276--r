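#' Min-max normalise features to \[0, 1\] on training statistics
#'
#' Each feature is linearly stretched to \[0, 1\] using the training-cohort
#' minimum and maximum; validation rows are transformed with the same
#' parameters and clipped to \[0, 1\]. Features constant on the training
#' cohort are dropped with a warning. Z-scoring (training mean/sd) is
#' available as an alternative.
#'
#' @param train Numeric matrix or data.frame (subjects x features).
#' @param validation Optional matrix with the same columns.
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return List with `train`, `validation` (or NULL), and `stats`.
#' @export
normalize_features <- function(train, validation = NULL,
                               method = c("minmax", "zscore")) {
  method <- match.arg(method)
  train <- as.matrix(train)
  lo <- apply(train, 2L, min); hi <- apply(train, 2L, max)
  const <- if (method == "minmax") hi == lo else apply(train, 2L, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) dropped: ",
            paste(utils::head(colnames(train)[const], 3L), collapse = ", "))
    train <- train[, !const, drop = FALSE]
    lo <- lo[!const]; hi <- hi[!const]
    if (!is.null(validation))
      validation <- as.matrix(validation)[, !const, drop = FALSE]
  } else if (!is.null(validation)) {
    validation <- as.matrix(validation)[, colnames(train), drop = FALSE]
  }
  tr <- if (method == "minmax") {
    sweep(sweep(train, 2L, lo), 2L, hi - lo, "/")
  } else {
    mu <- colMeans(train); sdv <- apply(train, 2L, stats::sd)
    sweep(sweep(train, 2L, mu), 2L, sdv, "/")
  }
  va <- NULL
  if (!is.null(validation)) {
    va <- if (method == "minmax") {
      pmin(pmax(sweep(sweep(validation, 2L, lo), 2L, hi - lo, "/"), 0), 1)
    } else {
      mu <- colMeans(train); sdv <- apply(as.matrix(train), 2L, stats::sd)
      sweep(sweep(validation, 2L, mu), 2L, sdv, "/")
    }
  }
  list(train = tr, validation = va,
       stats = list(method = method, lo = lo, hi = hi))
}

#' Greedy Spearman redundancy pruning
#'
#' Computes all pairwise absolute Spearman correlations, then repeatedly
#' takes the currently worst offending pair (|rho| > threshold) and drops
#' the member with the larger mean |rho| to all currently retained features
#' (ties broken by dropping the lexicographically later name). The result
#' contains no pair with |rho| above the threshold and is deterministic and
#' column-order independent.
#'
#' @param table Numeric matrix (subjects x named features), >= 3 rows.
#' @param threshold Absolute Spearman correlation cut-off (default 0.9).
#' @return Character vector of retained feature names (original order).
#' @export
spearman_prune <- function(table, threshold = 0.9) {
  x <- as.matrix(table)
  if (nrow(x) < 3L) stop("need at least 3 subjects")
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("V", seq_len(ncol(x)))
  A <- abs(stats::cor(x, method = "spearman"))
  A[!is.finite(A)] <- 1          # constant features: fully redundant
  diag(A) <- 0
  p <- ncol(A)
  active <- rep(TRUE, p)
  rs <- rowSums(A)               # sum |rho| to active features
  rmax <- apply(A, 1L, max)      # row maxima over active columns
  repeat {
    mx <- max(rmax)
    if (mx <= threshold) break
    # canonical worst pair: among all pairs attaining mx, the one whose
    # sorted name pair is smallest (keeps the result order-independent)
    rows <- which(rmax == mx)
    cand <- do.call(rbind, lapply(rows, function(r) {
      cols <- which(A[r, ] == mx)
      cbind(r, cols)
    }))
    key <- apply(cand, 1L, function(w)
      paste(sort(c(nms[w[1L]], nms[w[2L]])), collapse = "\r"))
    w <- cand[order(key)[1L], ]
    i <- w[1L]; j <- w[2L]
    na <- sum(active)
    mi <- rs[i] / na; mj <- rs[j] / na
    drop_j <- if (mi != mj) mj > mi else nms[j] > nms[i]
    victim <- if (drop_j) j else i
    active[victim] <- FALSE
    col_v <- A[, victim]
    rs <- rs - col_v
    A[victim, ] <- 0; A[, victim] <- 0
    rmax[victim] <- 0
    # rows whose maximum ran through the victim must be rescanned
    stale <- which(active & col_v >= rmax & rmax > 0)
    for (r in stale) rmax[r] <- max(A[r, ])
  }
  nms[active]
}

#' LASSO with cross-validated penalty selection
#'
#' L1-penalised least squares on the binary label treated as a continuous
#' response, minimising `(1/2n) RSS + lambda ||beta||_1` over a 100-point
#' log-spaced grid from `lambda_max = max_j |X_j' (y - ybar)| / n` down to
#' `1e-3 lambda_max`. Lambda is chosen to minimise the mean cross-validated
#' squared error over label-stratified folds, and the final model is refit
#' on the full training data at that lambda.
#'
#' @param X Normalised numeric matrix (subjects x features).
#' @param y Binary labels (0/1).
#' @param n_folds Number of CV folds (default 10).
#' @param lambda_grid Optional penalty grid (descending).
#' @param seed Seed for the fold assignment.
#' @return A `selection_result` list: `retained`, `selected`, `weights`,
#'   `intercept`, `lambda_selected`, `cv_curve`.
#' @export
lasso_cv <- function(X, y, n_folds = 10L, lambda_grid = NULL, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("need both classes in y")
  n <- nrow(X)
  if (n < n_folds) stop("fewer rows than folds")
  if (is.null(lambda_grid)) {
    lmax <- max(abs(crossprod(X, y - mean(y)))) / n
    lambda_grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 100L))
  }
  set.seed(as.integer(seed))
  foldid <- integer(n)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  cv <- glmnet::cv.glmnet(X, y, family = "gaussian", lambda = lambda_grid,
                          foldid = foldid, standardize = FALSE,
                          type.measure = "mse")
  lam <- cv$lambda.min          # lies on the supplied grid: no interpolation
  co <- as.numeric(stats::coef(cv$glmnet.fit, s = lam))
  weights <- co[-1L]
  names(weights) <- colnames(X)
  structure(list(
    retained = colnames(X),
    selected = colnames(X)[weights != 0],
    weights = weights[weights != 0],
    intercept = co[1L],
    lambda_selected = lam,
    cv_curve = data.frame(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd)
  ), class = "selection_result")
}

#' Full feature-selection stage on a training cohort
#'
#' Normalisation (training statistics), Spearman pruning, then LASSO; the
#' whole stage sees only the training rows, and the returned transform is
#' applied unchanged to validation data.
#'
#' @param X_train,X_val Feature matrices (validation may be NULL).
#' @param y_train Binary training labels.
#' @param prune_threshold Spearman cut-off.
#' @param n_folds LASSO CV folds.
#' @param seed Seed for fold assignment.
#' @return List with the normalised matrices restricted to retained
#'   features, and the `selection_result`.
#' @export
select_features <- function(X_train, y_train, X_val = NULL,
                            prune_threshold = 0.9, n_folds = 10L,
                            seed = 1L) {
  nrm <- normalize_features(X_train, X_val)
  kept <- spearman_prune(nrm$train, prune_threshold)
  tr <- nrm$train[, kept, drop = FALSE]
  va <- if (!is.null(nrm$validation)) nrm$validation[, kept, drop = FALSE]
  sel <- lasso_cv(tr, y_train, n_folds = n_folds, seed = seed)
  list(train = tr, validation = va, result = sel, normalization = nrm$stats)
}
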
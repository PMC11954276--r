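#' Stratified train/validation split
#'
#' The total training size is `round(ratio * n)`; it is allocated across
#' classes by largest remainder so that class proportions carry over to
#' within one subject. Both sides must contain both classes.
#'
#' @param labels Vector of class labels (e.g. "CI"/"CP" or 0/1).
#' @param ratio Training fraction (default 0.7).
#' @param seed Seed for the within-class sampling.
#' @return List with integer index vectors `train` and `validation`.
#' @export
split_cohort <- function(labels, ratio = 0.7, seed = 1L) {
  n <- length(labels)
  classes <- sort(unique(labels))
  if (any(table(labels) < 2L)) stop("need at least 2 subjects per class")
  n_train <- round(ratio * n)
  target <- ratio * as.numeric(table(labels)[as.character(classes)])
  base <- floor(target)
  rem <- n_train - sum(base)
  if (rem > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  set.seed(as.integer(seed))
  train <- integer(0)
  for (k in seq_along(classes)) {
    idx <- which(labels == classes[k])
    train <- c(train, sample(idx, base[k]))
  }
  train <- sort(train)
  validation <- setdiff(seq_len(n), train)
  if (length(unique(labels[train])) < length(classes) ||
      length(unique(labels[validation])) < length(classes))
    stop("a class is absent from one side of the split")
  list(train = train, validation = validation)
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Augments the minority class to the majority size: each synthetic point is
#' `x_i + u (x_neighbor - x_i)` with `u ~ U(0, 1)` and the neighbour drawn
#' among the k nearest minority points (k capped at minority size - 1).
#' Already balanced input is returned unchanged.
#'
#' @param X Numeric matrix (subjects x features).
#' @param y Binary labels.
#' @param k Number of nearest neighbours (default 5).
#' @param seed Seed for the interpolation draws.
#' @return List with augmented `X` and `y`.
#' @export
smote <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  tab <- table(y)
  if (length(tab) != 2L) stop("need exactly 2 classes")
  if (tab[1L] == tab[2L]) return(list(X = X, y = y))
  min_cl <- names(tab)[which.min(tab)]
  idx_min <- which(y == min_cl)
  n_min <- length(idx_min)
  if (n_min < 2L) stop("minority class has fewer than 2 points")
  n_syn <- max(tab) - n_min
  k <- min(k, n_min - 1L)
  Xm <- X[idx_min, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn <- matrix(0L, n_min, k)
  for (i in seq_len(n_min)) nn[i, ] <- order(D[i, ])[seq_len(k)]
  set.seed(as.integer(seed))
  base <- rep_len(seq_len(n_min), n_syn)
  pick <- nn[cbind(base, sample.int(k, n_syn, replace = TRUE))]
  u <- stats::runif(n_syn)
  syn <- Xm[base, , drop = FALSE] +
    u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  list(X = rbind(X, syn),
       y = c(y, rep(y[idx_min[1L]], n_syn)))
}

#' Radiomics score of one subject
#'
#' Linear combination of the selected features weighted by their LASSO
#' coefficients, plus the intercept.
#'
#' @param x Named numeric vector (or single-row matrix) of feature values.
#' @param model List with `weights` (named), `intercept`.
#' @return The rad-score (numeric scalar).
#' @export
radscore <- function(x, model) {
  x <- if (is.matrix(x)) x[1L, ] else x
  missing <- setdiff(names(model$weights), names(x))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  model$intercept + sum(model$weights * x[names(model$weights)])
}

radscore_matrix <- function(X, model) {
  missing <- setdiff(names(model$weights), colnames(X))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  drop(X[, names(model$weights), drop = FALSE] %*% model$weights) +
    model$intercept
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney U statistic divided by `n1 * n0`, with ties
#' counted one half. ROC points are generated from every distinct score
#' taken as a threshold under the rule score > threshold => positive.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (1/positive class first by value).
#' @return List with `points` (data.frame fpr/tpr/threshold, increasing
#'   fpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary(labels)
  if (length(unique(y)) < 2L) stop("need both classes")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(scores)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(-Inf, sort(unique(scores)))
  pts <- t(vapply(thr, function(t0) {
    pos <- scores > t0
    c(fpr = sum(pos & y == 0L) / n0, tpr = sum(pos & y == 1L) / n1)
  }, numeric(2L)))
  pts <- data.frame(fpr = pts[, 1L], tpr = pts[, 2L], threshold = thr)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  list(points = pts, auc = auc)
}

as_binary <- function(labels) {
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.integer(labels))
  if (all(labels %in% c("CI", "CP"))) return(as.integer(labels == "CI"))
  f <- as.factor(labels)
  if (nlevels(f) != 2L) stop("labels must be binary")
  as.integer(f == levels(f)[2L])
}

#' Youden-optimal threshold
#'
#' Maximises J = sensitivity + specificity - 1 over the ROC thresholds;
#' ties prefer higher sensitivity, then the lower threshold value.
#'
#' @param roc Output of [roc_auc()] (or its `points` data.frame).
#' @return Threshold (numeric scalar).
#' @export
youden_threshold <- function(roc) {
  pts <- if (is.data.frame(roc)) roc else roc$points
  pts <- pts[is.finite(pts$threshold), , drop = FALSE]
  if (nrow(pts) == 0L) stop("empty ROC")
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  best <- best[order(-pts$tpr[best], pts$threshold[best])][1L]
  pts$threshold[best]
}

wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(0, 1))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Threshold-based classification metrics
#'
#' Applies the rule score > threshold => positive (CI), builds the 2x2
#' confusion table, and reports accuracy, sensitivity and specificity with
#' Wilson 95% intervals plus the AUC with its DeLong interval.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param threshold Decision threshold.
#' @return List with `confusion`, `acc`, `sen`, `spe` (each with `_ci`),
#'   `auc`, `auc_ci`, `roc`.
#' @export
evaluate_scores <- function(scores, labels, threshold) {
  y <- as_binary(labels)
  pos <- scores > threshold
  tp <- sum(pos & y == 1L); fn <- sum(!pos & y == 1L)
  tn <- sum(!pos & y == 0L); fp <- sum(pos & y == 0L)
  roc <- roc_auc(scores, labels)
  dl <- delong_variance(scores, y)
  se <- sqrt(dl$var)
  list(confusion = matrix(c(tp, fn, fp, tn), 2L, 2L,
                          dimnames = list(pred = c("pos", "neg"),
                                          truth = c("pos", "neg"))),
       acc = (tp + tn) / length(y), acc_ci = wilson_ci(tp + tn, length(y)),
       sen = tp / (tp + fn), sen_ci = wilson_ci(tp, tp + fn),
       spe = tn / (tn + fp), spe_ci = wilson_ci(tn, tn + fp),
       auc = roc$auc,
       auc_ci = c(max(0, roc$auc - stats::qnorm(0.975) * se),
                  min(1, roc$auc + stats::qnorm(0.975) * se)),
       threshold = threshold, roc = roc$points)
}

#' Ridge-stabilised logistic regression
#'
#' Maximum-likelihood fit by iteratively reweighted least squares with a
#' small L2 penalty (default 1e-4) on the non-intercept coefficients, which
#' keeps the fit defined on separable data.
#'
#' @param X Numeric matrix (subjects x features).
#' @param y Binary labels.
#' @param ridge L2 penalty.
#' @param max_iter,tol IRLS controls.
#' @return List with `weights` (named), `intercept`.
#' @export
fit_logistic <- function(X, y, ridge = 1e-4, max_iter = 100L, tol = 1e-9) {
  X <- as.matrix(X)
  y <- as_binary(y)
  if (length(unique(y)) < 2L) stop("need both classes")
  if (any(apply(X, 2L, stats::sd) == 0)) stop("constant column in X")
  Xa <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xa)
  pen <- diag(c(0, rep(ridge, p - 1L)))
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(Xa, y - mu)) - drop(pen %*% beta)
    W <- mu * (1 - mu)
    H <- crossprod(Xa * W, Xa) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (sqrt(sum(grad^2)) < tol && sqrt(sum(step^2)) < tol) break
  }
  eta <- drop(Xa %*% beta)
  mu <- 1 / (1 + exp(-eta))
  grad <- drop(crossprod(Xa, y - mu)) - drop(pen %*% beta)
  if (sqrt(sum(grad^2)) > 1e-6)
    stop("logistic fit did not converge; gradient norm ",
         format(sqrt(sum(grad^2))))
  list(weights = stats::setNames(beta[-1L], colnames(X)),
       intercept = beta[1L])
}

#' Predicted probabilities from a logistic model
#' @param model Output of [fit_logistic()].
#' @param X Feature matrix with the model's columns.
#' @return Numeric vector of probabilities.
#' @export
predict_logistic <- function(model, X) {
  eta <- drop(as.matrix(X)[, names(model$weights), drop = FALSE] %*%
                model$weights) + model$intercept
  1 / (1 + exp(-eta))
}

# Placement values (structural components) for one marker.
delong_components <- function(scores, y) {
  sx <- scores[y == 1L]; sy <- scores[y == 0L]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(sx, function(a) mean(psi(a, sy)), numeric(1L))
  v01 <- vapply(sy, function(b) mean(psi(sx, b)), numeric(1L))
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

delong_variance <- function(scores, y) {
  cmp <- delong_components(scores, y)
  m <- length(cmp$v10); n <- length(cmp$v01)
  var <- stats::var(cmp$v10) / m + stats::var(cmp$v01) / n
  list(auc = cmp$auc, var = var)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two markers scored on the same subjects using the
#' placement-value (structural components) variance of the AUC difference
#' and a two-sided normal reference. Degenerate variance (e.g. identical
#' score vectors) returns p = 1 with a warning.
#'
#' @param scoresA,scoresB Paired score vectors.
#' @param labels Binary labels shared by both.
#' @return List with `aucA`, `aucB`, `z`, `p`.
#' @export
delong_test <- function(scoresA, scoresB, labels) {
  y <- as_binary(labels)
  if (length(unique(y)) < 2L) stop("need both classes")
  ca <- delong_components(scoresA, y)
  cb <- delong_components(scoresB, y)
  m <- length(ca$v10); n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1L, 1L] + s10[2L, 2L] - 2 * s10[1L, 2L]) / m +
              (s01[1L, 1L] + s01[2L, 2L] - 2 * s01[1L, 2L]) / n
  if (var_diff <= 0) {
    warning("degenerate variance in DeLong test; p = 1")
    return(list(aucA = ca$auc, aucB = cb$auc, z = 0, p = 1))
  }
  z <- (ca$auc - cb$auc) / sqrt(var_diff)
  list(aucA = ca$auc, aucB = cb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Decision curve analysis
#'
#' Net benefit of the classifier at each threshold probability `pt`:
#' `NB = TP/n - (FP/n) pt / (1 - pt)` where predictions are positive when
#' the predicted probability is at least `pt`. Treat-all and treat-none
#' reference curves are included.
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary labels.
#' @param thresholds Threshold probabilities (default 0.01..0.99).
#' @return data.frame with `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  y <- as_binary(labels)
  n <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    pos <- probabilities >= pt
    tp <- sum(pos & y == 1L); fp <- sum(pos & y == 0L)
    tp / n - (fp / n) * pt / (1 - pt)
  }, numeric(1L))
  data.frame(threshold = thresholds, net_benefit = nb,
             treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
             treat_none = 0)
}

#' Exact SHAP attributions for a linear (log-odds) model
#'
#' Under feature independence, the Shapley value of feature j for subject i
#' in a linear model is `w_j (x_ij - mean_background_j)`; the base value is
#' the model output at the background means. Local accuracy holds exactly:
#' base + rowSums(shap) equals the subject's log-odds.
#'
#' @param model List with `weights` (named) and `intercept`.
#' @param X Feature matrix (subjects x features).
#' @param background_means Named means of the background data; defaults to
#'   the column means of `X`.
#' @return List with `shap` (matrix), `base`.
#' @export
linear_shap <- function(model, X, background_means = NULL) {
  X <- as.matrix(X)[, names(model$weights), drop = FALSE]
  if (is.null(background_means)) background_means <- colMeans(X)
  background_means <- background_means[colnames(X)]
  phi <- sweep(X, 2L, background_means) %*% diag(model$weights,
                                                 ncol = ncol(X))
  colnames(phi) <- colnames(X)
  base <- model$intercept + sum(model$weights * background_means)
  list(shap = phi, base = base)
}

#' Fit and evaluate one metric combination
#'
#' Runs the complete modelling chain on a training/validation split:
#' normalisation and feature selection (training rows only), rad-score with
#' Youden threshold from the training ROC, SMOTE-balanced ridge-logistic
#' model on the selected features, and threshold metrics on both cohorts.
#'
#' @param X_train,X_val Feature matrices.
#' @param y_train,y_val Labels.
#' @param prune_threshold,n_folds,seed Selection controls.
#' @param smote_k SMOTE neighbour count.
#' @return List with `selection`, `radscore` (model + train/val reports)
#'   and `logistic` (model + train/val reports + shap).
#' @export
evaluate_combination <- function(X_train, y_train, X_val, y_val,
                                 prune_threshold = 0.9, n_folds = 10L,
                                 seed = 1L, smote_k = 5L) {
  sel <- select_features(X_train, as_binary(y_train), X_val,
                         prune_threshold = prune_threshold,
                         n_folds = n_folds, seed = seed)
  res <- sel$result
  if (length(res$selected) == 0L)
    warning("LASSO kept no features; models degrade to the intercept ",
            "(constant score, AUC 0.5)")
  rs_model <- list(weights = res$weights, intercept = res$intercept)
  rs_train <- radscore_matrix(sel$train, rs_model)
  rs_val <- radscore_matrix(sel$validation, rs_model)
  thr <- youden_threshold(roc_auc(rs_train, y_train))
  rad <- list(model = c(rs_model, youden_threshold = thr),
              train = evaluate_scores(rs_train, y_train, thr),
              validation = evaluate_scores(rs_val, y_val, thr),
              scores_train = rs_train, scores_val = rs_val)

  Xs_train <- sel$train[, res$selected, drop = FALSE]
  Xs_val <- sel$validation[, res$selected, drop = FALSE]
  sm <- smote(Xs_train, as_binary(y_train), k = smote_k, seed = seed)
  lr_model <- if (length(res$selected)) fit_logistic(sm$X, sm$y) else
    list(weights = stats::setNames(numeric(0), character(0)),
         intercept = stats::qlogis(mean(as_binary(y_train))))
  p_train <- predict_logistic(lr_model, Xs_train)
  p_val <- predict_logistic(lr_model, Xs_val)
  lr <- list(model = lr_model,
             train = evaluate_scores(p_train, y_train, 0.5),
             validation = evaluate_scores(p_val, y_val, 0.5),
             probs_train = p_train, probs_val = p_val,
             dca = decision_curve(p_val, y_val),
             shap = linear_shap(lr_model, Xs_val,
                                background_means = colMeans(Xs_train)))
  list(selection = res, radscore = rad, logistic = lr)
}

#' Sweep all combinations of derivative metrics
#'
#' For every non-empty subset of the supplied metrics (15 subsets for four),
#' concatenates that subset's feature tables (columns prefixed
#' `<METRIC>_`), and runs [evaluate_combination()] on the shared split.
#'
#' @param tables Named list of per-metric feature matrices (same rows).
#' @param labels Subject labels.
#' @param split Output of [split_cohort()].
#' @param subsets Optional list of metric subsets; default all non-empty.
#' @param ... Passed to [evaluate_combination()].
#' @return Named list of evaluation results, names like `"ReHo+VMHC"`.
#' @export
combination_sweep <- function(tables, labels, split, subsets = NULL, ...) {
  metrics <- names(tables)
  if (is.null(subsets)) {
    subsets <- unlist(lapply(seq_along(metrics), function(k)
      utils::combn(metrics, k, simplify = FALSE)), recursive = FALSE)
  }
  out <- list()
  for (sub in subsets) {
    X <- do.call(cbind, lapply(sub, function(m) {
      x <- as.matrix(tables[[m]])
      colnames(x) <- paste0(m, "_", colnames(x))
      x
    }))
    out[[paste(sub, collapse = "+")]] <- evaluate_combination(
      X[split$train, , drop = FALSE], labels[split$train],
      X[split$validation, , drop = FALSE], labels[split$validation], ...)
  }
  out
}
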
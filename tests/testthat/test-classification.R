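test_that("cohort split follows the 7:3 rule with stratification", {
  lab10 <- rep(c("CI", "CP"), each = 5)
  sp <- split_cohort(lab10, seed = 1)
  expect_identical(length(sp$train), 7L)
  expect_identical(length(sp$validation), 3L)

  sp2 <- split_cohort(lab10, seed = 1)
  expect_identical(sp, sp2)

  lab89 <- c(rep("CI", 55), rep("CP", 34))
  sp3 <- split_cohort(lab89, seed = 2)
  expect_identical(length(sp3$train), 62L)
  expect_identical(length(sp3$validation), 27L)
  # class proportions within one subject of 55:34
  expect_lte(abs(sum(lab89[sp3$train] == "CI") - 0.7 * 55), 1)
  expect_lte(abs(sum(lab89[sp3$train] == "CP") - 0.7 * 34), 1)
  expect_identical(sort(c(sp3$train, sp3$validation)), 1:89)
})

test_that("SMOTE balances classes by convex interpolation", {
  set.seed(61)
  X <- matrix(rnorm(30), 15, 2)
  y <- c(rep(1, 5), rep(0, 10))
  out <- smote(X, y, k = 3, seed = 2)
  expect_identical(as.integer(table(out$y)), c(10L, 10L))

  # already balanced: unchanged
  Xb <- X[1:10, ]; yb <- rep(c(0, 1), each = 5)
  outb <- smote(Xb, yb, seed = 2)
  expect_identical(outb$X, Xb)

  # 1-D minority at {0, 1}: synthetic points stay inside [0, 1]
  X1 <- matrix(c(0, 1, 5, 6, 7, 8), ncol = 1)
  y1 <- c(1, 1, 0, 0, 0, 0)
  o1 <- smote(X1, y1, seed = 3)
  syn <- o1$X[-(1:6), 1]
  expect_true(all(syn >= 0 & syn <= 1))
  expect_error(smote(matrix(1:6, ncol = 1), c(1, 0, 0, 0, 0, 0)), "fewer than 2")
})

test_that("rad-score is the weighted linear combination", {
  model <- list(weights = c(a = 0.5, b = -0.25), intercept = 0.4)
  expect_equal(radscore(c(a = 1, b = 2), model), 0.4)
  expect_equal(radscore(c(a = 0, b = 0), model), 0.4)
  m2 <- model; m2$weights["a"] <- 1
  expect_equal(radscore(c(a = 1, b = 2), m2) - radscore(c(a = 1, b = 2), model),
               0.5)
  expect_error(radscore(c(a = 1), model), "missing feature.*b")
})

test_that("AUC equals exhaustive concordant-pair counting", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  # brute-force pair enumeration oracle
  pair_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(62)
  for (i in 1:10) {
    s <- round(rnorm(30), 1)         # rounding makes ties likely
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y)$auc, pair_auc(s, y), tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 1, 0, 0))$auc, 0)
  # inverted labels mirror the AUC
  s <- rnorm(20); y <- rbinom(20, 1, 0.5); y[1] <- 1; y[2] <- 0
  expect_equal(roc_auc(s, y)$auc, 1 - roc_auc(s, 1 - y)$auc)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("Youden threshold maximises J over all ROC points", {
  set.seed(63)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  roc <- roc_auc(s, y)
  thr <- youden_threshold(roc)
  j_at <- function(t0) {
    sen <- mean(s[y == 1] > t0); spe <- mean(s[y == 0] <= t0)
    sen + spe - 1
  }
  jbest <- j_at(thr)
  for (t0 in sort(unique(s))) expect_lte(j_at(t0), jbest + 1e-12)

  # perfect separation: the lower edge of the gap is returned
  thr2 <- youden_threshold(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1)))
  expect_equal(thr2, 2)
  # constant scores: J = 0 at the single threshold
  roc3 <- roc_auc(rep(1, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(max(roc3$points$tpr - roc3$points$fpr), 0)
})

test_that("threshold metrics reproduce the reported confusion arithmetic", {
  # confusion TP=9 FN=1 TN=15 FP=2 -> SEN 0.900, SPE 0.882, ACC 0.889
  scores <- c(rep(1, 9), 0, rep(0, 15), 1, 1)
  labels <- c(rep(1, 10), rep(0, 17))
  ev <- evaluate_scores(scores, labels, 0.5)
  expect_equal(ev$sen, 0.900, tolerance = 5e-4)
  expect_equal(ev$spe, 0.882, tolerance = 5e-4)
  expect_equal(ev$acc, 0.889, tolerance = 5e-4)
  expect_identical(sum(ev$confusion), 27L)

  # all correct
  ev2 <- evaluate_scores(c(0, 0, 1, 1), c(0, 0, 1, 1), 0.5)
  expect_equal(c(ev2$acc, ev2$sen, ev2$spe), c(1, 1, 1))

  # formulas match direct counting on random confusions
  set.seed(64)
  for (i in 1:100) {
    n <- 40
    y <- rbinom(n, 1, 0.5); if (length(unique(y)) < 2) next
    s <- runif(n)
    t0 <- runif(1)
    ev <- evaluate_scores(s, y, t0)
    tp <- sum(s > t0 & y == 1); fn <- sum(s <= t0 & y == 1)
    tn <- sum(s <= t0 & y == 0); fp <- sum(s > t0 & y == 0)
    expect_equal(ev$sen, tp / (tp + fn))
    expect_equal(ev$spe, tn / (tn + fp))
    expect_equal(ev$acc, (tp + tn) / n)
  }
})

test_that("ridge-logistic fit satisfies its optimality conditions", {
  set.seed(65)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  fit <- fit_logistic(X, y)
  # gradient of the penalised log-likelihood vanishes
  beta <- c(fit$intercept, fit$weights)
  Xa <- cbind(1, X)
  mu <- plogis(drop(Xa %*% beta))
  grad <- drop(crossprod(Xa, y - mu)) - c(0, 1e-4 * fit$weights)
  expect_lt(sqrt(sum(grad^2)), 1e-6)

  # permuting rows leaves the fit unchanged
  p <- sample(n)
  fit2 <- fit_logistic(X[p, ], y[p])
  expect_equal(fit$weights, fit2$weights, tolerance = 1e-8)

  # wide 1-D gap gives near 0/1 probabilities
  X1 <- matrix(c(rnorm(10, -10), rnorm(10, 10)), ncol = 1,
               dimnames = list(NULL, "x"))
  y1 <- rep(c(0, 1), each = 10)
  f1 <- fit_logistic(X1, y1)
  pr <- predict_logistic(f1, X1)
  expect_true(all(pr[1:10] < 0.01) && all(pr[11:20] > 0.99))
})

test_that("DeLong machinery agrees with Mann-Whitney and pROC", {
  set.seed(66)
  n <- 60
  y <- rep(c(1, 0), each = 30)
  sA <- y + rnorm(n)
  sB <- 0.5 * y + rnorm(n)
  dt <- delong_test(sA, sB, y)
  expect_equal(dt$aucA, roc_auc(sA, y)$auc, tolerance = 1e-12)
  expect_equal(dt$aucB, roc_auc(sB, y)$auc, tolerance = 1e-12)

  expect_warning(same <- delong_test(sA, sA, y), "degenerate")
  expect_equal(same$p, 1)

  skip_if_not_installed("pROC")
  pr <- pROC::roc.test(pROC::roc(y, sA, quiet = TRUE),
                       pROC::roc(y, sB, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(dt$p, pr$p.value, tolerance = 1e-9)
  ci <- pROC::ci.auc(pROC::roc(y, sA, quiet = TRUE), method = "delong")
  ev <- evaluate_scores(sA, y, 0)
  expect_equal(ev$auc_ci[1], as.numeric(ci)[1], tolerance = 1e-6)
  expect_equal(ev$auc_ci[2], as.numeric(ci)[3], tolerance = 1e-6)
})

test_that("net benefit matches its closed forms", {
  set.seed(67)
  y <- rbinom(50, 1, 0.4); y[1:2] <- c(0, 1)
  p <- runif(50)
  dc <- decision_curve(p, y)
  prev <- mean(y)
  expect_true(all(dc$treat_none == 0))
  expect_equal(dc$treat_all,
               prev - (1 - prev) * dc$threshold / (1 - dc$threshold))
  # a perfect classifier attains NB = prevalence at every threshold
  dcp <- decision_curve(as.numeric(y), y, thresholds = seq(0.05, 0.95, 0.05))
  expect_equal(dcp$net_benefit, rep(prev, nrow(dcp)))
})

test_that("linear SHAP is locally accurate and equals enumerated Shapley", {
  set.seed(68)
  m <- 6
  w <- rnorm(m); names(w) <- paste0("f", 1:m)
  model <- list(weights = w, intercept = 0.3)
  X <- matrix(rnorm(10 * m), 10, m, dimnames = list(NULL, names(w)))
  bg <- colMeans(X)
  sh <- linear_shap(model, X, bg)
  eta <- drop(X %*% w) + 0.3
  expect_equal(unname(rowSums(sh$shap) + sh$base), unname(eta),
               tolerance = 1e-10)

  # zero-weight feature gets a zero column
  w0 <- w; w0["f3"] <- 0
  sh0 <- linear_shap(list(weights = w0, intercept = 0), X, bg)
  expect_true(all(sh0$shap[, "f3"] == 0))

  # coalition enumeration with mean-imputation value function
  x <- X[1, ]
  vfun <- function(S) 0.3 + sum(w * ifelse(seq_len(m) %in% S, x, bg))
  phi <- numeric(m)
  subsets <- unlist(lapply(0:(m - 1), function(k)
    combn(m - 1, k, simplify = FALSE)), recursive = FALSE)
  for (j in seq_len(m)) {
    others <- setdiff(seq_len(m), j)
    for (S0 in subsets) {
      S <- others[S0]
      wgt <- factorial(length(S)) * factorial(m - length(S) - 1) / factorial(m)
      phi[j] <- phi[j] + wgt * (vfun(c(S, j)) - vfun(S))
    }
  }
  expect_equal(unname(sh$shap[1, ]), phi, tolerance = 1e-10)
})

test_that("validation data never influence training artefacts", {
  set.seed(69)
  n <- 60; p <- 40
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- rep(c("CI", "CP"), each = 30)
  X[y == "CI", 1:4] <- X[y == "CI", 1:4] + 1.5
  sp <- split_cohort(y, seed = 4)
  a <- evaluate_combination(X[sp$train, ], y[sp$train],
                            X[sp$validation, ], y[sp$validation], seed = 5)
  y_bad <- rev(y[sp$validation])
  X_bad <- X[sp$validation, ] + 100
  b <- evaluate_combination(X[sp$train, ], y[sp$train], X_bad, y_bad, seed = 5)
  expect_identical(a$selection$weights, b$selection$weights)
  expect_identical(a$selection$lambda_selected, b$selection$lambda_selected)
  expect_identical(a$radscore$model$youden_threshold,
                   b$radscore$model$youden_threshold)
  expect_identical(a$logistic$model$weights, b$logistic$model$weights)
  expect_identical(a$radscore$train$auc, b$radscore$train$auc)
})

test_that("combination sweep enumerates subsets and audits prefixes", {
  set.seed(70)
  n <- 40
  mk_tab <- function() matrix(rnorm(n * 6), n, 6,
                              dimnames = list(NULL, sprintf("feat%d", 1:6)))
  tabs <- list(ALFF = mk_tab(), DC = mk_tab(), ReHo = mk_tab(),
               VMHC = mk_tab())
  tabs$ReHo[1:20, 1:3] <- tabs$ReHo[1:20, 1:3] + 2
  y <- rep(c("CI", "CP"), each = 20)
  sp <- split_cohort(y, seed = 6)
  res <- suppressWarnings(combination_sweep(tabs, y, sp, n_folds = 5, seed = 7))
  expect_identical(length(res), 15L)
  expect_true("ReHo+VMHC" %in% names(res))
  solo <- res$ALFF$selection$retained
  expect_true(all(grepl("^ALFF_", solo)))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(71)
  s <- rnorm(50); y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  a0 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_auc(qnorm(plogis(s)), y)$auc, a0, tolerance = 1e-9)
})
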
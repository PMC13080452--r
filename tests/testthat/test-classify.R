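test_that("AUC matches exhaustive pair counting and rank conventions", {
  # 4-point hand example: pairs (0.1,0.35), (0.1,0.8), (0.4,0.35), (0.4,0.8)
  # -> 3 of 4 positive-above-negative pairs
  expect_equal(auc_mann_whitney(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  # brute-force oracle over random score sets, including ties
  set.seed(5)
  for (i in 1:20) {
    s <- sample(seq(0, 1, by = 0.1), 14, replace = TRUE)
    y <- rep(c(0, 1), each = 7)
    pairs <- outer(s[y == 1], s[y == 0], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(auc_mann_whitney(s, y), mean(pairs))
  }
  # invariance under strictly monotone transforms
  s <- rnorm(40)
  y <- rbinom(40, 1, 0.5)
  if (length(unique(y)) == 2) {
    expect_equal(auc_mann_whitney(exp(s), y), auc_mann_whitney(s, y))
    expect_equal(auc_mann_whitney(s^3 + 2 * s, y), auc_mann_whitney(s, y))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  s <- c(rnorm(30), rnorm(30, 1))
  y <- rep(0:1, each = 30)
  expect_equal(auc_mann_whitney(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("risk-score fit flags separation and recovers planted signal", {
  set.seed(21)
  X <- cbind(CLDN3 = c(rnorm(20), rnorm(20, 6)), CLDN4 = rnorm(40),
             EpCAM = rnorm(40))
  y <- rep(0:1, each = 20)
  fit <- fit_risk_score(X, y)
  expect_identical(fit$markers, c("CLDN3", "CLDN4", "EpCAM"))
  expect_equal(fit$auc, 1)
  expect_true(fit$separation)
  # null labels: AUC near 1/2 at large n
  set.seed(22)
  Xn <- matrix(rnorm(600 * 3), ncol = 3,
               dimnames = list(NULL, c("CLDN3", "CLDN4", "EpCAM")))
  yn <- rbinom(600, 1, 0.5)
  fitn <- fit_risk_score(Xn, yn)
  expect_lt(abs(fitn$auc - 0.5), 0.1)
  expect_false(fitn$separation)
  expect_error(fit_risk_score(X, rep(1, 40)), "both classes")
  # predict reproduces training scores
  expect_equal(predict(fit, X), fit$scores)
})

test_that("pooled-covariance LDA matches MASS on shared assumptions", {
  skip_if_not_installed("MASS")
  set.seed(31)
  mu <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(2.5, 2.5, 4.5))
  X <- do.call(rbind, lapply(1:4, function(g)
    sweep(matrix(rnorm(20 * 3), 20), 2, mu[g, ], "+")))
  colnames(X) <- c("a", "b", "c")
  y <- factor(rep(c("HD", "ES", "PS", "PR"), each = 20),
              levels = c("HD", "ES", "PS", "PR"))
  fit <- fit_lda(X, y)
  ref <- MASS::lda(X, grouping = y)
  expect_equal(as.character(predict(fit, X)),
               as.character(predict(ref, as.data.frame(X))$class))
  expect_gte(fit$accuracy, 0.95)
  # confusion-matrix row sums equal the true class counts
  expect_equal(unname(rowSums(fit$confusion)), rep(20, 4))
  # duplicating every sample leaves the decision rule unchanged
  fit2 <- fit_lda(rbind(X, X), factor(rep(y, 2), levels = levels(y)))
  expect_equal(as.character(predict(fit2, X)), as.character(predict(fit, X)))
  # posterior rows are proper probabilities
  post <- predict(fit, X, type = "posterior")
  expect_equal(unname(rowSums(post)), rep(1, nrow(X)))
})

test_that("LDA survives singular covariance by flagged diagonal loading", {
  set.seed(32)
  base <- matrix(rnorm(30 * 2), 30)
  X <- cbind(base, base[, 1] + base[, 2])  # exactly collinear third column
  colnames(X) <- c("a", "b", "c")
  y <- factor(rep(c("A", "B"), each = 15))
  fit <- fit_lda(X, y)
  expect_true(fit$loaded)
  expect_true(all(is.finite(fit$cov_inv)))
  expect_error(fit_lda(X[1:16, ], factor(c(rep("A", 15), "B"))), "at least 2")
})

test_that("LOOCV runs one fold per sample and handles degenerate folds", {
  set.seed(41)
  X <- matrix(rnorm(24 * 2), 24)
  colnames(X) <- c("a", "b")
  y <- factor(rep(c("A", "B"), each = 12))
  cv <- loocv(X, y)
  expect_equal(sum(cv$confusion), 24)
  expect_length(cv$predictions, 24)
  # constant features, balanced classes: LOO majority flips against the
  # held-out sample, so accuracy cannot beat chance
  Xc <- matrix(1, 24, 2) + matrix(rnorm(48, sd = 1e-9), 24)
  colnames(Xc) <- c("a", "b")
  cvc <- loocv(Xc, y)
  expect_lte(cvc$accuracy, 0.5)
  # a 2-sample class collapses in its folds; they are flagged, not fatal
  y3 <- factor(c(rep("A", 11), rep("B", 11), "C", "C"))
  cv3 <- loocv(X, y3)
  expect_equal(cv3$n_degenerate_folds, 2L)
  expect_length(cv3$predictions, 24)
})

test_that("stratified bootstrap SE is deterministic and calibrated", {
  set.seed(51)
  X <- matrix(rnorm(100), ncol = 1)
  y <- factor(rep(c("A", "B"), each = 50))
  # constant metric
  b0 <- bootstrap_se(function(Xb, yb) 1, X, y, n_boot = 50, seed = 4)
  expect_equal(b0$se, 0)
  # determinism under the seed contract
  b1 <- bootstrap_se(function(Xb, yb) mean(Xb), X, y, n_boot = 200, seed = 9)
  b2 <- bootstrap_se(function(Xb, yb) mean(Xb), X, y, n_boot = 200, seed = 9)
  expect_identical(b1$se, b2$se)
  # SE of the mean of n standard normals ~ 1/sqrt(n) within 15%
  b3 <- bootstrap_se(function(Xb, yb) mean(Xb), X, y, n_boot = 1000, seed = 2)
  expect_lt(abs(b3$se - 0.1) / 0.1, 0.15)
  # stratification preserves the group sizes in every resample
  b4 <- bootstrap_se(function(Xb, yb) as.numeric(all(table(yb) == c(50, 50))),
                     X, y, n_boot = 100, seed = 3)
  expect_equal(b4$se, 0)
  # failing metric resamples are redrawn and counted
  flaky <- local({
    k <- 0
    function(Xb, yb) {
      k <<- k + 1
      if (k %% 7 == 0) stop("numerical failure")
      mean(Xb)
    }
  })
  b5 <- bootstrap_se(flaky, X, y, n_boot = 50, seed = 5)
  expect_gt(b5$n_failed, 0)
  expect_length(b5$values, 50)
})

test_that("weighted F1 and recall follow support-weighted definitions", {
  cm <- confusion_matrix(factor(c("A", "A", "A", "B", "B", "C")),
                         factor(c("A", "A", "B", "B", "B", "B")))
  # per-class: A prec 1, rec 2/3; B prec 1/2, rec 1; C prec 0, rec 0
  rec <- weighted_recall(cm)
  expect_equal(rec, (3 * (2 / 3) + 2 * 1 + 1 * 0) / 6)
  f1A <- 2 * 1 * (2 / 3) / (1 + 2 / 3)
  f1B <- 2 * 0.5 * 1 / 1.5
  expect_equal(weighted_f1(cm), (3 * f1A + 2 * f1B + 0) / 6)
  expect_equal(unname(rowSums(cm)), c(3, 2, 1))
})
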
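#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve computed from the rank statistic: the probability
#' that a random positive scores above a random negative, with ties given
#' half credit. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (logical, 0/1, or two-level factor; the
#'   second/true level is the positive class).
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels) {
  y <- .as_binary(labels)
  .check_num(scores, "scores", len = length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

.as_binary <- function(labels) {
  if (is.logical(labels)) labels <- factor(labels, levels = c(FALSE, TRUE))
  if (is.factor(labels)) {
    if (nlevels(labels) < 2) stop("both classes must be present", call. = FALSE)
    if (nlevels(labels) > 2) stop("labels must be binary", call. = FALSE)
    return(as.integer(labels) - 1L)
  }
  u <- sort(unique(labels))
  if (length(u) < 2) stop("both classes must be present", call. = FALSE)
  if (length(u) > 2) stop("labels must be binary", call. = FALSE)
  as.integer(labels == u[2])
}

#' ROC curve by threshold sweep
#'
#' @inheritParams auc_mann_whitney
#' @return data.frame with `threshold`, `fpr`, `tpr`, ordered from the
#'   all-positive to the all-negative operating point.
#' @export
roc_curve <- function(scores, labels) {
  y <- .as_binary(labels)
  thr <- c(-Inf, sort(unique(scores)))
  fpr <- vapply(thr, function(t) mean(scores[y == 0] > t), 0)
  tpr <- vapply(thr, function(t) mean(scores[y == 1] > t), 0)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Logistic risk-score model
#'
#' Fits a maximum-likelihood logistic regression of a binary outcome on a
#' marker panel (default: the three-marker panel CLDN3/CLDN4/EpCAM when those
#' columns are present). The per-sample risk score is the linear predictor.
#' When the classes are linearly separable the ML fit degenerates; a small
#' ridge penalty is then applied instead and flagged in the result.
#'
#' @param X numeric matrix of (standardized) marker values, samples x markers.
#' @param y binary labels.
#' @param markers character vector of columns to use; `NULL` uses the default
#'   panel if available, otherwise all columns.
#' @param ridge_lambda penalty used by the separation fallback.
#' @return Object of class `risk_score_fit`: coefficients, scores, ROC curve,
#'   AUC, `separation` flag.
#' @export
fit_risk_score <- function(X, y, markers = NULL, ridge_lambda = 1e-2) {
  X <- as.matrix(X)
  yb <- .as_binary(y)
  if (length(unique(yb)) < 2) stop("both classes must be present", call. = FALSE)
  if (is.null(markers)) {
    panel <- c("CLDN3", "CLDN4", "EpCAM")
    markers <- if (all(panel %in% colnames(X))) panel
               else colnames(X) %||% seq_len(ncol(X))
  }
  Xm <- X[, markers, drop = FALSE]
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, Xm), yb,
                   family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  separated <- !fit$converged || any(abs(fit$coefficients[-1]) > 15) ||
    any(fit$fitted.values > 1 - 1e-10 & yb == 1) &&
    all((fit$fitted.values > 0.5) == (yb == 1))
  if (separated) {
    gfit <- glmnet::glmnet(Xm, yb, family = "binomial", alpha = 0,
                           lambda = ridge_lambda, standardize = FALSE)
    beta <- c(as.numeric(gfit$a0), as.numeric(gfit$beta))
    names(beta) <- c("(Intercept)", markers)
  } else {
    beta <- fit$coefficients
    names(beta) <- c("(Intercept)", markers)
  }
  scores <- as.numeric(cbind(1, Xm) %*% beta)
  structure(list(coefficients = beta, markers = markers, scores = scores,
                 labels = yb, roc = roc_curve(scores, yb),
                 auc = auc_mann_whitney(scores, yb),
                 separation = separated),
            class = "risk_score_fit")
}

#' @export
print.risk_score_fit <- function(x, ...) {
  cat(sprintf("Logistic risk score on {%s}: AUC = %.3f%s\n",
              paste(x$markers, collapse = ", "), x$auc,
              if (x$separation) " (separation: ridge fallback)" else ""))
  invisible(x)
}

#' @export
coef.risk_score_fit <- function(object, ...) object$coefficients

#' @export
predict.risk_score_fit <- function(object, newdata, type = c("score", "prob"), ...) {
  type <- match.arg(type)
  s <- as.numeric(cbind(1, as.matrix(newdata)[, object$markers, drop = FALSE]) %*%
                    object$coefficients)
  if (type == "score") s else 1 / (1 + exp(-s))
}

#' Linear discriminant analysis with pooled covariance
#'
#' Gaussian LDA: class means, a shared within-class covariance (pooled,
#' `n - g` denominator) and empirical class priors. Prediction assigns the
#' class maximizing the linear discriminant score. A singular pooled
#' covariance triggers diagonal loading (`1e-6 * trace/dim`), flagged in the
#' result.
#'
#' @param X numeric matrix, samples x markers.
#' @param y class labels (factor or character; >= 2 samples per class).
#' @return Object of class `lda_fit` with means, covariance, priors,
#'   training predictions, confusion matrix, accuracy, weighted F1 and
#'   weighted recall.
#' @export
fit_lda <- function(X, y) {
  X <- as.matrix(X)
  y <- factor(y)
  if (any(table(y) < 2))
    stop("each class needs at least 2 samples", call. = FALSE)
  g <- nlevels(y); n <- nrow(X); p <- ncol(X)
  mu <- t(vapply(levels(y), function(l) colMeans(X[y == l, , drop = FALSE]),
                 numeric(p)))
  Sp <- matrix(0, p, p)
  for (l in levels(y)) {
    Xl <- X[y == l, , drop = FALSE]
    Sp <- Sp + crossprod(sweep(Xl, 2, colMeans(Xl)))
  }
  Sp <- Sp / (n - g)
  loaded <- FALSE
  Sinv <- tryCatch(solve(Sp), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv)) || rcond(Sp) < 1e-12) {
    Sp <- Sp + diag(1e-6 * sum(diag(Sp)) / p, p)
    loaded <- TRUE
    Sinv <- tryCatch(solve(Sp), error = function(e)
      stop("pooled covariance singular even after diagonal loading",
           call. = FALSE))
  }
  priors <- as.numeric(table(y)) / n
  names(priors) <- levels(y)
  obj <- structure(list(means = mu, cov = Sp, cov_inv = Sinv, priors = priors,
                        levels = levels(y), markers = colnames(X),
                        loaded = loaded),
                   class = "lda_fit")
  pred <- predict(obj, X)
  cm <- confusion_matrix(y, pred)
  obj$predictions <- pred
  obj$confusion <- cm
  obj$accuracy <- sum(diag(cm)) / sum(cm)
  obj$weighted_f1 <- weighted_f1(cm)
  obj$weighted_recall <- weighted_recall(cm)
  obj
}

#' @export
print.lda_fit <- function(x, ...) {
  cat(sprintf("LDA (%d classes, pooled covariance%s): training accuracy %.3f, weighted F1 %.3f\n",
              length(x$levels), if (x$loaded) ", diagonally loaded" else "",
              x$accuracy, x$weighted_f1))
  print(x$confusion)
  invisible(x)
}

#' @export
predict.lda_fit <- function(object, newdata, type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  Xn <- as.matrix(newdata)
  if (!is.null(object$markers) && !is.null(colnames(Xn)))
    Xn <- Xn[, object$markers, drop = FALSE]
  # linear discriminant scores delta_k(x)
  W <- object$cov_inv %*% t(object$means)                  # p x g
  b <- -0.5 * colSums(t(object$means) * W) + log(object$priors)
  sc <- Xn %*% W + matrix(b, nrow(Xn), length(b), byrow = TRUE)
  if (type == "posterior") {
    e <- exp(sc - apply(sc, 1, max))
    return(e / rowSums(e))
  }
  factor(object$levels[max.col(sc, ties.method = "first")],
         levels = object$levels)
}

#' Confusion matrix and support-weighted classification metrics
#'
#' @param true,pred true and predicted labels (coerced to a common factor).
#' @return `confusion_matrix`: a table with one row per true class;
#'   row sums equal the true class counts.
#' @export
confusion_matrix <- function(true, pred) {
  lev <- union(levels(factor(true)), levels(factor(pred)))
  table(true = factor(true, levels = lev), predicted = factor(pred, levels = lev))
}

#' @rdname confusion_matrix
#' @param cm a confusion matrix from [confusion_matrix()].
#' @export
weighted_recall <- function(cm) {
  support <- rowSums(cm)
  rec <- ifelse(support > 0, diag(cm) / support, 0)
  sum(rec * support) / sum(support)
}

#' @rdname confusion_matrix
#' @export
weighted_f1 <- function(cm) {
  support <- rowSums(cm)
  predn <- colSums(cm)
  prec <- ifelse(predn > 0, diag(cm) / predn, 0)
  rec <- ifelse(support > 0, diag(cm) / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  sum(f1 * support) / sum(support)
}

#' Leave-one-out cross-validation
#'
#' Exactly n folds: fold i trains the supplied model on all samples but i and
#' predicts sample i. Folds whose training set loses an entire class are
#' still predicted (from the remaining classes) and counted in
#' `n_degenerate_folds`.
#'
#' @param X samples x markers matrix.
#' @param y class labels.
#' @param fit_fun fitting function `(X, y) -> model`; the model must have a
#'   `predict(model, newdata)` method returning class labels. Default
#'   [fit_lda()].
#' @return Object of class `loocv_result`: held-out `predictions`,
#'   `accuracy`, `weighted_f1`, `weighted_recall`, `confusion`,
#'   `n_degenerate_folds`.
#' @export
loocv <- function(X, y, fit_fun = fit_lda) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X)
  if (n < nlevels(y) + 1)
    stop("need at least one more sample than classes", call. = FALSE)
  preds <- character(n)
  degenerate <- 0L
  for (i in seq_len(n)) {
    yi <- droplevels(y[-i])
    Xi <- X[-i, , drop = FALSE]
    tab <- table(yi)
    if (any(tab < 2)) {
      # a training class collapsed: drop it for this fold and flag
      degenerate <- degenerate + 1L
      keep <- yi %in% names(tab)[tab >= 2]
      yi <- droplevels(yi[keep])
      Xi <- Xi[keep, , drop = FALSE]
    }
    m <- fit_fun(Xi, yi)
    preds[i] <- as.character(predict(m, X[i, , drop = FALSE]))
  }
  preds <- factor(preds, levels = levels(y))
  cm <- confusion_matrix(y, preds)
  structure(list(predictions = preds, confusion = cm,
                 accuracy = sum(diag(cm)) / n,
                 weighted_f1 = weighted_f1(cm),
                 weighted_recall = weighted_recall(cm),
                 n_degenerate_folds = degenerate),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV: accuracy %.3f, weighted F1 %.3f, weighted recall %.3f (%d folds)\n",
              x$accuracy, x$weighted_f1, x$weighted_recall, sum(x$confusion)))
  invisible(x)
}

#' Stratified bootstrap standard error of a classification metric
#'
#' Resamples samples with replacement within each class (preserving the
#' cohort's group sizes), re-evaluates the metric, and reports the standard
#' deviation over resamples. Deterministic under a fixed seed; resamples on
#' which the metric fails are redrawn (up to `10 * n_boot` attempts in
#' total).
#'
#' @param metric_fun function `(X, y) -> scalar`.
#' @param X samples x markers matrix.
#' @param y class labels.
#' @param n_boot number of bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @param stratified resample within classes (default) or over all rows.
#' @return Object of class `bootstrap_se`: `se`, `values`, `n_failed`.
#' @export
bootstrap_se <- function(metric_fun, X, y, n_boot = 1000L, seed = 1L,
                         stratified = TRUE) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  vals <- numeric(n_boot)
  got <- 0L; tries <- 0L; failed <- 0L
  idx_by_class <- split(seq_len(n), y)
  while (got < n_boot && tries < 10L * n_boot) {
    tries <- tries + 1L
    idx <- if (stratified)
      unlist(lapply(idx_by_class, function(ii) sample(ii, length(ii), replace = TRUE)))
    else sample.int(n, n, replace = TRUE)
    v <- tryCatch(metric_fun(X[idx, , drop = FALSE], y[idx]),
                  error = function(e) NA_real_)
    if (is.finite(v)) {
      got <- got + 1L
      vals[got] <- v
    } else failed <- failed + 1L
  }
  if (got < n_boot)
    stop("bootstrap metric failed too often", call. = FALSE)
  structure(list(se = sd(vals), values = vals, n_failed = failed),
            class = "bootstrap_se")
}

#' @export
print.bootstrap_se <- function(x, ...) {
  cat(sprintf("Bootstrap SE = %.4g over %d resamples (%d redrawn)\n",
              x$se, length(x$values), x$n_failed))
  invisible(x)
}
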
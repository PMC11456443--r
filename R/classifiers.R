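# Classifier backends for pairwise decoding. Each family exposes
# .fitPredict<Family>(Xtr, ytr, Xte, ...) returning predicted 0/1 labels.
# ytr/y are integer 0/1; ties resolve to class 0 throughout.

#' Fit a Gaussian naive Bayes model
#'
#' Class-conditional independent Gaussians: per-feature means and (maximum
#' likelihood) variances per class, with a relative variance floor
#' (`epsilon` times the largest pooled feature variance) added to every
#' variance for numerical stability.
#'
#' @param X Trials x features matrix.
#' @param y Class labels (any two values; sorted unique order defines class
#'   index 0/1).
#' @param epsilon Relative variance floor.
#' @return list of class `gaussianNb` with `classes`, `priors`, `mu`,
#'   `sigma2` (features x classes).
#' @export
gaussianNbFit <- function(X, y, epsilon = 1e-9) {
  X <- as.matrix(X)
  cls <- sort(unique(y))
  mu <- vapply(cls, function(k) colMeans(X[y == k, , drop = FALSE]),
               numeric(ncol(X)))
  s2 <- vapply(cls, function(k) {
    Z <- X[y == k, , drop = FALSE]
    colMeans(Z^2) - colMeans(Z)^2
  }, numeric(ncol(X)))
  mu <- matrix(mu, ncol(X)); s2 <- matrix(s2, ncol(X))
  floorVar <- epsilon * max(apply(X, 2, stats::var), 1e-300)
  s2 <- s2 + floorVar
  structure(list(classes = cls,
                 priors = as.vector(table(factor(y, cls))) / length(y),
                 mu = mu, sigma2 = s2),
            class = "gaussianNb")
}

#' Predict with a Gaussian naive Bayes model
#'
#' Evaluates `argmax_k P(y = k) * prod_i N(x_i; mu_ik, sigma_ik^2)` in log
#' space; ties resolve to the lower class index.
#'
#' @param model A `gaussianNb` from [gaussianNbFit()].
#' @param X Trials x features matrix.
#' @return Predicted class labels.
#' @export
gaussianNbPredict <- function(model, X) {
  X <- as.matrix(X)
  lp <- vapply(seq_along(model$classes), function(k) {
    mu <- model$mu[, k]; s2 <- model$sigma2[, k]
    rowSums(-0.5 * (log(2 * pi * rep(1, nrow(X)) %o% s2) +
                      sweep(X, 2, mu)^2 / (rep(1, nrow(X)) %o% s2))) +
      log(model$priors[k])
  }, numeric(nrow(X)))
  lp <- matrix(lp, nrow(X))
  model$classes[max.col(lp, ties.method = "first")]
}

#' Ledoit-Wolf covariance shrinkage
#'
#' Shrinks the empirical covariance of (already centered) observations
#' toward a scaled identity, with the Ledoit-Wolf (2004) optimal shrinkage
#' intensity.
#'
#' @param Xc Centered observations (n x p).
#' @return list with `sigma` (shrunk covariance), `shrinkage`, `mu`.
#' @export
ledoitWolfShrinkage <- function(Xc) {
  Xc <- as.matrix(Xc)
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  delta2 <- sum((S - mu * diag(p))^2) / p
  if (delta2 < 1e-300)
    return(list(sigma = S, shrinkage = 0, mu = mu))
  # b2 = (1/(n^2 p)) * sum_i ||x_i x_i' - S||_F^2, using
  # sum_i ||x_i x_i'||_F^2 = sum_i (x_i'x_i)^2 and sum_i x_i x_i' = n S
  b2 <- (sum(rowSums(Xc^2)^2) - n * sum(S^2)) / (n^2 * p)
  b2 <- max(0, min(b2, delta2))
  shrink <- b2 / delta2
  list(sigma = (1 - shrink) * S + shrink * mu * diag(p),
       shrinkage = shrink, mu = mu)
}

# Binary LDA with shared Ledoit-Wolf-shrunk covariance (least-squares
# solve of Sigma w = mu1 - mu0, priors from class frequencies).
.fitPredictLda <- function(Xtr, ytr, Xte) {
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  m0 <- colMeans(Xtr[ytr == 0, , drop = FALSE])
  m1 <- colMeans(Xtr[ytr == 1, , drop = FALSE])
  Xc <- Xtr
  Xc[ytr == 0, ] <- sweep(Xtr[ytr == 0, , drop = FALSE], 2, m0)
  Xc[ytr == 1, ] <- sweep(Xtr[ytr == 1, , drop = FALSE], 2, m1)
  lw <- ledoitWolfShrinkage(Xc)
  w <- tryCatch(solve(lw$sigma, m1 - m0),
                error = function(e) MASS_ginv(lw$sigma) %*% (m1 - m0))
  pri <- c(mean(ytr == 0), mean(ytr == 1))
  b <- -0.5 * sum((m1 + m0) * w) + log(pri[2] / pri[1])
  as.integer(as.vector(Xte %*% w) + b > 0)
}

# Moore-Penrose fallback without importing MASS.
MASS_ginv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

.fitPredictNb <- function(Xtr, ytr, Xte) {
  m <- gaussianNbFit(Xtr, ytr)
  as.integer(gaussianNbPredict(m, Xte))
}

# L2 logistic regression over the paper's C grid via glmnet ridge
# (lambda = 1/(n*C)); C chosen by stratified inner CV on the training
# fold, ties toward the smallest C (strongest regularization), then refit
# on the full training fold.
.fitPredictLogR <- function(Xtr, ytr, Xte, cGrid = 10^(-6:4),
                            innerFolds = 6L) {
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  pad <- ncol(Xtr) < 2L
  if (pad) { Xtr <- cbind(Xtr, 0); Xte <- cbind(Xte, 0) }
  lamGrid <- sort(1 / (nrow(Xtr) * cGrid), decreasing = TRUE)
  fitPath <- function(X, y) {
    glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                   lambda = lamGrid, standardize = FALSE)
  }
  folds <- stratifiedFolds(ytr, innerFolds)
  acc <- matrix(NA_real_, length(lamGrid), max(folds))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    if (length(unique(ytr[tr])) < 2 || length(unique(ytr[!tr])) < 1) next
    g <- fitPath(Xtr[tr, , drop = FALSE], ytr[tr])
    pr <- stats::predict(g, Xtr[!tr, , drop = FALSE], s = lamGrid,
                         type = "class")
    acc[, f] <- colMeans(matrix(as.numeric(pr), sum(!tr)) == ytr[!tr])
  }
  mAcc <- rowMeans(acc, na.rm = TRUE)
  # lamGrid is decreasing = C increasing; first max -> smallest C
  bestLam <- lamGrid[which.max(mAcc)]
  g <- fitPath(Xtr, ytr)
  as.integer(stats::predict(g, Xte, s = bestLam, type = "class"))
}

# RBF SVM with sklearn-style gamma = 1/(p * Var(X)) and C chosen by
# stratified inner CV over the paper's grid (ties -> smallest C).
.fitPredictSvm <- function(Xtr, ytr, Xte, cGrid = 10^(-6:4),
                           innerFolds = 6L) {
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  v <- stats::var(as.vector(Xtr))
  gam <- if (is.finite(v) && v > 0) 1 / (ncol(Xtr) * v) else 1 / ncol(Xtr)
  yf <- factor(ytr, levels = c(0, 1))
  folds <- stratifiedFolds(ytr, innerFolds)
  acc <- vapply(cGrid, function(C) {
    ok <- 0; tot <- 0
    for (f in seq_len(max(folds))) {
      tr <- folds != f
      if (length(unique(ytr[tr])) < 2) next
      m <- e1071::svm(Xtr[tr, , drop = FALSE], yf[tr], kernel = "radial",
                      cost = C, gamma = gam, scale = FALSE)
      p <- stats::predict(m, Xtr[!tr, , drop = FALSE])
      ok <- ok + sum(p == yf[!tr]); tot <- tot + sum(!tr)
    }
    if (tot == 0) NA_real_ else ok / tot
  }, numeric(1))
  bestC <- cGrid[which.max(acc)]
  m <- e1071::svm(Xtr, yf, kernel = "radial", cost = bestC, gamma = gam,
                  scale = FALSE)
  as.integer(as.character(stats::predict(m, Xte)))
}

.fitPredictRf <- function(Xtr, ytr, Xte, nTrees = 100L) {
  yf <- factor(ytr, levels = c(0, 1))
  m <- randomForest::randomForest(as.matrix(Xtr), yf, ntree = nTrees,
                                  mtry = max(1L, floor(sqrt(ncol(Xtr)))))
  pr <- stats::predict(m, as.matrix(Xte), type = "prob")
  as.integer(pr[, "1"] > pr[, "0"])  # tie -> class 0
}

#' Stratified fold assignment
#'
#' Assigns trials to `k` folds, balancing classes: within each class, fold
#' labels are a shuffled near-even split. Uses the current RNG stream.
#'
#' @param y Class labels.
#' @param k Number of folds.
#' @return Integer fold id per trial.
#' @export
stratifiedFolds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Supported classifier families
#' @return Character vector of family codes.
#' @export
classifierFamilies <- function() c("logr", "lda", "nb", "svm", "rf")

# Dispatch a family's fit/predict on 0/1 labels.
.familyFitPredict <- function(family, Xtr, ytr, Xte, cGrid, innerFolds) {
  switch(family,
         logr = .fitPredictLogR(Xtr, ytr, Xte, cGrid, innerFolds),
         lda  = .fitPredictLda(Xtr, ytr, Xte),
         nb   = .fitPredictNb(Xtr, ytr, Xte),
         svm  = .fitPredictSvm(Xtr, ytr, Xte, cGrid, innerFolds),
         rf   = .fitPredictRf(Xtr, ytr, Xte),
         stop("unknown classifier family: ", family))
}
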